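toy_contacts <- function(reps, i, j) {
  tibble::tibble(structure_id = "s1", repeat_id = reps,
                 ank_position_a = i, partner_class = "intra_repeat",
                 ank_position_b = j, partner_id = reps,
                 interaction_type = "any", distance = 4)
}

full_coverage <- function(rep_ids, positions = 1:33) {
  tidyr::expand_grid(repeat_id = rep_ids, ank_position = positions) |>
    dplyr::mutate(structure_id = "s1", .before = 1)
}

test_that("contact map counts binary repeat evidence over pair coverage", {
  reps <- sprintf("r%02d", 1:10)
  cts <- toy_contacts(reps[1:4], 5L, 21L)
  map <- build_intra_map(cts, full_coverage(reps))
  nm <- normalized_map(map)
  expect_equal(nm[5, 21], 0.4)
  expect_equal(nm[21, 5], 0.4)
  # a repeat missing position 21 leaves o(5,21) at 9
  cov2 <- full_coverage(reps) |>
    dplyr::filter(!(repeat_id == "r10" & ank_position == 21))
  map2 <- build_intra_map(cts, cov2)
  expect_equal(map2$o[5, 21], 9)
  # multiple atomic contacts in one repeat still count once
  map3 <- build_intra_map(dplyr::bind_rows(cts, cts[1, ]),
                          full_coverage(reps))
  expect_equal(map3$c[5, 21], 4)
  expect_error(build_intra_map(toy_contacts("r1", 5L, 40L),
                               full_coverage("r1")), "positions outside")
})

test_that("contact maps stay symmetric with c <= o through filtering", {
  tr <- synthetic_truth(seed = 17)
  aln <- generate_alignment(tr, 80, 0)
  st <- generate_structures(aln, tr, 80)
  f <- filter_by_quality(st$structures)
  map <- build_intra_map(st$contacts, f[c("structure_id", "repeat_id",
                                          "ank_position")])
  expect_identical(map$c, t(map$c))
  expect_identical(map$o, t(map$o))
  expect_true(all(map$c <= map$o))
  fm <- filter_short_range(map)
  expect_identical(fm$c, t(fm$c))
  expect_true(all(fm$c <= fm$o))
  # row sums double-count each distinct pair observation
  expect_equal(sum(rowSums(fm$c)), 2 * sum(fm$c[upper.tri(fm$c)]))
})

test_that("short-range filtering keeps exactly the |i-j| >= 7 pairs", {
  map <- structure(list(c = matrix(1L, 33, 33), o = matrix(2L, 33, 33),
                        n_positions = 33L), class = "contact_map")
  fm <- filter_short_range(map)
  expect_equal(fm$c[5, 11], 0)      # |delta| = 6: removed
  expect_equal(fm$o[5, 11], 0)
  expect_equal(fm$c[5, 12], 1)      # |delta| = 7: retained
  expect_equal(sum(fm$c[upper.tri(fm$c)] > 0), 351)
})

test_that("planted contact probabilities are recovered within 3 sigma", {
  p <- matrix(0.5, 33, 33); diag(p) <- 0
  tr <- synthetic_truth(contact_probs = p, quality_fail_fraction = 0,
                        seed = 23)
  aln <- generate_alignment(tr, 1000, 0)
  st <- generate_structures(aln, tr, 1000)
  map <- build_intra_map(st$contacts,
                         st$structures[c("structure_id", "repeat_id",
                                         "ank_position")])
  nm <- normalized_map(map)
  off <- nm[upper.tri(nm)]
  sigma <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(off - 0.5) < 3 * sigma + 1e-12) ||
                mean(abs(off - 0.5) < 3 * sigma) > 0.99)
  expect_equal(mean(off), 0.5, tolerance = 0.01)
})

test_that("contact enrichment is null on homogeneous maps and scale invariant", {
  o <- matrix(20L, 33, 33); diag(o) <- 0L
  cmat <- matrix(10L, 33, 33); diag(cmat) <- 0L
  map <- filter_short_range(structure(
    list(c = cmat, o = o, n_positions = 33L), class = "contact_map"))
  enr <- contact_enrichment(map)
  expect_equal(enr$score, rep(0, 33))
  map2 <- map; map2$c <- map$c * 2L; map2$o <- map$o * 2L
  expect_equal(contact_enrichment(map2)$score, enr$score)
})

test_that("contact enrichment matches hand arithmetic on a 4-position toy", {
  cmat <- matrix(c(0, 3, 1, 2,
                   3, 0, 4, 0,
                   1, 4, 0, 5,
                   2, 0, 5, 0), 4, 4)
  o <- matrix(10L, 4, 4)
  map <- structure(list(c = cmat, o = o, n_positions = 4L),
                   class = "contact_map")
  enr <- contact_enrichment(map)
  Ci <- rowSums(cmat); Oi <- rowSums(o)
  for (i in 1:4) {
    want <- oracle_2x2(Ci[i], Oi[i], sum(Ci) - Ci[i], sum(Oi) - Oi[i])
    expect_equal(enr$score[i], want$score)
    expect_equal(enr$p[i], want$p)
  }
  # zero-coverage positions are reported unscored
  map$o[2, ] <- 0L; map$o[, 2] <- 0L; map$c[2, ] <- 0L; map$c[, 2] <- 0L
  enr2 <- contact_enrichment(map)
  expect_true(is.na(enr2$score[2]))
})

test_that("substrate evidence is binary per repeat and coverage-restricted", {
  sub <- tibble::tibble(structure_id = "s1", repeat_id = "r1",
                        ank_position_a = c(2L, 2L, 2L),
                        partner_class = "substrate",
                        ank_position_b = NA_integer_,
                        partner_id = "pep", interaction_type = "any",
                        distance = c(3.1, 4.0, 4.9))
  cov <- full_coverage(c("r1", "r2"))
  ev <- ppi_evidence(sub, cov)
  expect_equal(ev$a[2], 1L)              # three atomic contacts, one evidence
  expect_equal(ev$n[2], 2L)              # both repeats of the bound structure
  # no substrate rows anywhere: all evidence zero
  ev0 <- ppi_evidence(sub[0, ], cov, bound_structures = "s1")
  expect_equal(sum(ev0$a), 0L)
})

test_that("PPIES is null under uniform evidence and consistent per column", {
  ev <- tibble::tibble(ank_position = 1:33, a = 5L, n = 50L)
  out <- ppies(ev)
  expect_equal(out$score, rep(0, 33))
  grp <- ppies(ev, set_a = 4L)
  col <- out[out$position == 4, ]
  expect_equal(grp$score, col$score)
  expect_equal(grp$p, col$p)
  expect_error(ppies(ev, set_a = 1:2, set_b = 2:3), "overlap")
})

test_that("binding modes honour the repeat/residue minima and dominance rule", {
  mk <- function(protein, reps, pos) {
    tibble::tibble(protein_id = protein, repeat_id = reps, ank_position = pos)
  }
  # 5 concave residues on 2 repeats: concave mode
  b1 <- mk("p1", c("r1", "r1", "r1", "r2", "r2"), c(1L, 2L, 3L, 8L, 11L))
  m1 <- binding_mode(b1)
  expect_identical(m1$mode, "concave")
  # 3 residues: below the minimum, not evaluated
  m2 <- binding_mode(mk("p2", c("r1", "r2", "r2"), c(1L, 2L, 3L)))
  expect_identical(m2$mode, "not_evaluated")
  # 4 residues on a single repeat: not evaluated either
  m3 <- binding_mode(mk("p3", "r1", c(1L, 2L, 3L, 8L)))
  expect_identical(m3$mode, "not_evaluated")
  # 2/2/2 split across surfaces: mixed
  m4 <- binding_mode(mk("p4", c("r1", "r1", "r1", "r2", "r2", "r2"),
                        c(1L, 2L, 13L, 14L, 25L, 26L)))
  expect_identical(m4$mode, "mixed")
  expect_equal(m4$frac_concave, 1 / 3)
})
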