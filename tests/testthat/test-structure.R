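make_records <- function(n, rscc = 0.95, rsrz = 0, rsa = 0.3, ss8 = "H",
                         position = 1L) {
  tibble::tibble(structure_id = "s1", repeat_id = "r1",
                 ank_position = position, aa = "A",
                 rsa = rep_len(rsa, n), ss8 = rep_len(ss8, n),
                 phi = -60, psi = -45,
                 rscc = rep_len(rscc, n), rsrz = rep_len(rsrz, n))
}

test_that("quality filter applies strict thresholds and is idempotent", {
  rec <- dplyr::bind_rows(
    make_records(1, rscc = 0.85, rsrz = 0),    # boundary RSCC: dropped
    make_records(1, rscc = 0.9, rsrz = 1.9),   # kept
    make_records(1, rscc = 0.9, rsrz = 2),     # boundary RSRZ: dropped
    make_records(1, rscc = NA, rsrz = 0)       # missing metric: dropped
  )
  f <- filter_by_quality(rec)
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "n_dropped"), 3)
  f2 <- filter_by_quality(f)
  expect_equal(nrow(f2), nrow(f))
  expect_equal(attr(f2, "n_dropped"), 0)
})

test_that("planted quality failures survive at the planted rate", {
  tr <- synthetic_truth(quality_fail_fraction = 0.25, seed = 13)
  aln <- generate_alignment(tr, 40, 0)
  st <- generate_structures(aln, tr, 31)   # 1023 residues
  f <- filter_by_quality(st$structures)
  n <- nrow(st$structures)
  expect_equal(attr(f, "n_dropped") / n, 0.25,
               tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.25)
})

test_that("RSA normalisation uses the Tien theoretical maxima", {
  expect_equal(rsa_from_asa(0, "A"), 0)
  expect_equal(rsa_from_asa(129, "A"), 1)
  expect_equal(rsa_from_asa(52, "G"), 0.5)
  expect_equal(rsa_from_asa(264, "W"), 1)
  expect_gt(rsa_from_asa(200, "G"), 1)       # over-exposed values pass through
  expect_error(rsa_from_asa(10, "Z"), "unknown residue")
})

test_that("RSA classes partition [0, Inf) with inclusive boundaries", {
  expect_identical(classify_rsa(0.05), "buried")
  expect_identical(classify_rsa(0.25), "surface")
  expect_identical(classify_rsa(0.10), "partial")
  grid <- seq(0, 1.5, by = 0.005)
  cls <- classify_rsa(grid)
  expect_true(all(cls %in% c("buried", "partial", "surface")))
  expect_identical(cls, dplyr::case_when(grid <= 0.05 ~ "buried",
                                         grid >= 0.25 ~ "surface",
                                         TRUE ~ "partial"))
})

test_that("column summaries report SS consensus, median RSA and its CI", {
  rec <- make_records(10, ss8 = "H", rsa = c(0.1, 0.2, 0.3))
  s <- column_struct_summary(rec, 1)
  expect_equal(s$ss8_H, 1)
  expect_identical(s$consensus_ss, "H")
  expect_equal(s$median_rsa, 0.2)
  expect_identical(s$rsa_class, "partial")

  # planted Beta(mean 0.5) column: the true median sits inside the CI
  tr <- synthetic_truth(rsa_mean = 0.5, seed = 3)
  aln <- generate_alignment(tr, 500, 0)
  st <- generate_structures(aln, tr, 500)
  f <- filter_by_quality(st$structures)
  s7 <- column_struct_summary(f, 7)
  expect_gt(s7$n_residues, 400)
  expect_true(s7$rsa_ci_low <= 0.5 && 0.5 <= s7$rsa_ci_high)
  # seeded bootstrap is reproducible
  s7b <- column_struct_summary(f, 7)
  expect_equal(s7$rsa_ci_low, s7b$rsa_ci_low)
})

test_that("SS consensus recovers the planted argmax at every column", {
  ss <- matrix(0.05, 8, 33)
  argmax <- rep(c(1, 4, 6, 8), length.out = 33)   # H, E, T, C
  for (j in 1:33) ss[argmax[j], j] <- 1 - 0.05 * 7
  tr <- synthetic_truth(ss_labels = ss, quality_fail_fraction = 0, seed = 9)
  aln <- generate_alignment(tr, 200, 0)
  st <- generate_structures(aln, tr, 200)
  sm <- struct_summary_all(filter_by_quality(st$structures), n_boot = 50)
  expect_identical(sm$consensus_ss, c("H", "G", "I", "E", "B", "T", "S",
                                      "C")[argmax])
})

test_that("beta-turn typing matches ideals and the nearest-type rule", {
  expect_identical(classify_beta_turn(-60, -30, -90, 0), "I")
  expect_identical(classify_beta_turn(-60, 120, 80, 0), "II")
  expect_identical(classify_beta_turn(-60, -30, -120, 120), "VIII")
  expect_identical(classify_beta_turn(60, 30, 90, 0), "I'")
  expect_identical(classify_beta_turn(60, -120, -80, 0), "II'")
  expect_identical(classify_beta_turn(0, 0, 0, 180), "other")
  expect_true(is.na(classify_beta_turn(NA, 0, 0, 0)))
})

test_that("turn typing agrees with a brute-force nearest-type oracle", {
  ideals <- rbind(I = c(-60, -30, -90, 0), "I'" = c(60, 30, 90, 0),
                  II = c(-60, 120, 80, 0), "II'" = c(60, -120, -80, 0),
                  VIII = c(-60, -30, -120, 120))
  tol <- c(45, 90, 45, 45)
  wrap <- function(a, b) pmin(abs(a - b) %% 360, 360 - abs(a - b) %% 360)
  oracle <- function(ang) {
    d <- t(apply(ideals, 1, wrap, b = ang))
    ok <- apply(d, 1, function(x) all(x <= tol))
    if (!any(ok)) return("other")
    rownames(ideals)[which.min(ifelse(ok, rowSums(d), Inf))]
  }
  grid <- seq(-180, 170, by = 10)
  set.seed(1)
  for (k in 1:300) {
    ang <- sample(grid, 4, replace = TRUE)
    expect_identical(classify_beta_turn(ang[1], ang[2], ang[3], ang[4]),
                     oracle(ang), label = paste(ang, collapse = ","))
  }
})

test_that("Asx motifs require an Asx anchor and the diagnostic hydrogen bonds", {
  hb <- function(...) tibble::tibble(...)
  b29 <- hb(from_pos = 27L, from_atom = "side_chain", to_pos = 29L,
            to_atom = "backbone")
  expect_identical(detect_asx_motif(27L, "D", b29), "asx_beta_turn")
  expect_identical(detect_asx_motif(27L, "S", b29), "none")
  expect_identical(detect_asx_motif(27L, "N", b29[0, ]), "none")
  # reversed bond direction also matches
  b29r <- hb(from_pos = 29L, from_atom = "backbone", to_pos = 27L,
             to_atom = "side_chain")
  expect_identical(detect_asx_motif(27L, "N", b29r), "asx_beta_turn")
  # position 32 wraps into the next repeat: bonds to N of positions 1 and 3
  b32 <- hb(from_pos = c(32L, 32L), from_atom = "side_chain",
            to_pos = c(1L, 3L), to_atom = "backbone")
  expect_identical(detect_asx_motif(32L, "N", b32), "type1_beta_bulge_asx")
  expect_identical(detect_asx_motif(32L, "N", b32[1, ]), "none")
})

test_that("annotate_turns types the two canonical motif turns per repeat", {
  rec <- tibble::tibble(
    repeat_id = "r1",
    ank_position = c(28L, 29L, 33L, 1L),
    aa = c("A", "A", "A", "A"),
    phi = c(-60, -90, -60, 80), psi = c(-30, 0, 120, 0)
  )
  out <- annotate_turns(rec)
  expect_equal(nrow(out), 2)
  expect_identical(out$turn_type[out$span == "27-30"], "I")
  expect_identical(out$turn_type[out$span == "32-2"], "II")
})
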