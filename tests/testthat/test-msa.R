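test_that("build_profile counts exclude gaps and X, pseudocount shifts freqs", {
  aln <- repeat_alignment(c("AC", "AC"))
  p <- build_profile(aln)
  expect_equal(unname(p$counts["A", 1]), 2L)
  expect_equal(unname(p$frequencies["A", 1]), 1)
  aln2 <- repeat_alignment(c("A-", "AC", "AX"))
  p2 <- build_profile(aln2)
  expect_equal(unname(p2$occupancy[2]), 2 / 3)      # X occupies, gap does not
  expect_equal(p2$n_effective[2], 1L)               # but X never counts
  p3 <- build_profile(repeat_alignment(rep("A", 4)), pseudocount = 1)
  expect_equal(unname(p3$frequencies["A", 1]), 5 / 24)
  expect_equal(sum(p3$frequencies[, 1]), 1)
})

test_that("profile aligner reproduces identity, deletion and insertion cases", {
  p <- sharp_profile()
  cons <- consensus_of(p)
  r <- align_to_profile(cons, p)
  expect_identical(r$row, cons)
  expect_length(r$insertion_flags, 0)

  del <- paste0(substr(cons, 1, 14), substr(cons, 16, 33))
  rd <- align_to_profile(del, p)
  expect_equal(stringr::str_count(rd$row, "-"), 1)
  expect_length(rd$insertion_flags, 0)
  expect_identical(degap(rd$row), del)              # round trip

  ins <- paste0(substr(cons, 1, 15), "W", substr(cons, 16, 33))
  ri <- align_to_profile(ins, p)
  expect_identical(ri$insertion_flags, 16L)
  expect_identical(paste0(substr(ri$row, 1, 15), ri$insertions[["15"]],
                          substr(ri$row, 16, 33)), ins)

  expect_error(align_to_profile("AC", p), "shorter than 3")
})

test_that("terminal overhangs are free and never flagged", {
  p <- sharp_profile()
  cons <- consensus_of(p)
  r_pre <- align_to_profile(paste0("WW", cons), p)
  expect_length(r_pre$insertion_flags, 0)
  expect_identical(names(r_pre$insertions), "0")
  r_post <- align_to_profile(paste0(cons, "WWW"), p)
  expect_length(r_post$insertion_flags, 0)
  expect_identical(names(r_post$insertions), "33")
  expect_equal(r_pre$score, r_post$score)           # overhang costs nothing
})

test_that("aligner matches the exhaustive enumeration oracle on toy profiles", {
  # 4-column sharp profile over a reduced alphabet; all sequences up to
  # length 5 over {A, R} plus the consensus variants
  toy <- build_profile(repeat_alignment(rep("ARAR", 6)))
  S <- ankprof:::profile_score_matrix(toy, pseudocount = 1)
  seqs <- unlist(lapply(3:5, function(n) {
    apply(expand.grid(rep(list(c("A", "R")), n)), 1, paste, collapse = "")
  }))
  for (s in seqs) {
    got <- align_to_profile(s, toy)$score
    want <- oracle_align_score(s, S)
    expect_equal(got, want, tolerance = 1e-9, label = paste("seq", s))
  }
})

test_that("gap introducers are detected only for core-interior insertions", {
  p <- sharp_profile()
  cons <- consensus_of(p)
  batch <- seq_batch(c(cons, paste0(substr(cons, 1, 10), "W",
                                    substr(cons, 11, 33)),
                       paste0("W", cons)),
                     ids = c("clean", "interior", "leading"))
  res <- lapply(seq_len(nrow(batch)), function(k) {
    align_to_profile(batch$seq[k], p, id = batch$id[k])
  })
  expect_identical(detect_gap_introducers(res), "interior")
})

test_that("iterative_build keeps clean corpora gap-free and logs introducers", {
  set.seed(42)
  tr <- synthetic_truth(column_alphas = matrix(0.2, 20, 33), seed = 42)
  aln <- generate_alignment(tr, 90, 0)
  seqs <- degap(aln$rows)
  groups <- list(seq_batch(seqs[1:30], ids = sprintf("g1_%02d", 1:30)),
                 seq_batch(seqs[31:60], ids = sprintf("g2_%02d", 1:30)),
                 seq_batch(seqs[61:90], ids = sprintf("g3_%02d", 1:30)))
  built <- iterative_build(groups)
  expect_equal(nrow(built$removed), 0)
  expect_equal(aln_width(built$alignment), 33)
  expect_false(any(grepl("-", built$alignment$rows, fixed = TRUE)))
  expect_length(built$kept_ids, 90)

  # plant interior insertions in 3 sequences of group 2: they are removed
  # before the final re-append and reported in the log
  bad_ids <- sprintf("g2_%02d", 1:3)
  groups2 <- groups
  groups2[[2]]$seq[1:3] <- paste0(substr(groups2[[2]]$seq[1:3], 1, 16), "W",
                                  substr(groups2[[2]]$seq[1:3], 17, 33))
  built2 <- iterative_build(groups2)
  expect_setequal(built2$removed$id, bad_ids)
  expect_setequal(setdiff(built2$alignment$meta$id, built2$kept_ids), bad_ids)
  # the re-appended introducers bring an insertion column; core stays 33
  expect_length(built2$alignment$core_columns, 33)
  expect_gt(aln_width(built2$alignment), 33)
  # round trip: every aligned row de-gaps to its input
  all_in <- dplyr::bind_rows(groups2)
  got <- degap(built2$alignment$rows)
  expect_identical(got, unname(all_in$seq[match(built2$alignment$meta$id,
                                                all_in$id)]))
})

test_that("group order does not change core-column membership on clean data", {
  set.seed(7)
  tr <- synthetic_truth(column_alphas = matrix(0.2, 20, 33), seed = 7)
  seqs <- degap(generate_alignment(tr, 40, 0)$rows)
  g <- list(seq_batch(seqs[1:20], ids = sprintf("a%02d", 1:20)),
            seq_batch(seqs[21:30], ids = sprintf("b%02d", 1:10)),
            seq_batch(seqs[31:40], ids = sprintf("c%02d", 1:10)))
  b1 <- iterative_build(list(g[[1]], g[[2]], g[[3]]))
  b2 <- iterative_build(list(g[[1]], g[[3]], g[[2]]))
  expect_length(b1$alignment$core_columns, 33)
  expect_length(b2$alignment$core_columns, 33)
  expect_setequal(b1$alignment$meta$id, b2$alignment$meta$id)
  expect_equal(nrow(b1$removed), 0)
  expect_equal(nrow(b2$removed), 0)
})

test_that("occupancy filter is strictly greater-than", {
  expect_identical(filter_columns_by_occupancy(c(1.0, 0.004, 0.9)), c(1L, 3L))
  expect_identical(filter_columns_by_occupancy(c(0.3, 0, 0.2), 0), c(1L, 3L))
  # 1 of 200 rows occupying a column sits exactly at 0.5% and is removed
  expect_identical(filter_columns_by_occupancy(c(1, 1 / 200), 0.005), 1L)
})
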