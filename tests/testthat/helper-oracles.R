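# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner oracle enumerates every monotone
# alignment explicitly, and the 2x2 oracle assembles tables by direct
# iteration over residues/pairs and recomputes ratio, CI and p from first
# principles.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Exhaustive-enumeration alignment oracle: optimal score of aligning `seq`
# against the score matrix S (20 x L, rownames AA), global in the profile,
# free terminal sequence overhangs, affine gaps (run cost open+(g-1)*extend).
oracle_align_score <- function(seq, S, gap_open = -10, gap_extend = -0.5) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(chars)
  L <- ncol(S)
  run_cost <- function(g) if (g == 0) 0 else gap_open + (g - 1) * gap_extend
  best <- -Inf
  subsets <- lapply(0:(2^L - 1), function(b) which(bitwAnd(b, 2^(0:(L - 1))) > 0))
  for (cols in subsets) {
    k <- length(cols)
    if (k > m) next
    assignments <- if (k == 0) list(integer(0)) else combn(m, k, simplify = FALSE)
    for (res in assignments) {
      sc <- 0
      if (k > 0) sc <- sum(S[cbind(match(chars[res], rownames(S)), cols)])
      # deletion runs: unmatched columns, split by the matched ones
      unmatched <- setdiff(seq_len(L), cols)
      if (length(unmatched)) {
        runs <- split(unmatched, cumsum(c(1, diff(unmatched) != 1)))
        sc <- sc + sum(vapply(runs, function(r) run_cost(length(r)), 0))
      }
      # insertion runs: unmatched residues strictly between matched ones
      if (k > 0) {
        inner <- setdiff(seq(min(res), max(res)), res)
        if (length(inner)) {
          runs <- split(inner, cumsum(c(1, diff(inner) != 1)))
          sc <- sc + sum(vapply(runs, function(r) run_cost(length(r)), 0))
        }
      }
      best <- max(best, sc)
    }
  }
  best
}

# 2x2 ratio oracle: score, Katz CI and Fisher p from the four counts.
oracle_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b - a, c, d - c)
  if (any(cells == 0)) {
    a <- a + 0.5; b <- b + 1; c <- c + 0.5; d <- d + 1
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a - 1 / b + 1 / c - 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or, score = log(or),
       ci = log(or) + c(-z, z) * se,
       p = fisher.test(matrix(round(cells), 2))$p.value)
}

# Direct-iteration assembly of the per-column missense 2x2 table from the raw
# variant tibble and alignment, without map_variants_to_columns().
oracle_mes_table <- function(variants, aln, ank_pos) {
  core <- aln$core_columns
  human_rows <- which(aln$meta$is_human)
  occ <- integer(length(core))
  hits <- integer(length(core))
  seen <- character(0)
  for (r in human_rows) {
    chars <- strsplit(aln$rows[r], "", fixed = TRUE)[[1]]
    respos <- 0L
    id <- aln$meta$id[r]
    for (col in seq_along(chars)) {
      if (chars[col] == "-") next
      respos <- respos + 1L
      k <- match(col, core)
      if (is.na(k)) next
      occ[k] <- occ[k] + 1L
      vsub <- variants[variants$sequence_id == id &
                         variants$residue_position == respos &
                         variants$consequence == "missense", ]
      if (nrow(vsub) > 0) hits[k] <- hits[k] + 1L
    }
  }
  list(a = hits[ank_pos], b = occ[ank_pos],
       c = sum(hits[-ank_pos]), d = sum(occ[-ank_pos]))
}

# Sharp 33-column test profile built from repeated copies of a consensus.
sharp_profile <- function(cons = "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNP",
                          n_copies = 8) {
  build_profile(repeat_alignment(rep(cons, n_copies)))
}

consensus_of <- function(profile) {
  paste(rownames(profile$counts)[apply(profile$counts, 2, which.max)],
        collapse = "")
}

# Tiny sequence-record tibble for curation tests.
seq_batch <- function(seqs, ids = sprintf("s%03d", seq_along(seqs)),
                      source = "synthetic", is_human = FALSE) {
  tibble::tibble(id = ids, seq = seqs, source = source,
                 species = "synthetica_exemplaris",
                 is_human = rep_len(is_human, length(seqs)))
}
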