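#' Per-column amino-acid profile of a repeat alignment
#'
#' Counts the 20 standard amino acids in every alignment column, excluding
#' gaps and `X`, and converts counts to frequencies. A uniform pseudocount can
#' be added before normalisation; keep it at 0 for conservation scoring and
#' use a positive value when the profile feeds the log-odds aligner.
#'
#' @param aln A [repeat_alignment].
#' @param pseudocount Non-negative count added to every amino-acid cell before
#'   frequency normalisation (default 0).
#'
#' @return A `column_profile`: list with `counts` (20 x width matrix),
#'   `frequencies` (same shape; `NA` for empty columns), `occupancy`,
#'   `n_effective` (non-gap, non-X residues per column), `empty_columns`,
#'   `core_columns` and the `pseudocount` used.
#' @export
build_profile <- function(aln, pseudocount = 0) {
  stopifnot(inherits(aln, "repeat_alignment"), pseudocount >= 0)
  mat <- aln_char_matrix(aln$rows)
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(factor(mat[, j], levels = AA20), nbins = 20L)
  }, integer(20))
  dimnames(counts) <- list(AA20, NULL)
  n_eff <- colSums(counts)
  denom <- n_eff + 20 * pseudocount
  freqs <- sweep(counts + pseudocount, 2, denom, "/")
  freqs[, n_eff == 0 & pseudocount == 0] <- NA_real_
  structure(
    list(counts = counts, frequencies = freqs, occupancy = aln$column_occupancy,
         n_effective = n_eff, empty_columns = which(n_eff == 0),
         core_columns = aln$core_columns, pseudocount = pseudocount),
    class = "column_profile"
  )
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> %d columns (%d core), pseudocount %g\n",
              ncol(x$counts), length(x$core_columns), x$pseudocount))
  invisible(x)
}

## Log-odds scoring matrix (bits) over the profile's core columns:
## s(a, j) = log2(p_j(a) / (1/20)) with pseudocounted frequencies.
profile_score_matrix <- function(profile, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  counts <- profile$counts[, profile$core_columns, drop = FALSE]
  denom <- colSums(counts) + 20 * pseudocount
  p <- sweep(counts + pseudocount, 2, denom, "/")
  log2(p / 0.05)
}

#' Align one sequence to a column profile (global affine-gap)
#'
#' Aligns a sequence against the log-odds profile of the core motif columns
#' with affine gap penalties (Gotoh three-state dynamic programming). The
#' alignment is global in the profile; sequence overhangs before the first and
#' after the last core column are free, so terminal extensions are placed at
#' the motif boundary rather than forced inside it. Scores are in bits:
#' residue `a` at column `j` scores `log2(p_j(a)/0.05)` with pseudocounted
#' frequencies.
#'
#' @param seq Amino-acid string (ungapped); `X` scores 0 at every column.
#' @param profile A `column_profile` from [build_profile()].
#' @param gap_open Penalty (bits, negative) for opening a gap. Default -10.
#' @param gap_extend Penalty per additional gap position. Default -0.5.
#' @param pseudocount Pseudocount used for the scoring frequencies (default 1).
#' @param id Optional sequence id carried through to the result.
#'
#' @return A `profile_alignment_row`: list with `id`, `seq`, `row` (the
#'   sequence projected onto the core columns, `-` at deleted columns),
#'   `insertions` (named list of inserted residue runs, names = core column
#'   index after which the run sits, `0` = N-terminal overhang), and
#'   `insertion_flags` — the core columns into which this sequence would force
#'   an insertion (terminal overhangs are never flagged), plus the optimal
#'   `score`.
#' @export
align_to_profile <- function(seq, profile, gap_open = -10, gap_extend = -0.5,
                             pseudocount = 1, id = NA_character_) {
  stopifnot(inherits(profile, "column_profile"))
  seq <- toupper(seq)
  if (nchar(seq) < 3) stop("sequence shorter than 3 residues: ", id)
  if (length(profile$core_columns) < 1) stop("profile has no core columns")
  S <- profile_score_matrix(profile, pseudocount)
  L <- ncol(S)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(chars)
  idx <- match(chars, AA20)          # NA for X -> score 0
  sub <- matrix(0, m, L)
  known <- !is.na(idx)
  sub[known, ] <- S[idx[known], , drop = FALSE]

  NEG <- -1e18
  M  <- matrix(NEG, m + 1, L + 1)   # seq i aligned to column j
  Ix <- matrix(NEG, m + 1, L + 1)   # seq i inserted after column j
  Iy <- matrix(NEG, m + 1, L + 1)   # column j deleted
  M[1, 1] <- 0
  Ix[2:(m + 1), 1] <- 0             # free N-terminal overhang
  if (L >= 1) Iy[1, 2:(L + 1)] <- gap_open + gap_extend * (seq_len(L) - 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(L + 1)) {
      best_prev <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      M[i, j] <- sub[i - 1, j - 1] + best_prev
      Ix[i, j] <- max(M[i - 1, j] + gap_open, Ix[i - 1, j] + gap_extend,
                      Iy[i - 1, j] + gap_open)
      Iy[i, j] <- max(M[i, j - 1] + gap_open, Iy[i, j - 1] + gap_extend,
                      Ix[i, j - 1] + gap_open)
    }
  }
  ## free C-terminal overhang: end at any i with column L consumed
  end_scores <- pmax(M[, L + 1], Iy[, L + 1])
  i_end <- which.max(end_scores)
  score <- end_scores[i_end]
  state <- if (M[i_end, L + 1] >= Iy[i_end, L + 1]) "M" else "Iy"

  ## traceback (preference M > Iy > Ix on ties, fixed and deterministic)
  ops <- character(0)
  i <- i_end; j <- L + 1
  if (i_end <= m) ops <- rep("I", m - i_end + 1)   # trailing overhang
  while (!(i == 1 && j == 1)) {
    if (state == "M") {
      prev <- c(M = M[i - 1, j - 1], Iy = Iy[i - 1, j - 1],
                Ix = Ix[i - 1, j - 1])
      ops <- c("M", ops); i <- i - 1; j <- j - 1
      if (i == 1 && j == 1) break
      state <- names(prev)[which.max(prev)]
    } else if (state == "Iy") {
      cand <- c(M = M[i, j - 1] + gap_open, Iy = Iy[i, j - 1] + gap_extend,
                Ix = Ix[i, j - 1] + gap_open)
      ops <- c("D", ops); j <- j - 1
      state <- names(cand)[which.max(cand)]
    } else {                                        # Ix
      if (j == 1) {                                 # free leading overhang
        ops <- c(rep("I", i - 1), ops); i <- 1
        break
      }
      cand <- c(M = M[i - 1, j] + gap_open, Ix = Ix[i - 1, j] + gap_extend,
                Iy = Iy[i - 1, j] + gap_open)
      ops <- c("I", ops); i <- i - 1
      state <- names(cand)[which.max(cand)]
    }
  }

  row <- character(L)
  insertions <- list()
  ci <- 0L; cj <- 0L
  for (op in ops) {
    if (op == "M") {
      ci <- ci + 1L; cj <- cj + 1L
      row[cj] <- chars[ci]
    } else if (op == "D") {
      cj <- cj + 1L
      row[cj] <- GAP
    } else {
      ci <- ci + 1L
      key <- as.character(cj)
      insertions[[key]] <- paste0(insertions[[key]] %||% "", chars[ci])
    }
  }
  after <- as.integer(names(insertions))
  flags <- sort(after[after >= 1L & after <= L - 1L] + 1L)
  structure(
    list(id = id, seq = seq, row = paste(row, collapse = ""),
         insertions = insertions, insertion_flags = flags, score = score),
    class = "profile_alignment_row"
  )
}

#' @export
print.profile_alignment_row <- function(x, ...) {
  cat(sprintf("<profile_alignment_row> %s score %.2f bits, %d insertion flag(s)\n",
              x$id, x$score, length(x$insertion_flags)))
  invisible(x)
}

align_batch <- function(seqs, profile, ...) {
  lapply(seq_len(nrow(seqs)), function(k) {
    align_to_profile(seqs$seq[k], profile, ..., id = seqs$id[k])
  })
}

#' Identify sequences that introduce gaps in the core columns
#'
#' A sequence "introduces gaps" when its optimal alignment opens an insertion
#' state interior to the core motif block, which would force a gap column into
#' every other row. Terminal overhangs (before the first or after the last
#' core column) do not count.
#'
#' @param aln_batch List of `profile_alignment_row` results aligned to a
#'   common profile.
#' @return Character vector of offending sequence ids.
#' @export
detect_gap_introducers <- function(aln_batch) {
  flagged <- vapply(aln_batch, function(x) length(x$insertion_flags) > 0,
                    logical(1))
  vapply(aln_batch[flagged], `[[`, character(1), "id")
}

## Merge per-sequence alignment results into a single alignment, padding
## insertion runs to a common width per inter-column slot.
merge_aligned_rows <- function(results, meta) {
  L <- nchar(results[[1]]$row)
  ins_width <- integer(L + 1)        # slot k = insertions after core column k
  for (r in results) {
    for (key in names(r$insertions)) {
      k <- as.integer(key) + 1L
      ins_width[k] <- max(ins_width[k], nchar(r$insertions[[key]]))
    }
  }
  pad <- function(s, w) paste0(s, strrep(GAP, w - nchar(s)))
  rows <- vapply(results, function(r) {
    core <- strsplit(r$row, "", fixed = TRUE)[[1]]
    pieces <- character(2L * L + 1L)
    pieces[1] <- pad(r$insertions[["0"]] %||% "", ins_width[1])
    for (j in seq_len(L)) {
      pieces[2 * j] <- core[j]
      pieces[2 * j + 1] <- pad(r$insertions[[as.character(j)]] %||% "",
                               ins_width[j + 1])
    }
    paste(pieces, collapse = "")
  }, character(1))
  extra <- cumsum(c(0L, ins_width[1L + seq_len(L - 1L)]))
  core_cols <- ins_width[1] + seq_len(L) + extra
  repeat_alignment(rows, meta = meta, core_columns = core_cols)
}

#' Staged sequences-to-profile construction of a repeat alignment
#'
#' Builds a curated repeat alignment the way large repeat families are
#' assembled in practice: a seed batch of canonical-length sequences defines
#' the initial core-column profile; sequences that force insertions into the
#' core block are removed, re-aligned once against the updated profile, and
#' removed permanently if they still introduce gaps; the remaining sequence
#' groups are then folded in one group at a time under the same
#' remove/re-align/remove rule, with the profile recomputed after each group.
#' Finally, every removed sequence is aligned to the frozen final profile and
#' appended, so the returned alignment contains all inputs, with insertion
#' columns carrying the gap-introducers' extra residues.
#'
#' @param groups Ordered list of sequence batches; each a tibble with `id`,
#'   `seq`, `source`, `species`, `is_human`.
#' @param seed_batch Seed batch (same tibble shape); all sequences must share
#'   the canonical motif length. Defaults to the first group, which is then
#'   dropped from `groups`.
#' @param gap_open,gap_extend,pseudocount Passed to [align_to_profile()].
#'
#' @return List with `alignment` (a [repeat_alignment] whose `core_columns`
#'   mark the canonical motif), `removed` (tibble `id`, `stage`, `reason`) and
#'   `kept_ids` (ids aligned without core insertions).
#' @export
iterative_build <- function(groups, seed_batch = NULL, gap_open = -10,
                            gap_extend = -0.5, pseudocount = 1) {
  if (is.null(seed_batch)) {
    if (!length(groups)) stop("empty seed batch")
    seed_batch <- groups[[1]]
    groups <- groups[-1]
  }
  seed_batch <- tibble::as_tibble(seed_batch)
  if (!nrow(seed_batch)) stop("empty seed batch")
  len <- unique(nchar(seed_batch$seq))
  if (length(len) != 1L) {
    stop("seed batch sequences must share the canonical length; saw: ",
         paste(len, collapse = ", "))
  }

  all_meta <- dplyr::bind_rows(c(list(seed_batch), groups))[
    , c("id", "source", "species", "is_human")]
  seq_of <- setNames(
    dplyr::bind_rows(c(list(seed_batch), groups))$seq, all_meta$id)

  removed <- tibble::tibble(id = character(), stage = character(),
                            reason = character())
  results <- list()                   # kept profile_alignment_row, by id

  profile_from_results <- function(res) {
    rows <- vapply(res, `[[`, character(1), "row")
    ids <- vapply(res, `[[`, character(1), "id")
    aln <- repeat_alignment(rows, meta = all_meta[match(ids, all_meta$id), ])
    build_profile(aln)
  }

  absorb_batch <- function(batch, profile, stage) {
    res <- align_batch(batch, profile, gap_open = gap_open,
                       gap_extend = gap_extend, pseudocount = pseudocount)
    intro <- detect_gap_introducers(res)
    clean <- res[!vapply(res, function(x) x$id %in% intro, logical(1))]
    if (length(intro)) {
      ## one re-alignment attempt against the profile updated with this
      ## batch's clean sequences, then permanent removal
      prof2 <- profile_from_results(c(results, clean))
      retry <- align_batch(batch[batch$id %in% intro, , drop = FALSE], prof2,
                           gap_open = gap_open, gap_extend = gap_extend,
                           pseudocount = pseudocount)
      persistent <- detect_gap_introducers(retry)
      recovered <- retry[!vapply(retry, function(x) x$id %in% persistent,
                                 logical(1))]
      clean <- c(clean, recovered)
      if (length(persistent)) {
        removed <<- dplyr::bind_rows(removed, tibble::tibble(
          id = persistent, stage = stage,
          reason = "insertion in core columns after re-alignment"))
      }
    }
    results <<- c(results, clean)
  }

  ## stage 1: seed batch aligned against its own ungapped block profile
  seed_aln <- repeat_alignment(seed_batch$seq,
                               meta = seed_batch[, c("id", "source", "species",
                                                     "is_human")])
  seed_profile <- build_profile(seed_aln)
  absorb_batch(seed_batch, seed_profile, stage = "seed")

  ## stage 2: remaining groups in order, profile recomputed after each
  for (g in seq_along(groups)) {
    profile <- profile_from_results(results)
    absorb_batch(tibble::as_tibble(groups[[g]]), profile,
                 stage = sprintf("group_%d", g))
  }

  kept_ids <- vapply(results, `[[`, character(1), "id")

  ## stage 3: re-append removed sequences against the frozen final profile
  final_profile <- profile_from_results(results)
  if (nrow(removed)) {
    rb <- tibble::tibble(id = removed$id, seq = unname(seq_of[removed$id]))
    re <- align_batch(rb, final_profile, gap_open = gap_open,
                      gap_extend = gap_extend, pseudocount = pseudocount)
    results <- c(results, re)
  }

  ids <- vapply(results, `[[`, character(1), "id")
  aln <- merge_aligned_rows(results, all_meta[match(ids, all_meta$id), ])
  list(alignment = aln, removed = removed, kept_ids = kept_ids)
}

#' Filter alignment columns by occupancy
#'
#' Keeps columns whose occupancy (fraction of non-gap rows) is strictly
#' greater than the threshold; the customary cut for display and scoring of
#' large repeat alignments is 0.5%.
#'
#' @param aln A [repeat_alignment], or a bare numeric occupancy vector.
#' @param min_occupancy Strict lower bound on occupancy (default 0.005).
#' @return Ordered integer vector of surviving column indices.
#' @export
filter_columns_by_occupancy <- function(aln, min_occupancy = 0.005) {
  occ <- if (inherits(aln, "repeat_alignment")) aln$column_occupancy else aln
  which(occ > min_occupancy)
}

#' Write the removal log of a staged alignment build
#'
#' @param removed Tibble `id`, `stage`, `reason` from [iterative_build()].
#' @param path Output TSV path.
#' @export
write_removal_log <- function(removed, path) {
  readr::write_tsv(removed, path)
  invisible(path)
}
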