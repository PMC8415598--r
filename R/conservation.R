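#' Shannon entropy of an amino-acid frequency vector
#'
#' Entropy in bits over the 20 standard amino-acid types,
#' `S = -sum_i p_i log2 p_i`, with zero frequencies contributing zero. A fully
#' conserved column has `S = 0`; a column with all 20 amino acids at 1/20 has
#' `S = log2(20) ~ 4.32` bits.
#'
#' @param frequencies Numeric vector of length 20 summing to 1 (tolerance
#'   1e-6); zeros allowed.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(frequencies) {
  stopifnot(length(frequencies) == 20L)
  if (any(frequencies < 0)) stop("negative frequencies")
  if (abs(sum(frequencies) - 1) > 1e-6) {
    stop("frequencies must sum to 1 over the 20 amino-acid types")
  }
  p <- frequencies[frequencies > 0]
  -sum(p * log2(p))
}

#' Shenkin divergence score of an alignment column
#'
#' `V_Shenkin = 2^S * 6`, where `S` is the Shannon entropy (bits) of the
#' column's gap-excluded amino-acid frequencies. The score runs from 6 for a
#' fully conserved column to `2^log2(20) * 6 = 120` for a column with all 20
#' amino acids equally frequent; low values mean high conservation.
#'
#' @param column_counts Integer vector of length 20: amino-acid counts for the
#'   column (gaps and `X` already excluded).
#' @return The Shenkin score (dimensionless, in `[6, 120]`).
#' @export
shenkin_score <- function(column_counts) {
  stopifnot(length(column_counts) == 20L, all(column_counts >= 0))
  n <- sum(column_counts)
  if (n == 0) stop("empty column: Shenkin score undefined")
  2^shannon_entropy(column_counts / n) * 6
}

#' Normalise Shenkin scores to 0-100
#'
#' Min-max normalisation of per-column Shenkin scores. By default the anchors
#' are the most conserved and most divergent columns of this alignment, so the
#' extremes map exactly to 0 and 100; theoretical anchoring against the
#' attainable limits 6 and 120 is available for cross-alignment comparison.
#'
#' @param scores Numeric vector of per-column Shenkin scores (`NA` allowed for
#'   unscored columns).
#' @param anchors `"empirical"` (default; this alignment's min/max columns) or
#'   `"theoretical"` (6 and 120).
#' @return Numeric vector of normalised scores in `[0, 100]`.
#' @export
normalize_shenkin <- function(scores, anchors = c("empirical", "theoretical")) {
  anchors <- match.arg(anchors)
  ok <- !is.na(scores)
  if (anchors == "empirical") {
    if (sum(ok) < 2 || diff(range(scores[ok])) == 0) {
      stop("empirical normalisation needs >= 2 scored columns with distinct values")
    }
    lo <- min(scores[ok]); hi <- max(scores[ok])
  } else {
    lo <- 6; hi <- 2^log2(20) * 6
  }
  (scores - lo) / (hi - lo) * 100
}

#' Per-column divergence table of a repeat alignment
#'
#' Computes Shannon entropy, the Shenkin score and its 0-100 normalisation for
#' every core motif column. Gaps and `X` are excluded from the frequency
#' vectors; empty columns are reported with `NA` scores and do not contribute
#' normalisation anchors.
#'
#' @param aln A [repeat_alignment] (or a precomputed `column_profile` built
#'   with pseudocount 0).
#' @param anchors Passed to [normalize_shenkin()].
#' @return Tibble with `position` (motif position 1..length(core)),
#'   `n_effective`, `shannon`, `v_shenkin`, `n_shenkin`.
#' @export
column_divergence <- function(aln, anchors = c("empirical", "theoretical")) {
  profile <- if (inherits(aln, "column_profile")) aln else build_profile(aln)
  if (profile$pseudocount != 0) {
    stop("divergence scoring requires a pseudocount-free profile")
  }
  counts <- profile$counts[, profile$core_columns, drop = FALSE]
  n_eff <- colSums(counts)
  v <- vapply(seq_len(ncol(counts)), function(j) {
    if (n_eff[j] == 0) NA_real_ else shenkin_score(counts[, j])
  }, numeric(1))
  s <- ifelse(is.na(v), NA_real_, log2(v / 6))
  tibble::tibble(
    position = seq_len(ncol(counts)),
    n_effective = as.integer(n_eff),
    shannon = s,
    v_shenkin = v,
    n_shenkin = normalize_shenkin(v, anchors)
  )
}
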