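#' Enrichment score from a column-versus-rest 2x2 table
#'
#' Shared machinery behind the missense enrichment score (MES), the
#' protein-protein interaction enrichment score (PPIES) and intra-repeat
#' contact enrichment. Given event count `a` out of `b` trials in the focal
#' scope and `c` out of `d` in the comparison scope, the score is the natural
#' log of the ratio `(a/b) / (c/d)`. The 95% confidence interval uses the
#' normal approximation on the log scale (Katz method,
#' `SE = sqrt(1/a - 1/b + 1/c - 1/d)`); the p-value is a two-sided Fisher
#' exact test on the table `(a, b-a, c, d-c)`. When any cell of that table is
#' zero, a Haldane-Anscombe correction (+0.5 per cell) is applied to the ratio
#' and interval so the score stays finite; the p-value is computed on the
#' uncorrected table.
#'
#' @param a Events in the focal scope (e.g. missense variant sites at a
#'   column).
#' @param b Trials in the focal scope (e.g. human residues at the column);
#'   requires `b >= a`.
#' @param c Events in the comparison scope.
#' @param d Trials in the comparison scope; requires `d >= c`.
#' @param scope Label carried into the result.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return One-row tibble: `scope`, `a`, `b`, `c`, `d`, `or` (the rate ratio),
#'   `score` (= `ln(or)`), `ci_low`, `ci_high`, `p`.
#' @export
enrichment_from_counts <- function(a, b, c, d, scope = NA_character_,
                                   conf_level = 0.95) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  if (b - a < 0) stop("more events than trials in focal scope (a > b)")
  if (d - c < 0) stop("more events than trials in comparison scope (c > d)")
  cells <- c(a, b - a, c, d - c)
  if (any(cells == 0)) {
    a2 <- a + 0.5; b2 <- b + 1; c2 <- c + 0.5; d2 <- d + 1
  } else {
    a2 <- a; b2 <- b; c2 <- c; d2 <- d
  }
  or <- (a2 / b2) / (c2 / d2)
  se <- sqrt(1 / a2 - 1 / b2 + 1 / c2 - 1 / d2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- fisher.test(matrix(round(cells), nrow = 2))$p.value
  tibble::tibble(
    scope = as.character(scope), a = a, b = b, c = c, d = d,
    or = or, score = log(or),
    ci_low = log(or) - z * se, ci_high = log(or) + z * se, p = p
  )
}

#' Aggregate missense variants over alignment columns
#'
#' Maps each missense variant of a human sequence onto the alignment column
#' its residue occupies (via the aligned row, so insertions elsewhere in the
#' sequence cannot shift the mapping) and counts variant sites per column.
#' Multiple distinct variants at one residue count once (site-count mode);
#' allele counts are ignored here. Human occupancy per column counts non-gap
#' residues of human rows and is the denominator of the enrichment scores.
#'
#' @param variants Variant tibble: `sequence_id`, `residue_position` (1-based
#'   in the ungapped sequence), `ref_aa`, `alt_aa`, `consequence`
#'   (`missense` / `synonymous` / `other`), `allele_count`. Non-missense rows
#'   are retained in the input but never counted.
#' @param aln A [repeat_alignment]; every variant's `sequence_id` must be a
#'   human row.
#' @param check_ref Verify that `ref_aa` matches the aligned sequence at the
#'   variant position (default TRUE).
#'
#' @return Tibble with one row per alignment column: `column`, `ank_position`
#'   (motif position for core columns, `NA` for insertion columns),
#'   `missense_count`, `human_occupancy`.
#' @export
map_variants_to_columns <- function(variants, aln, check_ref = TRUE) {
  stopifnot(inherits(aln, "repeat_alignment"))
  variants <- tibble::as_tibble(variants)
  human <- aln$meta$is_human
  if (!any(human)) stop("alignment has no human sequences")
  hum_ids <- aln$meta$id[human]
  unknown <- setdiff(unique(variants$sequence_id), hum_ids)
  if (length(unknown)) {
    stop("variants reference non-human or unknown sequences: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  row_of <- setNames(aln$rows[human], hum_ids)
  colmap <- lapply(row_of, residue_columns)

  lens <- lengths(colmap)[variants$sequence_id]
  bad <- variants$residue_position < 1 | variants$residue_position > lens
  if (any(bad)) {
    stop("variant positions beyond sequence length: ",
         paste(sprintf("%s:%d", variants$sequence_id[bad],
                       variants$residue_position[bad])[seq_len(min(5, sum(bad)))],
               collapse = ", "))
  }
  col_idx <- if (nrow(variants)) {
    mapply(function(id, pos) colmap[[id]][pos],
           variants$sequence_id, variants$residue_position,
           USE.NAMES = FALSE)
  } else integer(0)
  if (check_ref && nrow(variants)) {
    ref_obs <- substring(row_of[variants$sequence_id], col_idx, col_idx)
    mism <- ref_obs != toupper(variants$ref_aa)
    if (any(mism)) {
      stop("ref_aa does not match the sequence for: ",
           paste(sprintf("%s:%d", variants$sequence_id[mism],
                         variants$residue_position[mism])[seq_len(min(5, sum(mism)))],
                 collapse = ", "))
    }
  }

  w <- aln_width(aln)
  mis <- variants$consequence == "missense"
  sites <- unique(tibble::tibble(col = col_idx[mis],
                                 id = variants$sequence_id[mis],
                                 pos = variants$residue_position[mis]))
  counts <- tabulate(sites$col, nbins = w)
  occ <- colSums(aln_char_matrix(aln$rows[human]) != GAP)
  ank <- rep(NA_integer_, w)
  ank[aln$core_columns] <- seq_along(aln$core_columns)
  tibble::tibble(column = seq_len(w), ank_position = ank,
                 missense_count = counts, human_occupancy = as.integer(occ))
}

#' Missense enrichment score of one motif column
#'
#' Builds the 2x2 table for a core column against the pooled remaining core
#' columns — `a` = missense variant sites at the column, `b` = human residues
#' at the column, `c`/`d` the same summed over all other core columns — and
#' scores it with [enrichment_from_counts()]. Insertion columns never enter
#' the table.
#'
#' @param col Motif position (1-based index into the core columns).
#' @param column_counts Tibble from [map_variants_to_columns()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble as in [enrichment_from_counts()], `scope` set to the
#'   position.
#' @export
column_mes <- function(col, column_counts, conf_level = 0.95) {
  core <- dplyr::filter(column_counts, !is.na(.data$ank_position))
  row <- core[core$ank_position == col, ]
  if (nrow(row) != 1L) stop("no core column at motif position ", col)
  if (row$human_occupancy < 1) stop("motif position ", col, " has no human residues")
  rest <- core[core$ank_position != col, ]
  enrichment_from_counts(
    a = row$missense_count, b = row$human_occupancy,
    c = sum(rest$missense_count), d = sum(rest$human_occupancy),
    scope = as.character(col), conf_level = conf_level
  )
}

#' @rdname column_mes
#' @param column_counts Tibble from [map_variants_to_columns()].
#' @param adjust Add a Benjamini-Hochberg adjusted column `q` (default TRUE);
#'   per-column reporting itself is unadjusted.
#' @return `mes_per_column()`: one row per core column with `position` plus
#'   the [enrichment_from_counts()] fields (and `q`).
#' @export
mes_per_column <- function(column_counts, conf_level = 0.95, adjust = TRUE) {
  core <- dplyr::filter(column_counts, !is.na(.data$ank_position))
  out <- dplyr::bind_rows(lapply(core$ank_position, column_mes,
                                 column_counts = column_counts,
                                 conf_level = conf_level))
  out <- dplyr::mutate(out, position = as.integer(.data$scope),
                       .before = "scope")
  out$scope <- NULL
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Missense enrichment score of a column group
#'
#' Pools counts within two disjoint sets of motif positions and scores set A
#' against set B (or against all remaining core columns when B is omitted) —
#' used e.g. for buried-versus-surface or per-surface comparisons.
#'
#' @param set_a,set_b Integer vectors of motif positions; disjoint,
#'   non-empty. `set_b = NULL` means "all other core columns".
#' @inheritParams column_mes
#' @return One-row tibble as in [enrichment_from_counts()].
#' @export
group_mes <- function(set_a, set_b = NULL, column_counts, conf_level = 0.95) {
  core <- dplyr::filter(column_counts, !is.na(.data$ank_position))
  if (!length(set_a)) stop("set_a is empty")
  if (!all(set_a %in% core$ank_position)) stop("set_a has unknown positions")
  if (is.null(set_b)) set_b <- setdiff(core$ank_position, set_a)
  if (!length(set_b)) stop("set_b is empty")
  if (length(intersect(set_a, set_b))) stop("column sets overlap")
  pa <- core[core$ank_position %in% set_a, ]
  pb <- core[core$ank_position %in% set_b, ]
  enrichment_from_counts(
    a = sum(pa$missense_count), b = sum(pa$human_occupancy),
    c = sum(pb$missense_count), d = sum(pb$human_occupancy),
    scope = paste0("{", paste(set_a, collapse = ","), "} vs {",
                   paste(set_b, collapse = ","), "}"),
    conf_level = conf_level
  )
}

#' Read a missense variant table
#'
#' Tab-separated with `#` comment lines; expected columns `sequence_id`,
#' `residue_position`, `ref_aa`, `alt_aa`, `consequence`, `allele_count`.
#'
#' @param path TSV path.
#' @return Variant tibble.
#' @export
read_variant_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           sequence_id = readr::col_character(),
                           residue_position = readr::col_integer(),
                           ref_aa = readr::col_character(),
                           alt_aa = readr::col_character(),
                           consequence = readr::col_character(),
                           allele_count = readr::col_integer()))
  if (any(out$allele_count < 1)) stop("allele_count must be >= 1")
  out
}
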