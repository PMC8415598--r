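#' Repeat multiple sequence alignment container
#'
#' `repeat_alignment()` bundles aligned rows, per-row metadata and the indices
#' of the core motif columns (for ankyrin repeats, the 33 canonical positions)
#' into a light S3 object used throughout the package. Columns outside
#' `core_columns` represent insertions relative to the motif.
#'
#' @param rows Character vector of aligned sequences of equal width; gaps are
#'   `"-"`.
#' @param meta Tibble with one row per sequence: `id`, `source`, `species`,
#'   `is_human`. A minimal default is created when omitted.
#' @param core_columns Integer indices of the core motif columns, in motif
#'   order. Defaults to every column.
#'
#' @return An object of class `repeat_alignment` with elements `rows`, `meta`,
#'   `core_columns` and `column_occupancy` (fraction of non-gap rows per
#'   column).
#' @export
repeat_alignment <- function(rows, meta = NULL, core_columns = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  widths <- unique(nchar(rows))
  if (length(widths) != 1L) {
    stop("all aligned rows must have equal width; saw widths: ",
         paste(widths, collapse = ", "))
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(
      id = names(rows) %||% sprintf("seq_%04d", seq_along(rows)),
      source = "unknown", species = "unknown", is_human = FALSE
    )
  }
  meta <- tibble::as_tibble(meta)
  stopifnot(nrow(meta) == length(rows),
            all(c("id", "source", "species", "is_human") %in% names(meta)))
  if (anyDuplicated(meta$id)) stop("duplicated sequence ids in alignment")
  core_columns <- as.integer(core_columns %||% seq_len(widths))
  stopifnot(all(core_columns >= 1L), all(core_columns <= widths),
            !is.unsorted(core_columns), !anyDuplicated(core_columns))
  rows <- unname(toupper(rows))
  bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "X-]*$"), rows)
  if (any(bad)) {
    stop("rows contain characters outside the amino-acid alphabet (+X, '-'): ",
         paste(meta$id[bad], collapse = ", "))
  }
  mat <- aln_char_matrix(rows)
  occ <- colMeans(mat != GAP)
  structure(
    list(rows = rows, meta = meta, core_columns = core_columns,
         column_occupancy = occ),
    class = "repeat_alignment"
  )
}

aln_char_matrix <- function(rows) {
  matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(rows), byrow = TRUE)
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf(
    "<repeat_alignment> %d sequences x %d columns (%d core), %d human\n",
    length(x$rows), nchar(x$rows[1]), length(x$core_columns),
    sum(x$meta$is_human)))
  invisible(x)
}

#' @rdname repeat_alignment
#' @param aln A `repeat_alignment`.
#' @export
aln_width <- function(aln) nchar(aln$rows[1])

#' @rdname repeat_alignment
#' @export
n_sequences <- function(aln) length(aln$rows)

#' Remove gap characters from aligned rows
#'
#' De-gapping an aligned row recovers the original input sequence exactly
#' (round-trip property used throughout the curation tests).
#'
#' @param x Character vector of aligned rows.
#' @return Character vector of ungapped sequences.
#' @export
degap <- function(x) gsub(GAP, "", x, fixed = TRUE)

#' Map residue numbers to alignment columns for one row
#'
#' Residue `k` of the ungapped sequence sits at the column of the k-th non-gap
#' character of its aligned row.
#'
#' @param row One aligned row (character scalar).
#' @return Integer vector: element `k` is the alignment column of residue `k`.
#' @export
residue_columns <- function(row) {
  which(strsplit(row, "", fixed = TRUE)[[1]] != GAP)
}

## ---- FASTA / Stockholm I/O -------------------------------------------------

meta_to_header <- function(meta) {
  sprintf("%s source=%s species=%s is_human=%s",
          meta$id, meta$source, gsub(" ", "_", meta$species),
          ifelse(meta$is_human, "yes", "no"))
}

header_to_meta <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  grab <- function(key, default) {
    m <- stringr::str_match(headers, paste0(key, "=([^\\s]+)"))[, 2]
    ifelse(is.na(m), default, m)
  }
  tibble::tibble(
    id = id,
    source = grab("source", "unknown"),
    species = grab("species", "unknown"),
    is_human = grab("is_human", "no") == "yes"
  )
}

#' Read and write repeat alignments and sequence sets as FASTA
#'
#' Sequence metadata travels in the FASTA header as `key=value` pairs
#' (`source=`, `species=`, `is_human=yes|no`). `read_repeat_fasta()` accepts
#' both aligned (gapped) and unaligned files.
#'
#' @param path File path.
#' @param core_columns Optional core-column indices to attach on read; default
#'   all columns (aligned input) or none (unaligned input).
#' @return `read_repeat_fasta()` returns a tibble `id, seq, source, species,
#'   is_human` when sequences are unaligned (unequal widths or gap-free), or a
#'   [repeat_alignment] when rows share a common width and contain gaps.
#' @export
read_repeat_fasta <- function(path, core_columns = NULL) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  meta <- header_to_meta(headers)
  tbl <- tibble::tibble(id = meta$id, seq = unname(seqs)) |>
    dplyr::bind_cols(meta[, c("source", "species", "is_human")])
  widths <- unique(nchar(tbl$seq))
  if (length(widths) == 1L && any(grepl(GAP, tbl$seq, fixed = TRUE))) {
    return(repeat_alignment(tbl$seq, meta = meta, core_columns = core_columns))
  }
  tbl
}

#' @rdname read_repeat_fasta
#' @param aln A [repeat_alignment] (or tibble with `id`, `seq` + metadata for
#'   unaligned output).
#' @export
write_repeat_fasta <- function(aln, path) {
  if (inherits(aln, "repeat_alignment")) {
    seqs <- aln$rows
    headers <- meta_to_header(aln$meta)
  } else {
    seqs <- aln$seq
    headers <- meta_to_header(aln)
  }
  set <- Biostrings::BStringSet(setNames(seqs, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a repeat alignment in Stockholm 1.0 format
#'
#' Emits a minimal single-block Stockholm file with `#=GS` description lines
#' carrying the per-sequence metadata and a `#=GC RF` line marking core motif
#' columns with `x` and insertion columns with `.`.
#'
#' @param aln A [repeat_alignment].
#' @param path Output file path.
#' @export
write_stockholm <- function(aln, path) {
  stopifnot(inherits(aln, "repeat_alignment"))
  idw <- max(nchar(aln$meta$id), nchar("#=GC RF"))
  pad <- function(x) formatC(x, width = idw, flag = "-")
  rf <- rep(".", aln_width(aln))
  rf[aln$core_columns] <- "x"
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf("#=GS %s DE source=%s species=%s is_human=%s",
            aln$meta$id, aln$meta$source, gsub(" ", "_", aln$meta$species),
            ifelse(aln$meta$is_human, "yes", "no")),
    paste(pad(aln$meta$id), gsub("-", ".", aln$rows, fixed = TRUE)),
    paste(pad("#=GC RF"), paste(rf, collapse = "")),
    "//"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stockholm
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  seq_lines <- lines[!grepl("^(#|//)", lines) & nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(seq_lines), "\\s+", 2)
  rows <- tapply(parts[, 2], factor(parts[, 1], levels = unique(parts[, 1])),
                 paste, collapse = "")
  rows <- gsub("[.]", "-", toupper(rows))
  gs <- lines[grepl("^#=GS ", lines)]
  meta <- NULL
  if (length(gs)) {
    gsp <- stringr::str_match(gs, "^#=GS\\s+(\\S+)\\s+DE\\s+(.*)$")
    meta <- header_to_meta(paste(gsp[, 2], gsp[, 3]))
    meta <- meta[match(names(rows), meta$id), ]
  }
  rf_line <- lines[grepl("^#=GC RF", lines)]
  core <- NULL
  if (length(rf_line)) {
    rf <- paste(stringr::str_split_fixed(trimws(rf_line), "\\s+", 3)[, 3],
                collapse = "")
    core <- which(strsplit(rf, "")[[1]] == "x")
  }
  repeat_alignment(as.character(rows),
                   meta = meta, core_columns = core)
}
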