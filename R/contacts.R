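#' Intra-repeat contact map of the motif
#'
#' Builds the symmetric position-by-position contact map across structural
#' repeats. Contact evidence is binary per repeat: `c[i, j]` counts the
#' repeats with at least one atomic contact between motif positions `i` and
#' `j`, and `o[i, j]` counts the repeats where both positions are structurally
#' resolved, so `c/o` is the proportion of repeats with observed contact.
#' Contacts whose endpoints are not both in the coverage table are ignored,
#' which keeps `c <= o` even on imperfect inputs.
#'
#' @param contacts Contact tibble restricted (internally) to
#'   `partner_class == "intra_repeat"`; needs `repeat_id`, `ank_position_a`,
#'   `ank_position_b`.
#' @param coverage Tibble of resolved residues: `repeat_id`, `ank_position`
#'   (typically the quality-filtered structure table).
#' @param n_positions Motif length (default 33).
#' @return A `contact_map`: list with matrices `c` and `o` and
#'   `n_positions`.
#' @export
build_intra_map <- function(contacts, coverage, n_positions = 33L) {
  contacts <- dplyr::filter(tibble::as_tibble(contacts),
                            .data$partner_class == "intra_repeat")
  coverage <- tibble::as_tibble(coverage)
  posns <- c(contacts$ank_position_a, contacts$ank_position_b,
             coverage$ank_position)
  if (any(posns < 1 | posns > n_positions, na.rm = TRUE)) {
    stop("motif positions outside 1..", n_positions)
  }
  cmat <- matrix(0L, n_positions, n_positions)
  omat <- matrix(0L, n_positions, n_positions)

  cov_by_rep <- split(coverage$ank_position, coverage$repeat_id)
  for (pos in cov_by_rep) {
    z <- integer(n_positions)
    z[unique(pos)] <- 1L
    omat <- omat + z %o% z
  }
  if (nrow(contacts)) {
    pairs <- unique(tibble::tibble(
      rep = contacts$repeat_id,
      i = pmin(contacts$ank_position_a, contacts$ank_position_b),
      j = pmax(contacts$ank_position_a, contacts$ank_position_b)
    ))
    cov_key <- paste(coverage$repeat_id, coverage$ank_position)
    covered <- paste(pairs$rep, pairs$i) %in% cov_key &
      paste(pairs$rep, pairs$j) %in% cov_key
    pairs <- pairs[covered & pairs$i != pairs$j, , drop = FALSE]
    upper <- tabulate((pairs$j - 1L) * n_positions + pairs$i,
                      nbins = n_positions^2)
    cmat <- matrix(upper, n_positions, n_positions)
    cmat <- cmat + t(cmat)
  }
  diag(cmat) <- 0L
  structure(list(c = cmat, o = omat, n_positions = n_positions),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d positions, %d pair observations, max coverage %d\n",
              x$n_positions, sum(x$c[upper.tri(x$c)]), max(x$o)))
  invisible(x)
}

#' @rdname build_intra_map
#' @param map A `contact_map`.
#' @return `normalized_map()`: matrix of contact proportions `c/o` (`NA`
#'   where a pair was never co-resolved).
#' @export
normalized_map <- function(map) {
  out <- map$c / map$o
  out[map$o == 0] <- NA_real_
  out
}

#' Remove short-range contacts from a contact map
#'
#' Zeroes both the contact and the coverage entries of position pairs within
#' `min_separation` residues of each other, keeping only pairs with
#' `|i - j| >= min_separation + 1` — the long-range contacts relevant to the
#' fold (helix-helix packing) rather than trivial neighbours. With the
#' default 6, 351 of the 528 position pairs of a 33-position motif survive.
#'
#' @param map A `contact_map`.
#' @param min_separation Pairs with `|i - j| <=` this are removed (default 6).
#' @return The filtered `contact_map`.
#' @export
filter_short_range <- function(map, min_separation = 6L) {
  sep <- abs(row(map$c) - col(map$c))
  drop <- sep <= min_separation
  map$c[drop] <- 0L
  map$o[drop] <- 0L
  map
}

#' Per-position enrichment in intra-repeat contacts
#'
#' For each motif position `i`, sums contact evidence `C_i = sum_j c[i, j]`
#' and coverage `O_i = sum_j o[i, j]` over the (already short-range filtered)
#' map, forms the motif totals `C_t`/`O_t`, and scores position versus rest
#' with the shared ratio machinery: `(C_i/O_i) / ((C_t - C_i)/(O_t - O_i))`.
#' Positions with zero coverage are reported unscored (`NA` row).
#'
#' @param map A `contact_map`, short-range filtered.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with one row per position: `position` plus the
#'   [enrichment_from_counts()] fields.
#' @export
contact_enrichment <- function(map, conf_level = 0.95) {
  Ci <- rowSums(map$c)
  Oi <- rowSums(map$o)
  Ct <- sum(Ci); Ot <- sum(Oi)
  dplyr::bind_rows(lapply(seq_len(map$n_positions), function(i) {
    if (Oi[i] == 0) {
      return(tibble::tibble(position = i, a = Ci[i], b = Oi[i],
                            c = Ct - Ci[i], d = Ot - Oi[i],
                            or = NA_real_, score = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_))
    }
    out <- enrichment_from_counts(Ci[i], Oi[i], Ct - Ci[i], Ot - Oi[i],
                                  scope = as.character(i),
                                  conf_level = conf_level)
    dplyr::mutate(out, position = i, .before = "scope") |>
      dplyr::select(-"scope")
  }))
}

#' Binary substrate-contact evidence per motif position
#'
#' A repeat instance provides evidence of substrate contact at position `i`
#' if at least one inter-atomic contact links that position to the substrate
#' in at least one structure. Coverage is restricted to repeats of
#' substrate-bound structures: `n_i` counts repeat instances resolved at
#' position `i` in structures that present a substrate interaction.
#'
#' @param contacts Contact tibble; rows with
#'   `partner_class == "substrate"` carry the evidence. Needs
#'   `structure_id`, `repeat_id`, `ank_position_a`.
#' @param coverage Resolved-residue tibble: `structure_id`, `repeat_id`,
#'   `ank_position`.
#' @param bound_structures Character vector of substrate-bound structure ids;
#'   defaults to every structure with at least one substrate contact row.
#' @param n_positions Motif length (default 33).
#' @return Tibble `ank_position`, `a` (repeat instances with evidence), `n`
#'   (repeat instances resolved in bound structures).
#' @export
ppi_evidence <- function(contacts, coverage, bound_structures = NULL,
                         n_positions = 33L) {
  contacts <- dplyr::filter(tibble::as_tibble(contacts),
                            .data$partner_class == "substrate")
  coverage <- tibble::as_tibble(coverage)
  if (is.null(bound_structures)) {
    bound_structures <- unique(contacts$structure_id)
  }
  cov_b <- coverage[coverage$structure_id %in% bound_structures, ]
  n_i <- tabulate(
    unique(cov_b[c("structure_id", "repeat_id", "ank_position")])$ank_position,
    nbins = n_positions)
  ev <- unique(contacts[c("structure_id", "repeat_id", "ank_position_a")])
  ## evidence only counts where the residue itself is in the coverage set,
  ## so a_i <= n_i holds even when quality filtering removed the residue
  ev <- dplyr::semi_join(
    ev, cov_b, by = c("structure_id", "repeat_id",
                      "ank_position_a" = "ank_position"))
  a_i <- tabulate(ev$ank_position_a, nbins = n_positions)
  tibble::tibble(ank_position = seq_len(n_positions), a = a_i, n = n_i)
}

#' Protein-protein interaction enrichment score (PPIES)
#'
#' Scores enrichment in substrate contacts per motif position
#' (column-versus-rest) or between groups of positions, reusing the shared
#' ratio machinery on the binary evidence counts of [ppi_evidence()].
#'
#' @param evidence Tibble from [ppi_evidence()].
#' @param set_a,set_b Optional position groups (as in [group_mes()]); when
#'   `set_a` is `NULL` every position is scored against the rest.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of enrichment rows (one per position, or a single group
#'   row).
#' @export
ppies <- function(evidence, set_a = NULL, set_b = NULL, conf_level = 0.95) {
  if (sum(evidence$n) == 0) stop("no coverage in substrate-bound structures")
  if (is.null(set_a)) {
    return(dplyr::bind_rows(lapply(evidence$ank_position, function(i) {
      row <- evidence[evidence$ank_position == i, ]
      rest <- evidence[evidence$ank_position != i, ]
      out <- enrichment_from_counts(row$a, row$n, sum(rest$a), sum(rest$n),
                                    scope = as.character(i),
                                    conf_level = conf_level)
      dplyr::mutate(out, position = i, .before = "scope") |>
        dplyr::select(-"scope")
    })))
  }
  if (!length(set_a)) stop("set_a is empty")
  if (is.null(set_b)) set_b <- setdiff(evidence$ank_position, set_a)
  if (length(intersect(set_a, set_b))) stop("column sets overlap")
  pa <- evidence[evidence$ank_position %in% set_a, ]
  pb <- evidence[evidence$ank_position %in% set_b, ]
  enrichment_from_counts(sum(pa$a), sum(pa$n), sum(pb$a), sum(pb$n),
                         scope = paste0("{", paste(set_a, collapse = ","),
                                        "} vs {",
                                        paste(set_b, collapse = ","), "}"),
                         conf_level = conf_level)
}

#' Per-protein substrate binding mode
#'
#' Classifies which face of the repeat domain dominates substrate binding.
#' Proteins with fewer than `min_repeats` distinct repeats or `min_residues`
#' distinct residues in substrate contact are not evaluated. Otherwise the
#' binding residues are mapped to surfaces and the mode is the surface
#' (concave, convex or basal) holding at least `tau` of them, or `"mixed"`
#' when none dominates; core positions count as buried and can only
#' contribute to a mixed call.
#'
#' @param binding Tibble of substrate-binding residues: `protein_id`,
#'   `repeat_id`, `ank_position`.
#' @param surface_map Position-to-surface tibble; default [ank_surface_map()].
#' @param tau Dominance threshold on the binding-residue fraction (default
#'   2/3).
#' @param min_repeats,min_residues Evaluation minima (defaults 2 and 4).
#' @return Tibble with one row per protein: `protein_id`,
#'   `n_binding_repeats`, `n_binding_residues`, `frac_concave`, `frac_convex`,
#'   `frac_basal`, `frac_buried`, `mode`.
#' @export
binding_mode <- function(binding, surface_map = ank_surface_map(), tau = 2 / 3,
                         min_repeats = 2L, min_residues = 4L) {
  binding <- unique(tibble::as_tibble(binding)[
    c("protein_id", "repeat_id", "ank_position")])
  surf_of <- setNames(surface_map$surface, surface_map$position)
  dplyr::bind_rows(lapply(split(binding, binding$protein_id), function(b) {
    n_rep <- dplyr::n_distinct(b$repeat_id)
    n_res <- nrow(b)
    surf <- surf_of[as.character(b$ank_position)]
    surf[surf == "core"] <- "buried"
    frac <- tabulate(factor(surf, levels = c("concave", "convex", "basal",
                                             "buried")), nbins = 4) / n_res
    mode <- if (n_rep < min_repeats || n_res < min_residues) {
      "not_evaluated"
    } else {
      dom <- which(frac[1:3] >= tau)
      if (length(dom)) c("concave", "convex", "basal")[dom[1]] else "mixed"
    }
    tibble::tibble(protein_id = b$protein_id[1], n_binding_repeats = n_rep,
                   n_binding_residues = n_res,
                   frac_concave = frac[1], frac_convex = frac[2],
                   frac_basal = frac[3], frac_buried = frac[4], mode = mode)
  }))
}

#' Read / write contact tables and contact maps
#'
#' The contact TSV carries Arpeggio-style residue-level contact records:
#' `structure_id`, `repeat_id`, `ank_position_a`, `partner_class`
#' (`intra_repeat` / `inter_repeat` / `substrate`), `ank_position_b` (empty
#' for substrate rows), `partner_id`, `interaction_type`, `distance`. The
#' reader validates the upstream atomic distance cutoff rather than
#' recomputing geometry.
#'
#' @param path TSV path.
#' @param max_distance Distance cutoff (Angstrom) the producer applied
#'   (default 5).
#' @return Contact tibble.
#' @export
read_contact_tsv <- function(path, max_distance = 5) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("structure_id", "repeat_id", "ank_position_a", "partner_class",
            "ank_position_b", "partner_id", "interaction_type", "distance")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("contact table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(out$distance > max_distance)) {
    stop("contact distances exceed the ", max_distance, " A cutoff")
  }
  intra <- out$partner_class %in% c("intra_repeat", "inter_repeat")
  if (any(intra & is.na(out$ank_position_b))) {
    stop("intra/inter-repeat contacts need both motif positions")
  }
  out
}

#' @rdname read_contact_tsv
#' @param map A `contact_map`.
#' @export
write_contact_map_tsv <- function(map, path) {
  n <- map$n_positions
  idx <- which(upper.tri(matrix(0, n, n), diag = FALSE), arr.ind = TRUE)
  tbl <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                        c = map$c[idx], o = map$o[idx],
                        fraction = ifelse(map$o[idx] > 0,
                                          map$c[idx] / map$o[idx], NA_real_))
  readr::write_tsv(dplyr::arrange(tbl, .data$i, .data$j), path)
  invisible(path)
}
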