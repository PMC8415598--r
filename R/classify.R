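#' Conserved/unconserved x depleted/enriched column taxonomy
#'
#' Combines the normalised Shenkin divergence and the missense enrichment
#' score of a column into the four-way position taxonomy: CMD (conserved,
#' `n_shenkin <= 25`, missense depleted, `mes < 0`), CME (conserved,
#' enriched), UMD (unconserved, `n_shenkin >= 75`, depleted) and UME
#' (unconserved, enriched). Columns between the divergence windows, or with
#' `mes` exactly 0, are `"none"`. Both divergence boundaries are inclusive;
#' the MES inequalities are strict. The function is total on the real plane
#' and the four labelled regions are disjoint.
#'
#' @param n_shenkin Normalised Shenkin score(s), 0-100.
#' @param mes Missense enrichment score(s) (natural-log ratio).
#' @return Character vector in `{"CMD", "CME", "UMD", "UME", "none"}`.
#' @export
classify_column <- function(n_shenkin, mes) {
  dplyr::case_when(
    n_shenkin <= 25 & mes < 0 ~ "CMD",
    n_shenkin <= 25 & mes > 0 ~ "CME",
    n_shenkin >= 75 & mes < 0 ~ "UMD",
    n_shenkin >= 75 & mes > 0 ~ "UME",
    TRUE ~ "none"
  )
}

#' Surface classification of the 33 ankyrin motif positions
#'
#' The default position-to-surface map of the ankyrin repeat: 9 core
#' (buried) positions, the 8-position concave face (beta-turn plus first
#' helix), the 9-position convex face and the 7-position basal face defined
#' by the high-RSA ridges at positions 23/25 and 1/12/33. Custom maps with
#' the same shape can be supplied for other repeat families.
#'
#' @return Tibble `position` (1-33), `surface`
#'   (`core`/`concave`/`convex`/`basal`).
#' @export
ank_surface_map <- function() {
  map <- c(
    "1" = "concave", "2" = "concave", "3" = "concave", "4" = "core",
    "5" = "core", "6" = "core", "7" = "core", "8" = "concave",
    "9" = "core", "10" = "core", "11" = "concave", "12" = "concave",
    "13" = "convex", "14" = "convex", "15" = "convex", "16" = "convex",
    "17" = "core", "18" = "core", "19" = "convex", "20" = "convex",
    "21" = "core", "22" = "convex", "23" = "convex", "24" = "convex",
    "25" = "basal", "26" = "basal", "27" = "basal", "28" = "basal",
    "29" = "basal", "30" = "basal", "31" = "basal", "32" = "concave",
    "33" = "concave"
  )
  tibble::tibble(position = as.integer(names(map)), surface = unname(map))
}

#' Attach surface labels to scored columns
#'
#' @param columns Tibble with a `position` column (motif positions).
#' @param surface_map Position-to-surface tibble; default [ank_surface_map()].
#' @return `columns` with a `surface` column appended.
#' @export
assign_surfaces <- function(columns, surface_map = ank_surface_map()) {
  columns <- tibble::as_tibble(columns)
  missing <- setdiff(columns$position, surface_map$position)
  if (length(missing)) {
    stop("positions without surface assignment: ",
         paste(missing, collapse = ", "))
  }
  dplyr::left_join(columns, surface_map, by = "position")
}

#' Suggest ridge positions from per-column RSA medians
#'
#' High-RSA non-core positions form ridges that delimit the faces of a repeat
#' domain (for the ankyrin repeat: positions 1, 12, 33 and the 23/25 ridge
#' defining the basal face). This advisory scan returns the non-core
#' positions whose median RSA meets the threshold as candidate surface
#' boundaries for new families; it never overrides the surface map.
#'
#' @param summaries Tibble with `position` and `median_rsa` (e.g. from
#'   [struct_summary_all()]).
#' @param rsa_threshold Minimum median RSA (default 0.45).
#' @param surface_map Map used to exclude core positions.
#' @return Integer vector of candidate ridge positions.
#' @export
suggest_ridges <- function(summaries, rsa_threshold = 0.45,
                           surface_map = ank_surface_map()) {
  core <- surface_map$position[surface_map$surface == "core"]
  cand <- summaries$position[!summaries$position %in% core &
                               summaries$median_rsa >= rsa_threshold]
  sort(as.integer(cand))
}
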