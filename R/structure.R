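#' Theoretical maximum accessible surface area per residue (Tien et al.)
#'
#' The theoretical MaxASA values (Angstrom^2) of Tien et al. (2013), used to
#' convert DSSP absolute accessible surface areas into relative solvent
#' accessibilities. Shipped as versioned package data; the empirical variant
#' of the table is deliberately not used.
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
tien_max_asa <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 264.0, Y = 263.0, V = 174.0)
}

#' Filter structural residues by electron-density quality
#'
#' Keeps residues with real-space correlation coefficient strictly above
#' `rscc_min` AND real-space R-value Z-score strictly below `rsrz_max`
#' (defaults RSCC > 0.85 and RSRZ < 2). Residues missing either metric are
#' dropped. The operation is idempotent.
#'
#' @param records Tibble of per-residue structural records with `rscc` and
#'   `rsrz` columns.
#' @param rscc_min,rsrz_max Strict thresholds.
#' @return The surviving records; the number dropped is reported via
#'   `attr(, "n_dropped")`.
#' @export
filter_by_quality <- function(records, rscc_min = 0.85, rsrz_max = 2) {
  records <- tibble::as_tibble(records)
  keep <- !is.na(records$rscc) & !is.na(records$rsrz) &
    records$rscc > rscc_min & records$rsrz < rsrz_max
  out <- records[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Relative solvent accessibility from absolute ASA
#'
#' Divides DSSP's accessible surface area by the residue type's theoretical
#' maximum ([tien_max_asa()]). Values above 1 can occur for distorted
#' conformations and are reported as-is.
#'
#' @param asa Absolute accessible surface area(s), Angstrom^2, `>= 0`.
#' @param aa One-letter residue code(s), recycled against `asa`.
#' @return Numeric RSA fraction(s).
#' @export
rsa_from_asa <- function(asa, aa) {
  stopifnot(all(asa >= 0))
  mx <- tien_max_asa()[toupper(aa)]
  if (anyNA(mx)) {
    stop("unknown residue type(s): ",
         paste(unique(aa[is.na(mx)]), collapse = ", "))
  }
  unname(asa / mx)
}

#' Classify relative solvent accessibility
#'
#' Buried iff RSA <= 5%, surface iff RSA >= 25%, otherwise partially exposed;
#' both boundary values are inclusive of the outer classes. The three classes
#' partition `[0, Inf)` exactly.
#'
#' @param rsa Numeric RSA fraction(s), `>= 0`.
#' @return Character vector in `{"buried", "partial", "surface"}`.
#' @export
classify_rsa <- function(rsa) {
  stopifnot(all(rsa >= 0))
  dplyr::case_when(rsa <= 0.05 ~ "buried",
                   rsa >= 0.25 ~ "surface",
                   TRUE ~ "partial")
}

bootstrap_median_ci <- function(x, n_boot = 1000, conf_level = 0.95,
                                boot_seed = 1) {
  if (length(x) == 1L) return(c(x, x))
  with_seed(boot_seed, {
    meds <- vapply(seq_len(n_boot), function(i) {
      median(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
  })
  unname(quantile(meds, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
}

#' Structural summary of one motif position
#'
#' Summarises quality-filtered residues mapped to a motif position:
#' eight-state DSSP secondary-structure frequencies and their consensus
#' (argmax, ties resolved in the fixed order H, G, I, E, B, T, S, C), the
#' median RSA with a seeded bootstrap 95% CI (1000 resamples), and the RSA
#' class of the median.
#'
#' @param records Quality-filtered residue tibble with `ank_position`, `ss8`,
#'   `rsa`.
#' @param position Motif position (1-33) to summarise.
#' @param n_boot,boot_seed Bootstrap resamples and seed for the median CI.
#' @return One-row tibble: `position`, `n_residues`, `ss8_<state>`
#'   frequencies, `consensus_ss`, `median_rsa`, `rsa_ci_low`, `rsa_ci_high`,
#'   `rsa_class`.
#' @export
column_struct_summary <- function(records, position, n_boot = 1000,
                                  boot_seed = 1) {
  sub <- records[!is.na(records$ank_position) &
                   records$ank_position == position, ]
  if (!nrow(sub)) stop("no structural records at motif position ", position)
  ssf <- tabulate(factor(sub$ss8, levels = SS8), nbins = 8L) / nrow(sub)
  ci <- bootstrap_median_ci(sub$rsa, n_boot = n_boot,
                            boot_seed = boot_seed + position)
  med <- median(sub$rsa)
  out <- tibble::tibble(position = as.integer(position),
                        n_residues = nrow(sub))
  out[paste0("ss8_", SS8)] <- as.list(ssf)
  out$consensus_ss <- SS8[which.max(ssf)]
  out$median_rsa <- med
  out$rsa_ci_low <- ci[1]
  out$rsa_ci_high <- ci[2]
  out$rsa_class <- classify_rsa(med)
  out
}

#' @rdname column_struct_summary
#' @return `struct_summary_all()`: one row per motif position present in
#'   `records`.
#' @export
struct_summary_all <- function(records, n_boot = 1000, boot_seed = 1) {
  positions <- sort(unique(records$ank_position[!is.na(records$ank_position)]))
  dplyr::bind_rows(lapply(positions, column_struct_summary, records = records,
                          n_boot = n_boot, boot_seed = boot_seed))
}

## Ideal inner-residue dihedrals (phi2, psi2, phi3, psi3) of the classic
## beta-turn types, Hutchinson/Thornton convention.
BETA_TURN_IDEALS <- rbind(
  I      = c(-60,  -30,  -90,    0),
  `I'`   = c( 60,   30,   90,    0),
  II     = c(-60,  120,   80,    0),
  `II'`  = c( 60, -120,  -80,    0),
  VIII   = c(-60,  -30, -120,  120)
)

angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Classify a beta-turn from the inner residues' dihedral angles
#'
#' Assigns the nearest ideal turn type (I, I', II, II', VIII) from the phi/psi
#' angles of residues i+1 and i+2 of a four-residue turn. Each angle must lie
#' within +/-45 degrees of the ideal, except psi(i+1) which is allowed +/-90
#' degrees; among types within tolerance the one with the smallest total
#' angular deviation wins, and if none qualifies the turn is `"other"`. These
#' windows follow the common convention; they are a convention choice, not a
#' universal standard.
#'
#' @param phi2,psi2 Dihedrals (degrees) of residue i+1.
#' @param phi3,psi3 Dihedrals of residue i+2.
#' @return Turn type string, or `NA` when any dihedral is missing.
#' @export
classify_beta_turn <- function(phi2, psi2, phi3, psi3) {
  if (anyNA(c(phi2, psi2, phi3, psi3))) return(NA_character_)
  obs <- c(phi2, psi2, phi3, psi3)
  tol <- c(45, 90, 45, 45)
  diffs <- t(apply(BETA_TURN_IDEALS, 1, angle_diff, b = obs))
  ok <- apply(diffs, 1, function(d) all(d <= tol))
  if (!any(ok)) return("other")
  total <- rowSums(diffs)
  names(which.min(ifelse(ok, total, Inf)))
}

next_motif_position <- function(position, offset, period = 33L) {
  ((position + offset - 1L) %% period) + 1L
}

#' Detect Asx motifs stabilising the motif's beta-turns
#'
#' The two beta-turns of the ankyrin repeat can be reinforced by an Asx (Asn
#' or Asp) side chain hydrogen-bonding to downstream backbone amides: an
#' Asx-beta-turn when the side chain at position 27 bonds the backbone N two
#' residues downstream, and a type 1 beta-bulge loop with Asx when the side
#' chain at position 32 bonds the backbone N of both i+2 and i+4 (wrapping
#' into the next repeat). Repeats without Asx at the anchor form a simple
#' beta-turn.
#'
#' @param anchor_position Motif position of the candidate anchor (27 or 32).
#' @param anchor_aa One-letter residue at the anchor.
#' @param hbonds Tibble of hydrogen bonds with columns `from_pos`,
#'   `from_atom`, `to_pos`, `to_atom`; atom classes are `"side_chain"` or
#'   `"backbone"`. Direction is not interpreted: a bond between the anchor
#'   side chain and a downstream backbone N matches either way around.
#' @return `"asx_beta_turn"`, `"type1_beta_bulge_asx"` or `"none"`.
#' @export
detect_asx_motif <- function(anchor_position, anchor_aa, hbonds) {
  stopifnot(anchor_position %in% c(27L, 32L))
  if (!toupper(anchor_aa) %in% c("N", "D")) return("none")
  hbonds <- tibble::as_tibble(hbonds)
  has_bond <- function(target_pos) {
    any((hbonds$from_pos == anchor_position &
           hbonds$from_atom == "side_chain" &
           hbonds$to_pos == target_pos & hbonds$to_atom == "backbone") |
          (hbonds$to_pos == anchor_position &
             hbonds$to_atom == "side_chain" &
             hbonds$from_pos == target_pos & hbonds$from_atom == "backbone"))
  }
  if (anchor_position == 27L) {
    if (has_bond(next_motif_position(27L, 2L))) return("asx_beta_turn")
  } else {
    if (has_bond(next_motif_position(32L, 2L)) &&
        has_bond(next_motif_position(32L, 4L))) {
      return("type1_beta_bulge_asx")
    }
  }
  "none"
}

#' Annotate the canonical beta-turns of structural repeats
#'
#' For each repeat, types the two canonical turns of the motif — 27-30 (inner
#' residues 28, 29) and 32-2 (inner residues 33 and 1 of the following repeat
#' position) — from the inner dihedrals, and calls the Asx motif status of
#' each anchor when hydrogen bonds are supplied.
#'
#' @param records Per-residue tibble with `repeat_id`, `ank_position`, `aa`,
#'   `phi`, `psi`.
#' @param hbonds Optional hydrogen-bond tibble (see [detect_asx_motif()])
#'   with an additional `repeat_id` column.
#' @return Tibble: `repeat_id`, `span`, `turn_type`, `asx_motif`.
#' @export
annotate_turns <- function(records, hbonds = NULL) {
  spans <- list(`27-30` = c(anchor = 27L, i2 = 28L, i3 = 29L),
                `32-2`  = c(anchor = 32L, i2 = 33L, i3 = 1L))
  per_repeat <- split(tibble::as_tibble(records), records$repeat_id)
  dplyr::bind_rows(lapply(names(per_repeat), function(rid) {
    rec <- per_repeat[[rid]]
    get1 <- function(pos, what) {
      v <- rec[[what]][rec$ank_position == pos]
      if (length(v)) v[1] else NA
    }
    dplyr::bind_rows(lapply(names(spans), function(sp) {
      s <- spans[[sp]]
      tt <- classify_beta_turn(get1(s["i2"], "phi"), get1(s["i2"], "psi"),
                               get1(s["i3"], "phi"), get1(s["i3"], "psi"))
      asx <- if (is.null(hbonds)) {
        NA_character_
      } else {
        hb <- hbonds[hbonds$repeat_id == rid, , drop = FALSE]
        detect_asx_motif(s[["anchor"]], get1(s["anchor"], "aa") %||% "X", hb)
      }
      tibble::tibble(repeat_id = rid, span = sp, turn_type = tt,
                     asx_motif = asx)
    }))
  }))
}

#' Read a per-residue structural annotation table
#'
#' Tab-separated, `#` comments; expected columns `structure_id`, `repeat_id`,
#' `ank_position`, `aa`, `asa`, `ss8`, `phi`, `psi`, `rscc`, `rsrz`, and
#' optionally `rsa` (recomputed from `asa` when absent) and `bound`.
#'
#' @param path TSV path.
#' @return Residue tibble with an `rsa` column.
#' @export
read_structure_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("structure_id", "repeat_id", "ank_position", "aa", "asa", "ss8",
            "phi", "psi", "rscc", "rsrz")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("structure table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"rsa" %in% names(out)) out$rsa <- rsa_from_asa(out$asa, out$aa)
  bad <- !out$ss8 %in% SS8
  if (any(bad)) stop("unknown ss8 states: ",
                     paste(unique(out$ss8[bad]), collapse = ", "))
  out
}
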