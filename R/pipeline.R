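#' Default pipeline configuration
#'
#' Assembles the declarative configuration consumed by [run_pipeline()]. All
#' analysis thresholds default to the values used throughout the package
#' documentation; every one of them can be overridden per run.
#'
#' @param seed Base seed for all randomness in the run.
#' @param out_dir Output directory for the report bundle.
#' @param synthetic List describing a synthetic run: `n_seq`, `n_human`,
#'   `n_struct_repeats`, plus any [synthetic_truth()] arguments under
#'   `truth`. Mutually exclusive with `inputs`.
#' @param inputs List of file paths for a file-based run: `alignment`
#'   (aligned FASTA or Stockholm), `variants`, `structures`, `contacts`
#'   (TSVs), and optionally `sequences` (unaligned FASTA) with
#'   `curate = TRUE` to build the alignment first.
#' @param curate Build the alignment from unaligned sequences via
#'   [iterative_build()] (groups formed by `source`).
#' @param thresholds Named overrides of the analysis thresholds
#'   (`occupancy`, `rscc_min`, `rsrz_max`, `min_separation`,
#'   `conserved_max`, `unconserved_min`, `ridge_rsa`, `tau`, `conf_level`).
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("ankprof_run_"),
                            synthetic = NULL, inputs = NULL, curate = FALSE,
                            thresholds = list()) {
  th <- list(occupancy = 0.005, rscc_min = 0.85, rsrz_max = 2,
             min_separation = 6L, conserved_max = 25, unconserved_min = 75,
             ridge_rsa = 0.45, tau = 2 / 3, conf_level = 0.95)
  th[names(thresholds)] <- thresholds
  list(seed = as.integer(seed), out_dir = out_dir, synthetic = synthetic,
       inputs = inputs, curate = curate, thresholds = th)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the column-profiling pipeline end to end
#'
#' Executes (optional) alignment curation, per-column divergence scoring,
#' missense-variant enrichment, structural feature summarisation, contact
#' and substrate-interaction enrichment, and the final position taxonomy and
#' surface assignment, then writes the report bundle: per-stage TSVs, a
#' per-position master table joining every score, a JSON summary, and a run
#' log. Identical configuration and seed produce byte-identical outputs.
#'
#' @param config A list from [pipeline_config()].
#' @return Invisibly, the in-memory result bundle (alignment, per-position
#'   tibbles and file paths).
#' @export
run_pipeline <- function(config) {
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- inputs ----
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    truth <- stage("synthetic_data", do.call(
      synthetic_truth, c(syn$truth %||% list(), list(seed = config$seed))))
    aln <- stage("synthetic_data",
                 generate_alignment(truth, syn$n_seq, syn$n_human))
    variants <- stage("synthetic_data", generate_variants(aln, truth))
    strc <- stage("synthetic_data",
                  generate_structures(aln, truth, syn$n_struct_repeats))
    structures <- strc$structures
    contacts <- strc$contacts
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (isTRUE(config$curate)) {
      seqs <- stage("msa_curation", read_repeat_fasta(inp$sequences))
      groups <- split(seqs, seqs$source)
      built <- stage("msa_curation", iterative_build(unname(groups)))
      aln <- built$alignment
      write_removal_log(built$removed, file.path(config$out_dir,
                                                 "removed_sequences.tsv"))
    } else {
      aln <- stage("input", {
        a <- if (grepl("\\.(sto|stk|stockholm)$", inp$alignment)) {
          read_stockholm(inp$alignment)
        } else {
          read_repeat_fasta(inp$alignment)
        }
        if (!inherits(a, "repeat_alignment")) {
          stop("alignment input is not aligned")
        }
        a
      })
    }
    variants <- stage("input", read_variant_tsv(inp$variants))
    structures <- stage("input", read_structure_tsv(inp$structures))
    contacts <- stage("input", read_contact_tsv(inp$contacts))
  } else {
    stop("config needs either $synthetic or $inputs")
  }

  ## ---- conservation ----
  divergence <- stage("conservation", column_divergence(aln))

  ## ---- variant enrichment ----
  counts <- stage("variant_enrichment", map_variants_to_columns(variants, aln))
  mes <- stage("variant_enrichment",
               mes_per_column(counts, conf_level = th$conf_level))

  ## ---- structure features ----
  filtered <- stage("structure_features",
                    filter_by_quality(structures, th$rscc_min, th$rsrz_max))
  summaries <- stage("structure_features",
                     struct_summary_all(filtered, boot_seed = config$seed))
  turns <- stage("structure_features", annotate_turns(filtered))

  ## ---- contact analysis ----
  cov <- filtered[c("structure_id", "repeat_id", "ank_position")]
  cmap <- stage("contact_analysis", {
    filter_short_range(build_intra_map(contacts, cov), th$min_separation)
  })
  cenr <- stage("contact_analysis",
                contact_enrichment(cmap, conf_level = th$conf_level))
  evidence <- stage("contact_analysis", ppi_evidence(contacts, cov))
  ppi <- if (sum(evidence$n) > 0) {
    stage("contact_analysis", ppies(evidence, conf_level = th$conf_level))
  } else {
    NULL
  }
  bound_ids <- unique(contacts$structure_id[
    contacts$partner_class == "substrate"])
  modes <- if (length(bound_ids)) {
    bind_tbl <- dplyr::filter(contacts, .data$partner_class == "substrate")
    stage("contact_analysis", binding_mode(
      tibble::tibble(protein_id = bind_tbl$structure_id,
                     repeat_id = bind_tbl$repeat_id,
                     ank_position = bind_tbl$ank_position_a),
      tau = th$tau))
  } else {
    NULL
  }

  ## ---- classification & report ----
  master <- divergence |>
    dplyr::left_join(dplyr::rename_with(mes, ~ paste0("mes_", .x),
                                        -"position"),
                     by = "position") |>
    dplyr::rename(mes = "mes_score") |>
    dplyr::left_join(summaries[c("position", "median_rsa", "rsa_class",
                                 "consensus_ss")], by = "position")
  if (!is.null(ppi)) {
    master <- dplyr::left_join(
      master,
      dplyr::select(ppi, "position", ppies = "score",
                    ppies_ci_low = "ci_low", ppies_ci_high = "ci_high",
                    ppies_p = "p"),
      by = "position")
  }
  master <- master |>
    dplyr::left_join(dplyr::select(cenr, "position", contact_score = "score",
                                   contact_ci_low = "ci_low",
                                   contact_ci_high = "ci_high",
                                   contact_p = "p"),
                     by = "position") |>
    assign_surfaces() |>
    dplyr::mutate(label = classify_column(.data$n_shenkin, .data$mes))
  ridges <- suggest_ridges(summaries, th$ridge_rsa)

  ## ---- outputs ----
  paths <- c(divergence = "divergence.tsv", mes = "mes.tsv",
             struct_summary = "struct_summary.tsv", turns = "turns.tsv",
             contact_map = "contact_map.tsv",
             contact_enrichment = "contact_enrichment.tsv",
             ppies = "ppies.tsv", binding_modes = "binding_modes.tsv",
             positions = "positions.tsv", summary = "summary.json",
             log = "run_log.txt")
  paths <- setNames(file.path(config$out_dir, paths), names(paths))
  readr::write_tsv(divergence, paths["divergence"])
  readr::write_tsv(mes, paths["mes"])
  readr::write_tsv(summaries, paths["struct_summary"])
  readr::write_tsv(turns, paths["turns"])
  write_contact_map_tsv(cmap, paths["contact_map"])
  readr::write_tsv(cenr, paths["contact_enrichment"])
  if (!is.null(ppi)) readr::write_tsv(ppi, paths["ppies"])
  if (!is.null(modes)) readr::write_tsv(modes, paths["binding_modes"])
  readr::write_tsv(master, paths["positions"])
  jsonlite::write_json(
    list(n_sequences = n_sequences(aln), n_human = sum(aln$meta$is_human),
         n_variant_sites = sum(counts$missense_count),
         n_structural_residues = nrow(filtered),
         candidate_ridges = ridges,
         positions = master),
    paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("ankprof %s", as.character(utils::packageVersion("ankprof"))),
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s", if (!is.null(config$synthetic)) "synthetic"
            else "files"),
    sprintf("thresholds: %s",
            paste(names(th), unlist(th), sep = "=", collapse = " ")),
    sprintf("sequences: %d (human %d)", n_sequences(aln),
            sum(aln$meta$is_human)),
    sprintf("variant sites mapped: %d", sum(counts$missense_count)),
    sprintf("structural residues kept: %d (dropped %d)", nrow(filtered),
            attr(filtered, "n_dropped")),
    sprintf("candidate ridge positions: %s",
            paste(ridges, collapse = ", "))
  ), paths["log"])

  invisible(list(alignment = aln, divergence = divergence, counts = counts,
                 mes = mes, summaries = summaries, turns = turns,
                 contact_map = cmap, contact_enrichment = cenr,
                 ppi_evidence = evidence, ppies = ppi,
                 binding_modes = modes, master = master, ridges = ridges,
                 paths = paths))
}
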