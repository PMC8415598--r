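#' Ground truth for the synthetic repeat-family generator
#'
#' Defines the per-column statistical structure from which synthetic
#' alignments, variant tables, structural tables and contact tables are
#' drawn, so every downstream score can be checked against a known truth.
#' Columns are exchangeable across sequences (star phylogeny): one categorical
#' amino-acid distribution per column, sampled once from a Dirichlet whose
#' concentration controls conservation (low total alpha = conserved).
#'
#' @param n_columns Motif length (default 33).
#' @param column_alphas 20 x `n_columns` matrix of strictly positive Dirichlet
#'   concentrations (rows = amino acids in [AA20] order). Default 0.5
#'   everywhere: moderately conserved columns.
#' @param variant_log_effects Per-column true ln rate-ratio of missense
#'   variant occurrence versus baseline (recycled; default 0).
#' @param baseline_variant_rate Probability that a human residue at a neutral
#'   column carries a missense variant site (default 0.1).
#' @param rsa_mean Per-column mean RSA on (0, 1) (recycled; default 0.3).
#' @param rsa_kappa Beta concentration for RSA: `alpha = m * kappa`,
#'   `beta = (1 - m) * kappa` (default 10).
#' @param ss_labels 8 x `n_columns` matrix of DSSP 8-state probabilities
#'   (rows in [SS8] order); default mostly alpha-helical with some turn/coil.
#' @param contact_probs Symmetric `n_columns` matrix of per-pair intra-repeat
#'   contact probabilities; default decays with sequence separation the way
#'   helical packing does.
#' @param ppi_probs Per-column substrate-contact probability for repeats of
#'   substrate-bound structures (recycled; default 0.05).
#' @param quality_fail_fraction Fraction of residues planted to fail the
#'   RSCC/RSRZ quality filter (default 0.1).
#' @param bound_fraction Fraction of synthetic structures flagged
#'   substrate-bound (default 0.5).
#' @param repeats_per_domain Repeats grouped into one synthetic structure
#'   (default 4, a small ankyrin repeat domain).
#' @param seed Base seed for all generators.
#'
#' @return A `synthetic_truth` list with the validated fields above.
#' @export
synthetic_truth <- function(n_columns = 33L, column_alphas = NULL,
                            variant_log_effects = 0,
                            baseline_variant_rate = 0.1,
                            rsa_mean = 0.3, rsa_kappa = 10,
                            ss_labels = NULL, contact_probs = NULL,
                            ppi_probs = 0.05, quality_fail_fraction = 0.1,
                            bound_fraction = 0.5, repeats_per_domain = 4L,
                            seed = 1L) {
  n <- as.integer(n_columns)
  stopifnot(n >= 2L)
  if (is.null(column_alphas)) column_alphas <- matrix(0.5, 20, n)
  column_alphas <- as.matrix(column_alphas)
  stopifnot(nrow(column_alphas) == 20L, ncol(column_alphas) == n,
            all(column_alphas > 0))
  variant_log_effects <- rep_len(variant_log_effects, n)
  rsa_mean <- rep_len(rsa_mean, n)
  stopifnot(all(rsa_mean > 0), all(rsa_mean < 1), rsa_kappa > 0)
  if (is.null(ss_labels)) {
    ss_labels <- matrix(c(0.70, 0.05, 0.01, 0.02, 0.02, 0.10, 0.05, 0.05),
                        8, n)
  }
  ss_labels <- as.matrix(ss_labels)
  stopifnot(nrow(ss_labels) == 8L, ncol(ss_labels) == n,
            all(abs(colSums(ss_labels) - 1) < 1e-6))
  if (is.null(contact_probs)) {
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    contact_probs <- pmin(0.02 + 0.5 * exp(-sep / 3), 0.9)
    diag(contact_probs) <- 0
  }
  contact_probs <- as.matrix(contact_probs)
  stopifnot(nrow(contact_probs) == n, ncol(contact_probs) == n,
            isTRUE(all.equal(contact_probs, t(contact_probs))),
            all(contact_probs >= 0), all(contact_probs <= 1))
  ppi_probs <- rep_len(ppi_probs, n)
  stopifnot(all(ppi_probs >= 0), all(ppi_probs <= 1),
            baseline_variant_rate >= 0, baseline_variant_rate <= 1,
            quality_fail_fraction >= 0, quality_fail_fraction < 1,
            bound_fraction >= 0, bound_fraction <= 1)
  structure(
    list(n_columns = n, column_alphas = column_alphas,
         variant_log_effects = variant_log_effects,
         baseline_variant_rate = baseline_variant_rate,
         rsa_mean = rsa_mean, rsa_kappa = rsa_kappa, ss_labels = ss_labels,
         contact_probs = contact_probs, ppi_probs = ppi_probs,
         quality_fail_fraction = quality_fail_fraction,
         bound_fraction = bound_fraction,
         repeats_per_domain = as.integer(repeats_per_domain),
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

sample_dirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) {          # extreme concentrations underflow: one-hot draw
    g[sample.int(length(alpha), 1L, prob = alpha)] <- 1
  }
  g / sum(g)
}

#' Generate a synthetic repeat alignment
#'
#' Draws each column's amino-acid distribution once from
#' `Dirichlet(column_alphas)`, then samples every sequence independently,
#' column-wise, from those distributions — a gap-free core block with
#' exchangeable rows. The first `n_human` sequences are flagged human.
#' Reproducible under a fixed seed; the sampled per-column probabilities are
#' attached as `attr(, "column_probs")` for downstream checks.
#'
#' @param truth A [synthetic_truth()].
#' @param n_seq Number of sequences (> 0).
#' @param n_human Number of human-flagged sequences (`<= n_seq`).
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return A [repeat_alignment] of `n_seq` gap-free rows.
#' @export
generate_alignment <- function(truth, n_seq, n_human, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_seq <= 0 || n_human < 0) stop("counts must be positive")
  if (n_human > n_seq) stop("n_human exceeds n_seq")
  n <- truth$n_columns
  with_seed(seed, {
    probs <- apply(truth$column_alphas, 2, sample_dirichlet)
    mat <- vapply(seq_len(n), function(j) {
      sample(AA20, n_seq, replace = TRUE, prob = probs[, j])
    }, character(n_seq))
  })
  if (n_seq == 1L) mat <- matrix(mat, nrow = 1L)
  rows <- apply(mat, 1, paste, collapse = "")
  meta <- tibble::tibble(
    id = sprintf("synth_%05d", seq_len(n_seq)),
    source = "synthetic",
    species = ifelse(seq_len(n_seq) <= n_human, "homo_sapiens",
                     "synthetica_exemplaris"),
    is_human = seq_len(n_seq) <= n_human
  )
  aln <- repeat_alignment(rows, meta = meta)
  attr(aln, "column_probs") <- probs
  aln
}

#' Generate a missense variant table with known per-column effects
#'
#' Every human residue at column `i` receives a missense variant site with
#' probability `baseline_variant_rate * exp(variant_log_effects[i])`; an
#' effect pushing the probability above 1 is an error naming the column. Alt
#' amino acids are sampled uniformly among the 19 non-reference residues;
#' allele counts are fixed at 1 (the enrichment machinery counts sites, not
#' alleles).
#'
#' @inheritParams generate_alignment
#' @param aln Alignment from [generate_alignment()] (gap-free core block with
#'   at least one human row).
#' @return Variant tibble (`sequence_id`, `residue_position`, `ref_aa`,
#'   `alt_aa`, `consequence`, `allele_count`).
#' @export
generate_variants <- function(aln, truth, seed = truth$seed + 1L) {
  stopifnot(inherits(aln, "repeat_alignment"),
            inherits(truth, "synthetic_truth"))
  human <- which(aln$meta$is_human)
  if (!length(human)) stop("alignment has no human sequences")
  n <- truth$n_columns
  stopifnot(aln_width(aln) == n)
  p <- truth$baseline_variant_rate * exp(truth$variant_log_effects)
  if (any(p > 1)) {
    stop("variant probability exceeds 1 at column(s) ",
         paste(which(p > 1), collapse = ", "))
  }
  mat <- aln_char_matrix(aln$rows[human])
  with_seed(seed, {
    hit <- matrix(runif(length(human) * n), length(human), n) <
      matrix(p, length(human), n, byrow = TRUE)
    idx <- which(hit, arr.ind = TRUE)
    ref <- mat[idx]
    alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L), character(1))
  })
  ord <- order(idx[, 1], idx[, 2])
  tibble::tibble(
    sequence_id = aln$meta$id[human][idx[ord, 1]],
    residue_position = as.integer(idx[ord, 2]),
    ref_aa = ref[ord], alt_aa = unname(alt[ord]),
    consequence = "missense", allele_count = 1L
  )
}

ss_phi_psi <- function(ss) {
  ideal <- rbind(H = c(-60, -45), G = c(-74, -4), I = c(-57, -70),
                 E = c(-120, 120), B = c(-120, 120), T = c(-60, -30),
                 S = c(-90, 0), C = c(-90, 120))
  ideal[ss, , drop = FALSE]
}

#' Generate synthetic structural and contact tables
#'
#' For each of the first `n_struct_repeats` sequences (grouped into
#' structures of `repeats_per_domain` repeats), draws per-column RSA from a
#' Beta with the truth's mean and concentration, secondary structure from the
#' per-column 8-state distribution, phi/psi from canonical per-state angles
#' with +/-15 degree uniform jitter, and RSCC/RSRZ so that
#' `quality_fail_fraction` of residues fail the quality filter. Intra-repeat
#' contacts are Bernoulli draws from `contact_probs`; repeats of structures
#' flagged substrate-bound additionally draw per-column substrate contacts
#' from `ppi_probs`.
#'
#' @inheritParams generate_variants
#' @param n_struct_repeats Number of structural repeats (`<=` sequences in
#'   `aln`).
#' @return List with `structures` (per-residue tibble including `rsa`, `asa`,
#'   quality metrics and a per-structure `bound` flag) and `contacts`
#'   (contact tibble with `intra_repeat` and `substrate` rows).
#' @export
generate_structures <- function(aln, truth, n_struct_repeats,
                                seed = truth$seed + 2L) {
  stopifnot(inherits(aln, "repeat_alignment"),
            inherits(truth, "synthetic_truth"))
  if (n_struct_repeats <= 0) stop("counts must be positive")
  if (n_struct_repeats > n_sequences(aln)) {
    stop("n_struct_repeats exceeds number of sequences")
  }
  n <- truth$n_columns
  stopifnot(aln_width(aln) == n)
  rep_ids <- aln$meta$id[seq_len(n_struct_repeats)]
  rpd <- truth$repeats_per_domain
  struct_of <- sprintf("synthstr_%04d", (seq_len(n_struct_repeats) - 1L) %/%
                         rpd + 1L)
  n_struct <- length(unique(struct_of))
  mat <- aln_char_matrix(aln$rows[seq_len(n_struct_repeats)])

  with_seed(seed, {
    bound_struct <- runif(n_struct) < truth$bound_fraction
    nres <- n_struct_repeats * n
    col_of <- rep(seq_len(n), each = n_struct_repeats)
    rsa <- rbeta(nres, truth$rsa_mean[col_of] * truth$rsa_kappa,
                 (1 - truth$rsa_mean[col_of]) * truth$rsa_kappa)
    ss <- vapply(seq_len(n), function(j) {
      sample(SS8, n_struct_repeats, replace = TRUE,
             prob = truth$ss_labels[, j])
    }, character(n_struct_repeats))
    ss <- as.vector(ss)
    ideal <- ss_phi_psi(ss)
    phi <- ideal[, 1] + runif(nres, -15, 15)
    psi <- ideal[, 2] + runif(nres, -15, 15)
    fail <- runif(nres) < truth$quality_fail_fraction
    rscc <- ifelse(fail, runif(nres, 0.50, 0.85), runif(nres, 0.90, 1.00))
    rsrz <- ifelse(fail & runif(nres) < 0.5, runif(nres, 2, 4),
                   runif(nres, -2, 1))
    ## a residue fails on RSCC, RSRZ or both; passing residues satisfy both
    aa <- as.vector(mat)
    structures <- tibble::tibble(
      structure_id = rep(struct_of, times = n),
      repeat_id = rep(rep_ids, times = n),
      ank_position = col_of,
      aa = aa,
      rsa = rsa,
      asa = rsa * unname(tien_max_asa()[aa]),
      ss8 = ss, phi = phi, psi = psi,
      rscc = rscc, rsrz = rsrz,
      bound = rep(bound_struct[match(struct_of, unique(struct_of))],
                  times = n)
    )
    ## intra-repeat contacts: Bernoulli per repeat and position pair
    ut <- which(upper.tri(truth$contact_probs), arr.ind = TRUE)
    pvec <- truth$contact_probs[ut]
    npairs <- nrow(ut)
    hits <- matrix(runif(n_struct_repeats * npairs), n_struct_repeats,
                   npairs) < matrix(pvec, n_struct_repeats, npairs,
                                    byrow = TRUE)
    hit_idx <- which(hits, arr.ind = TRUE)
    contacts <- tibble::tibble(
      structure_id = struct_of[hit_idx[, 1]],
      repeat_id = rep_ids[hit_idx[, 1]],
      ank_position_a = ut[hit_idx[, 2], 1],
      partner_class = "intra_repeat",
      ank_position_b = ut[hit_idx[, 2], 2],
      partner_id = rep_ids[hit_idx[, 1]],
      interaction_type = "any",
      distance = round(runif(nrow(hit_idx), 3.5, 5), 2)
    )
    ## substrate contacts for repeats of bound structures
    bound_rep <- which(bound_struct[match(struct_of, unique(struct_of))])
    if (length(bound_rep)) {
      shits <- matrix(runif(length(bound_rep) * n), length(bound_rep), n) <
        matrix(truth$ppi_probs, length(bound_rep), n, byrow = TRUE)
      sidx <- which(shits, arr.ind = TRUE)
      sub <- tibble::tibble(
        structure_id = struct_of[bound_rep[sidx[, 1]]],
        repeat_id = rep_ids[bound_rep[sidx[, 1]]],
        ank_position_a = as.integer(sidx[, 2]),
        partner_class = "substrate",
        ank_position_b = NA_integer_,
        partner_id = "substrate_1",
        interaction_type = "any",
        distance = round(runif(nrow(sidx), 3, 5), 2)
      )
      contacts <- dplyr::bind_rows(contacts, sub)
    }
  })
  contacts <- dplyr::arrange(contacts, .data$repeat_id, .data$partner_class,
                             .data$ank_position_a, .data$ank_position_b)
  list(structures = structures, contacts = contacts)
}

#' Write a complete synthetic input bundle
#'
#' Emits the five pipeline input artefacts — aligned FASTA, Stockholm,
#' variant TSV, structure TSV, contact TSV — plus the ground truth as JSON,
#' into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param truth,aln,variants,structures,contacts The synthetic objects.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_bundle <- function(dir, truth, aln, variants, structures,
                                   contacts) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "alignment.fasta"),
    stockholm = file.path(dir, "alignment.sto"),
    variants = file.path(dir, "variants.tsv"),
    structures = file.path(dir, "structures.tsv"),
    contacts = file.path(dir, "contacts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_repeat_fasta(aln, paths["fasta"])
  write_stockholm(aln, paths["stockholm"])
  readr::write_tsv(variants, paths["variants"])
  readr::write_tsv(structures, paths["structures"])
  readr::write_tsv(contacts, paths["contacts"])
  tr <- unclass(truth)
  tr$column_alphas <- as.data.frame(tr$column_alphas)
  tr$ss_labels <- as.data.frame(tr$ss_labels)
  tr$contact_probs <- as.data.frame(tr$contact_probs)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
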