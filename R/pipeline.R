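# End-to-end orchestration: read a cohort directory, score every patient,
# and append the optional LOH / TCR / network layers.

.require_patients <- function(have, want, where) {
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    abort(paste0("patient(s) required but absent from ", where, ": ",
                 paste(head(missing, 5), collapse = ", ")))
  }
}

#' Run the scoring pipeline on a cohort directory
#'
#' Reads the bundle layout written by [write_cohort()] (or assembled by
#' hand): `alleles.fasta`, `genotypes.tsv`, `binding.tsv`, and optionally
#' `mutations.tsv`, `clinical.tsv`, `loh.tsv`, `clones.tsv`. Computes
#' per-locus divergence, filters binders, counts burden, scores and
#' classifies every patient, then joins TMB, LOH strata and baseline TCR
#' metrics where the corresponding tables exist. Tables must agree on
#' patient ids; a patient present in `genotypes.tsv` but missing from a
#' required table is an error naming the patient.
#'
#' @param dir Cohort directory.
#' @param binder_mode,binder_threshold Passed to [filter_binders()].
#' @param mode,cutoff Passed to [classify_haps()].
#' @param tnb_mode Passed to [tnb_per_locus()].
#' @param nn_model Optional `haps_nn` (or path to a model JSON) used to add
#'   an `nn_score` column; requires `mutations.tsv` and `clones.tsv` (for
#'   TMB and diversity features).
#' @return A tibble with one row per patient: divergences, burdens, product
#'   terms, `haps`, `haps_class`, `cutoff`, plus `tmb`, `loh_status`,
#'   `stratum`, `shannon`, `clonality`, `nn_score`, `nn_class` when their
#'   inputs are available.
#' @export
run_haps_pipeline <- function(dir,
                              binder_mode = c("ic50", "rank"),
                              binder_threshold = NULL,
                              mode = c("wes", "panel"),
                              cutoff = NULL,
                              tnb_mode = c("peptides", "pairs"),
                              nn_model = NULL) {
  binder_mode <- match.arg(binder_mode)
  mode <- match.arg(mode)
  tnb_mode <- match.arg(tnb_mode)
  path <- function(f) file.path(dir, f)
  for (f in c("alleles.fasta", "genotypes.tsv", "binding.tsv")) {
    if (!file.exists(path(f))) abort(paste0("required input missing: ", f))
  }

  alleles <- read_allele_fasta(path("alleles.fasta"))
  genotypes <- read_genotype_tsv(path("genotypes.tsv"))
  binding <- read_binding_tsv(path("binding.tsv"))
  patients <- genotypes$patient_id
  .require_patients(patients, unique(binding$patient_id), "genotypes.tsv")

  divergence <- hla_divergence(genotypes, alleles)
  binders <- filter_binders(binding, mode = binder_mode,
                            threshold = binder_threshold)
  burden <- tnb_per_locus(binders, genotypes, mode = tnb_mode)
  result <- compute_haps(divergence, burden) |>
    classify_haps(cutoff = cutoff, mode = mode)

  if (file.exists(path("mutations.tsv"))) {
    mutations <- read_mutation_tsv(path("mutations.tsv"))
    .require_patients(mutations$patient_id, patients, "mutations.tsv")
    result <- left_join(result, tmb(mutations), by = "patient_id")
  }

  if (file.exists(path("loh.tsv"))) {
    loh <- read_loh_tsv(path("loh.tsv"))
    .require_patients(unique(loh$patient_id), patients, "loh.tsv")
    status <- loh_patient_status(classify_loh(loh))
    strata <- stratify_haps_loh(result, status, collapse = "four")
    result <- result |>
      left_join(select(strata, "patient_id", "loh_status", "stratum"),
                by = "patient_id")
  }

  if (file.exists(path("clones.tsv"))) {
    clones <- read_clones_tsv(path("clones.tsv"))
    if (!"patient_id" %in% names(clones)) {
      abort("clones.tsv must carry a `patient_id` column in pipeline mode")
    }
    if ("timepoint" %in% names(clones)) {
      clones <- filter(clones, .data$timepoint == "baseline")
    }
    .require_patients(unique(clones$patient_id), patients, "clones.tsv")
    metrics <- clones |>
      group_by(.data$patient_id, .data$cdr3_aa) |>
      summarise(count = sum(.data$count), .groups = "drop_last") |>
      summarise(
        shannon = {
          p <- .data$count / sum(.data$count)
          -sum(p * log(p))
        },
        clonality = ifelse(dplyr::n() == 1, 1,
                           1 - shannon / log(dplyr::n())),
        .groups = "drop")
    result <- left_join(result, metrics, by = "patient_id")
  }

  if (!is.null(nn_model)) {
    if (is.character(nn_model)) nn_model <- read_nn_model(nn_model)
    needed <- c("haps", "tmb", "shannon")
    missing <- setdiff(needed, names(result))
    if (length(missing) > 0) {
      abort(paste0("network scoring needs column(s) ",
                   paste(missing, collapse = ", "),
                   "; provide mutations.tsv and clones.tsv"))
    }
    feats <- result |>
      select("patient_id", "haps", "tmb") |>
      mutate(tcr_diversity = result$shannon)
    result$nn_score <- predict(nn_model, feats)
    if (!is.null(nn_model$threshold)) {
      result$nn_class <- ifelse(result$nn_score >= nn_model$threshold,
                                "DCR", "PD")
    }
  }

  result
}
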