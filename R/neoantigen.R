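# Neoantigen calling from MHC-I binding predictions, per-locus burden, TMB,
# and the neoantigen quality score.

#' Filter binding predictions to putative neoantigens
#'
#' Keeps records with binding stronger than the threshold: strictly
#' `ic50_nm < threshold` (default 500 nM) or strictly `rank_pct < threshold`
#' (default 1 percent). Row order is preserved and the input is not modified.
#'
#' @param binding Tibble of binding records with at least `patient_id`,
#'   `peptide`, `allele` and the column named by `mode`.
#' @param mode `"ic50"` (column `ic50_nm`) or `"rank"` (column `rank_pct`).
#' @param threshold Positive cut-off; defaults to 500 (nM) for `"ic50"` and
#'   1.0 (percentile rank) for `"rank"`.
#' @return The subset of `binding` passing the filter.
#' @examples
#' b <- tibble::tibble(patient_id = "P1", peptide = c("A", "B", "C"),
#'                     allele = "A*02:01", ic50_nm = c(499, 500, 501))
#' filter_binders(b) # keeps only the 499 nM record
#' @export
filter_binders <- function(binding, mode = c("ic50", "rank"),
                           threshold = NULL) {
  mode <- match.arg(mode)
  col <- switch(mode, ic50 = "ic50_nm", rank = "rank_pct")
  threshold <- threshold %||% switch(mode, ic50 = 500, rank = 1.0)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number")
  }
  if (!col %in% names(binding)) {
    abort(paste0("binding table has no `", col, "` column (mode \"",
                 mode, "\")"))
  }
  vals <- binding[[col]]
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    abort(paste0("record(s) missing `", col, "` at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  binding[vals < threshold, , drop = FALSE]
}

#' Per-locus tumor neoantigen burden
#'
#' Counts, for each patient and each HLA-I locus, the neoantigenic peptides
#' presented by at least one allele of that locus. In the default
#' `"peptides"` mode a mutant peptide counts once per locus even if bound by
#' both alleles (burden measures presentable peptides, not peptide-allele
#' pairs); `"pairs"` mode counts distinct peptide-allele pairs for
#' sensitivity analysis. `tnb_total` is the per-patient count of distinct
#' peptides (or pairs) over all loci. Patients present in `genotypes` but
#' without binders get zero counts.
#'
#' @param binders Filtered binding records (see [filter_binders()]).
#' @param genotypes Genotype tibble (`patient_id`, `A1` .. `C2`); every
#'   record's allele must belong to that patient's genotype.
#' @param mode `"peptides"` (default) or `"pairs"`.
#' @return Tibble with columns `patient_id`, `tnb_A`, `tnb_B`, `tnb_C`,
#'   `tnb_total`.
#' @export
tnb_per_locus <- function(binders, genotypes, mode = c("peptides", "pairs")) {
  mode <- match.arg(mode)
  .check_genotype_cols(genotypes)
  required <- c("patient_id", "peptide", "allele")
  missing <- setdiff(required, names(binders))
  if (length(missing) > 0) {
    abort(paste0("binder table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }

  geno_long <- genotypes |>
    tidyr::pivot_longer(cols = all_of(c("A1", "A2", "B1", "B2", "C1", "C2")),
                        names_to = "slot", values_to = "allele_raw") |>
    mutate(allele = parse_allele_name(.data$allele_raw)$allele,
           locus = parse_allele_name(.data$allele_raw)$locus) |>
    distinct(.data$patient_id, .data$allele, .data$locus)

  if (nrow(binders) > 0) {
    parsed <- parse_allele_name(binders$allele)
    recs <- binders |>
      mutate(allele = parsed$allele) |>
      select("patient_id", "peptide", "allele")
    unknown <- anti_join(recs, geno_long,
                         by = c("patient_id", "allele"))
    if (nrow(unknown) > 0) {
      ex <- unknown[1, ]
      abort(sprintf(
        "binder allele %s is absent from patient %s's genotype",
        ex$allele, ex$patient_id))
    }
    recs <- inner_join(recs, geno_long, by = c("patient_id", "allele"))
    per_locus <- recs |>
      group_by(.data$patient_id, .data$locus) |>
      summarise(
        n = if (mode == "peptides") dplyr::n_distinct(.data$peptide)
            else dplyr::n_distinct(paste(.data$peptide, .data$allele)),
        .groups = "drop")
    totals <- recs |>
      group_by(.data$patient_id) |>
      summarise(
        tnb_total = if (mode == "peptides") dplyr::n_distinct(.data$peptide)
                    else dplyr::n_distinct(paste(.data$peptide, .data$allele)),
        .groups = "drop")
    wide <- per_locus |>
      tidyr::pivot_wider(names_from = "locus", values_from = "n",
                         names_prefix = "tnb_", values_fill = 0L)
  } else {
    wide <- tibble(patient_id = character())
    totals <- tibble(patient_id = character(), tnb_total = integer())
  }

  out <- genotypes |>
    distinct(.data$patient_id) |>
    left_join(wide, by = "patient_id") |>
    left_join(totals, by = "patient_id")
  for (col in c("tnb_A", "tnb_B", "tnb_C", "tnb_total")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out |> select("patient_id", "tnb_A", "tnb_B", "tnb_C", "tnb_total")
}

#' Neoantigen quality (self-discrimination) score
#'
#' \deqn{D = (1-w)\,\log\!\frac{K_d^{WT}}{K_d^{MT}} +
#'          w\,\log\!\frac{EC_{50}^{MT}}{EC_{50}^{WT}}}
#' The first term rewards mutant peptides that bind MHC-I more tightly than
#' their wild-type counterpart (differential presentation); the second
#' rewards divergence in T-cell cross-reactivity. `w` sets the relative
#' weight. Natural log by default. The cross-reactivity model producing the
#' EC50 quantities is upstream and consumed as input.
#'
#' @param kd_wt,kd_mt Wild-type / mutant dissociation constants (nM), > 0.
#' @param ec50_wt,ec50_mt Cross-reactivity half-max quantities (same
#'   arbitrary unit), > 0.
#' @param w Relative weight in \[0, 1\].
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric vector of quality scores (vectorized over inputs).
#' @examples
#' neoantigen_quality(10, 1, 1, 10, w = 0.5) # ln 10
#' @export
neoantigen_quality <- function(kd_wt, kd_mt, ec50_wt, ec50_mt, w = 0.5,
                               base = exp(1)) {
  vals <- c(kd_wt, kd_mt, ec50_wt, ec50_mt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("dissociation constants and EC50 quantities must be positive")
  }
  if (any(w < 0 | w > 1)) abort("`w` must lie in [0, 1]")
  (1 - w) * log(kd_wt / kd_mt, base = base) +
    w * log(ec50_mt / ec50_wt, base = base)
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutations per megabase of sequenced coding region.
#'
#' @param mutations Tibble with columns `patient_id`, `n_nonsynonymous`,
#'   `region_size_mb`.
#' @return Tibble with columns `patient_id`, `tmb`.
#' @examples
#' tmb(tibble::tibble(patient_id = "P1", n_nonsynonymous = 50,
#'                    region_size_mb = 1.09))
#' @export
tmb <- function(mutations) {
  required <- c("patient_id", "n_nonsynonymous", "region_size_mb")
  missing <- setdiff(required, names(mutations))
  if (length(missing) > 0) {
    abort(paste0("mutation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(is.na(mutations$region_size_mb) | mutations$region_size_mb <= 0)) {
    abort("`region_size_mb` must be positive")
  }
  if (any(is.na(mutations$n_nonsynonymous) | mutations$n_nonsynonymous < 0)) {
    abort("`n_nonsynonymous` must be non-negative")
  }
  mutations |>
    mutate(tmb = .data$n_nonsynonymous / .data$region_size_mb) |>
    select("patient_id", "tmb")
}
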