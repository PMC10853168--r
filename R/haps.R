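# The HLA tumor-Antigen Presentation Score: per-locus divergence times
# log10(burden + 1), averaged over the three class I loci.

#' Compute the HLA tumor-Antigen Presentation Score (HAPS)
#'
#' For each locus i in \{A, B, C\}, the product term is
#' `hed_i * log10(tnb_i + 1)`; HAPS is the mean of the three terms. A patient
#' scores 0 exactly when every locus is homozygous (divergence 0) or presents
#' no neoantigens.
#'
#' @param divergence Tibble from [hla_divergence()] (`patient_id`, `hed_A`,
#'   `hed_B`, `hed_C`).
#' @param tnb Tibble from [tnb_per_locus()] (`patient_id`, `tnb_A`, `tnb_B`,
#'   `tnb_C`). Patient ids must match `divergence` exactly.
#' @return Tibble with columns `patient_id`, `hed_*`, `tnb_*`, `term_A`,
#'   `term_B`, `term_C`, `haps`.
#' @examples
#' d <- tibble::tibble(patient_id = "P1", hed_A = 6, hed_B = 8, hed_C = 4)
#' t <- tibble::tibble(patient_id = "P1", tnb_A = 99, tnb_B = 9, tnb_C = 0)
#' compute_haps(d, t)$haps # 20/3
#' @export
compute_haps <- function(divergence, tnb) {
  for (nm in c("hed_A", "hed_B", "hed_C")) {
    if (!nm %in% names(divergence)) {
      abort(paste0("divergence table is missing `", nm, "`"))
    }
  }
  for (nm in c("tnb_A", "tnb_B", "tnb_C")) {
    if (!nm %in% names(tnb)) {
      abort(paste0("burden table is missing `", nm, "`"))
    }
  }
  if (!setequal(divergence$patient_id, tnb$patient_id) ||
      anyDuplicated(divergence$patient_id) ||
      anyDuplicated(tnb$patient_id)) {
    abort("divergence and burden tables must carry the same patient ids")
  }
  inner_join(divergence, tnb, by = "patient_id") |>
    mutate(
      term_A = .data$hed_A * log10(.data$tnb_A + 1),
      term_B = .data$hed_B * log10(.data$tnb_B + 1),
      term_C = .data$hed_C * log10(.data$tnb_C + 1),
      haps = (.data$term_A + .data$term_B + .data$term_C) / 3
    )
}

#' Dichotomize HAPS into high and low
#'
#' `"high"` includes the cut-off (`haps >= cutoff`). The default cut-offs are
#' the hazard-ratio-minimizing values reported for whole-exome (10) and
#' gene-panel (1.31) sequencing cohorts; any numeric cut-off may be supplied
#' instead, e.g. one chosen by [scan_cutoff()] on your own cohort.
#'
#' @param haps Tibble with a `haps` column (e.g. from [compute_haps()]).
#' @param cutoff Numeric cut-off; overrides `mode` when given.
#' @param mode `"wes"` (cut-off 10) or `"panel"` (cut-off 1.31).
#' @return `haps` with columns `haps_class` (`"high"`/`"low"`) and `cutoff`
#'   appended.
#' @export
classify_haps <- function(haps, cutoff = NULL, mode = c("wes", "panel")) {
  mode <- match.arg(mode)
  cutoff <- cutoff %||% switch(mode, wes = 10, panel = 1.31)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    abort("`cutoff` must be a single finite number")
  }
  if (!"haps" %in% names(haps)) abort("`haps` column not found")
  haps |>
    mutate(haps_class = ifelse(.data$haps >= cutoff, "high", "low"),
           cutoff = cutoff)
}
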