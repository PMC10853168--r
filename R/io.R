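# Readers and writers for the tabular/FASTA formats the pipeline consumes.
# Canonical dialect: TSV, header row, UTF-8, "." for missing.

#' Parse and normalize HLA class I allele names
#'
#' Accepts `"HLA-A*02:01"`, `"A*02:01:01"`, `"A*02:01"` and the like;
#' normalizes to the locus letter plus a 2-field code. Class II names (e.g.
#' `"DRB1*04:01"`) are rejected: only the classical class I loci A, B, C are
#' in scope.
#'
#' @param x Character vector of allele names.
#' @return A tibble with columns `input`, `locus` (`"A"`, `"B"` or `"C"`) and
#'   `allele` (normalized 2-field name).
#' @examples
#' parse_allele_name(c("HLA-A*02:01", "B*07:02:01"))
#' @export
parse_allele_name <- function(x) {
  if (length(x) == 0 || any(!nzchar(x))) {
    abort("allele names must be non-empty strings")
  }
  stripped <- stringr::str_remove(x, "^HLA-")
  m <- stringr::str_match(stripped, "^([ABC])\\*(\\d+):(\\d+)(?::[0-9:A-Z]+)?$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(paste0("cannot parse HLA class I allele name(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  tibble(
    input = x,
    locus = m[, 2],
    allele = paste0(m[, 2], "*", m[, 3], ":", m[, 4])
  )
}

.read_tsv_strict <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # parsing problems are re-raised as errors below, so readr's own warning
  # is redundant
  out <- suppressWarnings(
    readr::read_tsv(path, comment = "#", na = c("", ".", "NA"),
                    show_col_types = FALSE, col_types = col_types,
                    progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed rows in ", path, " (line ",
                 paste(unique(probs$row), collapse = ", "), ")"))
  }
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' Read an aligned HLA allele FASTA
#'
#' Headers are allele names; sequences are the aligned binding-domain protein
#' (gap character `"-"`). All records must share one alignment length.
#'
#' @param path FASTA file.
#' @return Tibble with columns `allele`, `sequence`.
#' @export
read_allele_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readAAStringSet(path)
  out <- tibble(
    allele = names(set),
    sequence = as.character(set)
  )
  if (length(unique(nchar(out$sequence))) > 1) {
    abort(paste0("alignment lengths differ in ", path))
  }
  out
}

#' Write an aligned HLA allele FASTA
#' @param alleles Tibble with columns `allele`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  set <- Biostrings::AAStringSet(setNames(alleles$sequence, alleles$allele))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a patient HLA genotype table
#'
#' Expects columns `patient_id`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2`.
#' @param path TSV file.
#' @return Tibble of genotypes.
#' @export
read_genotype_tsv <- function(path) {
  .read_tsv_strict(path, c("patient_id", "A1", "A2", "B1", "B2", "C1", "C2"))
}

#' Read an MHC-I binding-prediction table
#'
#' Tolerant of NetMHCpan-style tab output: `#`-prefixed comment lines are
#' skipped and extra columns ignored. Requires `patient_id`, `peptide`,
#' `allele`, and at least one of `ic50_nm`, `rank_pct`; `wt_peptide` is
#' optional.
#' @param path TSV file.
#' @return Tibble of binding records.
#' @export
read_binding_tsv <- function(path) {
  out <- .read_tsv_strict(path, c("patient_id", "peptide", "allele"))
  if (!any(c("ic50_nm", "rank_pct") %in% names(out))) {
    abort(paste0(path, " must carry `ic50_nm` and/or `rank_pct`"))
  }
  out
}

#' Read a mutation summary table (`patient_id`, `n_nonsynonymous`,
#' `region_size_mb`)
#' @param path TSV file.
#' @return Tibble.
#' @export
read_mutation_tsv <- function(path) {
  .read_tsv_strict(path, c("patient_id", "n_nonsynonymous", "region_size_mb"))
}

#' Read a clinical outcome table
#'
#' Requires `patient_id`, `os_months`, `os_event`; further columns
#' (`pfs_months`, `pfs_event`, `response`, covariates) pass through.
#' @param path TSV file.
#' @return Tibble.
#' @export
read_clinical_tsv <- function(path) {
  .read_tsv_strict(path, c("patient_id", "os_months", "os_event"))
}

#' Read an HLA allele-specific copy-number (LOH) table
#'
#' Requires `patient_id`, `locus`, `minor_cn`, `p_allelic_imbalance`.
#' @param path TSV file.
#' @return Tibble.
#' @export
read_loh_tsv <- function(path) {
  .read_tsv_strict(path,
                   c("patient_id", "locus", "minor_cn", "p_allelic_imbalance"))
}

#' Read a TCR clone table
#'
#' Accepts either the package's canonical columns `cdr3_aa`, `count` or the
#' MiXCR export names `aaSeqCDR3`, `cloneCount`; extra columns are ignored.
#' Optional `patient_id` and `timepoint` columns pass through.
#' @param path TSV file.
#' @return Tibble with columns `cdr3_aa`, `count` (plus any metadata columns).
#' @export
read_clones_tsv <- function(path) {
  out <- .read_tsv_strict(path, character())
  if ("aaSeqCDR3" %in% names(out) && !"cdr3_aa" %in% names(out)) {
    out <- rename(out, cdr3_aa = "aaSeqCDR3")
  }
  if ("cloneCount" %in% names(out) && !"count" %in% names(out)) {
    out <- rename(out, count = "cloneCount")
  }
  missing <- setdiff(c("cdr3_aa", "count"), names(out))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' Write a tibble as canonical TSV
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}
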