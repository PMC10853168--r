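# Expression-signature scores defined by closed formula.

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 expression, the two cytolytic effectors
#' upregulated on CD8+ T-cell activation. Unit-agnostic: scaling both genes
#' by k scales CYT by k. No pseudocount is added by default; supply one for
#' zero-inflated data.
#'
#' @param expr Named numeric vector of expression values, or a tibble with
#'   columns `gene` and `value` (one sample).
#' @param pseudocount Non-negative value added to both genes before the
#'   geometric mean (default 0).
#' @return The CYT score.
#' @examples
#' cyt_score(c(GZMA = 4, PRF1 = 9)) # 6
#' @export
cyt_score <- function(expr, pseudocount = 0) {
  if (is.data.frame(expr)) {
    if (!all(c("gene", "value") %in% names(expr))) {
      abort("expression table must have columns `gene` and `value`")
    }
    expr <- setNames(expr$value, expr$gene)
  }
  missing <- setdiff(c("GZMA", "PRF1"), names(expr))
  if (length(missing) > 0) {
    abort(paste0("missing gene(s): ", paste(missing, collapse = ", ")))
  }
  if (pseudocount < 0) abort("`pseudocount` must be non-negative")
  g <- expr[["GZMA"]] + pseudocount
  p <- expr[["PRF1"]] + pseudocount
  if (g < 0 || p < 0) abort("expression values must be non-negative")
  sqrt(g * p)
}

#' MHC class I / II immune-infiltration signature gene sets
#'
#' Packaged gene lists for users running their own enrichment scoring
#' (e.g. ssGSEA, which is out of scope here).
#'
#' @param class `"I"` or `"II"`.
#' @return Character vector of gene symbols.
#' @export
mhc_signature_genes <- function(class = c("I", "II")) {
  class <- match.arg(class)
  if (class == "I") {
    c("B2M", "TAP1", "TAP2", "TAPBP", "HLA-A", "HLA-B", "HLA-C", "HLA-E",
      "HLA-F", "HLA-G")
  } else {
    c("HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB", "HLA-DPA1", "HLA-DPA2",
      "HLA-DPA3", "HLA-DPB1", "HLA-DPB2", "HLA-DQA1", "HLA-DQA2",
      "HLA-DQB1", "HLA-DQB2", "HLA-DRA", "HLA-DRB1", "HLA-DRB2",
      "HLA-DRB3", "HLA-DRB4", "HLA-DRB5", "HLA-DRB6", "HLA-DRB7",
      "HLA-DRB8", "HLA-DRB9")
  }
}
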