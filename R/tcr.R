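# TCR beta CDR3 repertoire metrics: seeded downsampling, Shannon diversity,
# clonality, top-clone edit-distance summaries and substitution-bounded
# similarity networks. Clones are amino-acid level: identical CDR3s are
# merged (counts summed) before any metric.

.check_clones <- function(clones, min_clones = 1) {
  missing <- setdiff(c("cdr3_aa", "count"), names(clones))
  if (length(missing) > 0) {
    abort(paste0("clone table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(clones) < min_clones) {
    abort(sprintf("at least %d clone(s) required", min_clones))
  }
  if (any(!nzchar(clones$cdr3_aa))) abort("clone sequences must be non-empty")
  if (any(is.na(clones$count) | clones$count < 1)) {
    abort("clone counts must be positive")
  }
  invisible(clones)
}

#' Merge clones identical at the amino-acid level
#'
#' Nucleotide-distinct clonotypes translating to the same CDR3 amino-acid
#' sequence are merged, summing counts.
#'
#' @param clones Tibble with columns `cdr3_aa`, `count`.
#' @return Tibble with unique `cdr3_aa` and summed `count`.
#' @export
merge_clones <- function(clones) {
  .check_clones(clones)
  clones |>
    group_by(.data$cdr3_aa) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Downsample a repertoire to a fixed read count
#'
#' Draws `n` reads without replacement from the repertoire's reads
#' (multivariate hypergeometric over clones), emulating the fixed-depth
#' subsampling applied before diversity comparisons (e.g. 1e6 qualified
#' reads per sample). Clones reduced to zero reads are dropped.
#'
#' @param clones Tibble with columns `cdr3_aa`, `count`.
#' @param n Target total reads; must not exceed the current total (no
#'   upsampling).
#' @param seed Mandatory integer seed; same seed, same result.
#' @return Downsampled clone tibble with total count exactly `n`.
#' @export
tcr_downsample <- function(clones, n, seed) {
  clones <- merge_clones(clones)
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  total <- sum(clones$count)
  if (n > total) {
    abort(sprintf("cannot draw %s reads from %s (no upsampling)",
                  format(n, big.mark = ","), format(total, big.mark = ",")))
  }
  if (n == total) return(clones)
  breaks <- cumsum(clones$count)
  idx <- withr::with_seed(seed, sample.int(total, n))
  clone_of <- findInterval(idx - 1, breaks) + 1L
  counts <- tabulate(clone_of, nbins = nrow(clones))
  out <- clones
  out$count <- counts
  out[out$count > 0, , drop = FALSE]
}

#' Shannon diversity of a repertoire
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over clone frequencies
#' \eqn{p_i = count_i / total} (natural log).
#'
#' @param clones Tibble with columns `cdr3_aa`, `count`.
#' @return `H` in nats; 0 for a monoclonal repertoire, `ln(n)` at uniformity.
#' @examples
#' tcr_shannon(tibble::tibble(cdr3_aa = c("CASSA", "CASSB"), count = c(1, 1)))
#' @export
tcr_shannon <- function(clones) {
  clones <- merge_clones(clones)
  p <- clones$count / sum(clones$count)
  -sum(p * log(p))
}

#' Repertoire clonality
#'
#' `1 - H / ln(n)` where `n` is the number of productive unique sequences:
#' 0 for a perfectly even repertoire, approaching 1 under clonal dominance.
#' A single-clone repertoire is defined as maximally clonal (1), the limit as
#' evenness vanishes.
#'
#' @inheritParams tcr_shannon
#' @return Clonality in \[0, 1\].
#' @export
tcr_clonality <- function(clones) {
  clones <- merge_clones(clones)
  n <- nrow(clones)
  if (n == 1) return(1)
  1 - tcr_shannon(clones) / log(n)
}

#' Change in clonality between timepoints
#'
#' `clonality(followup) - clonality(baseline)`. When both tables carry a
#' `patient_id` column the ids must agree.
#'
#' @param baseline,followup Clone tibbles for the two timepoints.
#' @return Signed clonality change.
#' @export
tcr_clonality_delta <- function(baseline, followup) {
  pid <- function(x) if ("patient_id" %in% names(x))
    unique(x$patient_id) else NULL
  p1 <- pid(baseline); p2 <- pid(followup)
  if (!is.null(p1) && !is.null(p2) &&
      (length(p1) != 1 || length(p2) != 1 || p1 != p2)) {
    abort("baseline and follow-up repertoires belong to different patients")
  }
  tcr_clonality(followup) - tcr_clonality(baseline)
}

.top_clones <- function(clones, n) {
  clones |>
    arrange(desc(.data$count), .data$cdr3_aa) |>
    head(n)
}

#' Edit-distance summary of the top clones
#'
#' Selects the `top_n` most abundant clones (ties broken lexicographically by
#' sequence for reproducibility) and computes Levenshtein distances between
#' all CDR3 pairs. Levenshtein is used for the summary because CDR3 lengths
#' vary; the fixed-length Hamming rule is reserved for
#' [tcr_similarity_network()]. `summary = "nearest"` averages each clone's
#' nearest-neighbour distance instead of all unordered pairs.
#'
#' @param clones Tibble with columns `cdr3_aa`, `count` (>= 2 clones after
#'   merging).
#' @param top_n Number of top clones to keep (default 30).
#' @param summary `"all_pairs"` (default) or `"nearest"`.
#' @return An object of class `tcr_edit_summary`: `clones` (tibble),
#'   `matrix` (symmetric integer distance matrix), `mean`, `median`.
#'   `tidy()` returns the pair list.
#' @export
tcr_edit_distance <- function(clones, top_n = 30,
                              summary = c("all_pairs", "nearest")) {
  summary <- match.arg(summary)
  clones <- merge_clones(clones)
  .check_clones(clones, min_clones = 2)
  top <- .top_clones(clones, top_n)
  d <- adist(top$cdr3_aa)
  dimnames(d) <- list(top$cdr3_aa, top$cdr3_aa)
  pairs <- d[upper.tri(d)]
  vals <- if (summary == "all_pairs") {
    pairs
  } else {
    diag(d) <- NA
    apply(d, 1, min, na.rm = TRUE)
  }
  structure(list(
    clones = top,
    matrix = d,
    summary = summary,
    mean = mean(vals),
    median = median(vals)
  ), class = "tcr_edit_summary")
}

#' @export
print.tcr_edit_summary <- function(x, ...) {
  cat(sprintf("Edit distances over top %d clones (%s): mean %.3f, median %.3f\n",
              nrow(x$clones), x$summary, x$mean, x$median))
  invisible(x)
}

#' @export
tidy.tcr_edit_summary <- function(x, ...) {
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(
    cdr3_a = rownames(x$matrix)[idx[, 1]],
    cdr3_b = colnames(x$matrix)[idx[, 2]],
    distance = x$matrix[idx]
  )
}

#' @export
glance.tcr_edit_summary <- function(x, ...) {
  tibble(n_clones = nrow(x$clones), mean = x$mean, median = x$median,
         summary = x$summary)
}

#' CDR3 similarity network under a substitution bound
#'
#' Connects CDR3 sequences of equal length whose Hamming distance is at most
#' `max_subs` substitutions (default 3); sequences of unequal length are
#' never connected. Undirected, no self-edges.
#'
#' @param clones Tibble with columns `cdr3_aa`, `count` (>= 2 clones).
#' @param max_subs Maximum substitutions for an edge.
#' @return Tibble of edges: `cdr3_a`, `cdr3_b`, `distance`.
#' @export
tcr_similarity_network <- function(clones, max_subs = 3) {
  clones <- merge_clones(clones)
  .check_clones(clones, min_clones = 2)
  seqs <- clones$cdr3_aa
  n <- length(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  edges <- list()
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (lens[i] != lens[j]) next
      h <- sum(chars[[i]] != chars[[j]])
      if (h <= max_subs) {
        k <- k + 1
        edges[[k]] <- tibble(cdr3_a = seqs[i], cdr3_b = seqs[j], distance = h)
      }
    }
  }
  if (k == 0) {
    return(tibble(cdr3_a = character(), cdr3_b = character(),
                  distance = integer()))
  }
  bind_rows(edges)
}

#' Repertoire metric panel
#'
#' Convenience wrapper returning diversity, clonality and clone count in one
#' row, e.g. for joining into a per-patient feature table.
#'
#' @inheritParams tcr_shannon
#' @return One-row tibble: `n_clones`, `total_reads`, `shannon`, `clonality`.
#' @export
tcr_metrics <- function(clones) {
  clones <- merge_clones(clones)
  tibble(
    n_clones = nrow(clones),
    total_reads = sum(clones$count),
    shannon = tcr_shannon(clones),
    clonality = tcr_clonality(clones)
  )
}
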