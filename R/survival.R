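# Survival contracts behind the score: Cox hazard ratios, Kaplan-Meier with
# log-rank, the HR-minimizing cut-off scan, and HLA-LOH stratification.
# Model fitting is delegated to the survival package; this file owns the
# group conventions, the scan and its tie-breaking.

.as_high_low <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(x, "high", "low")
  } else if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      abort("numeric group labels must be 0 (low) / 1 (high)")
    }
    out <- ifelse(x == 1, "high", "low")
  } else {
    out <- as.character(x)
    if (!all(out %in% c("high", "low"))) {
      abort('character group labels must be "high" / "low"')
    }
  }
  factor(out, levels = c("low", "high"))
}

.check_surv_inputs <- function(data, time, event, group) {
  for (nm in c(time, event, group)) {
    if (!nm %in% names(data)) {
      abort(paste0("column `", nm, "` not found in the clinical table"))
    }
  }
  if (any(data[[time]] < 0, na.rm = TRUE)) abort("survival times must be >= 0")
  if (!all(data[[event]] %in% c(0, 1))) {
    abort("event indicators must be 0 (censored) / 1 (event)")
  }
  g <- .as_high_low(data[[group]])
  if (any(table(g) == 0)) {
    abort("both groups (high and low) must be non-empty")
  }
  if (sum(data[[event]]) == 0) {
    abort("no events in the cohort; hazard models are undefined")
  }
  g
}

#' Cox proportional-hazards ratio for a binary grouping
#'
#' Fits `Surv(time, event) ~ group (+ covariates)` and reports the hazard
#' ratio of the `"high"` group versus `"low"`, its 95% confidence interval
#' and Wald p-value. An HR below 1 means the high group has lower hazard
#' (longer survival).
#'
#' @param data Clinical tibble.
#' @param group Name of the grouping column; logical (`TRUE` = high), 0/1, or
#'   `"high"`/`"low"`.
#' @param time,event Column names for follow-up time (months) and the event
#'   indicator (1 = event, 0 = censored).
#' @param adjust Optional character vector of covariate column names included
#'   additively (multivariable mode).
#' @return One-row tibble: `hr`, `ci_low`, `ci_high`, `p`, `n_high`, `n_low`,
#'   `n_events`.
#' @export
cox_hr <- function(data, group, time = "os_months", event = "os_event",
                   adjust = NULL) {
  g <- .check_surv_inputs(data, time, event, group)
  if (min(table(g)) < 2) abort("each group needs at least 2 patients")
  df <- as.data.frame(data)
  df$.group <- g
  rhs <- c(".group", adjust)
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                ") ~ ", paste(rhs, collapse = " + ")))
  fit <- survival::coxph(f, data = df)
  s <- summary(fit)
  i <- grep("^\\.grouphigh$", rownames(s$coefficients))
  tibble(
    hr = unname(s$conf.int[i, "exp(coef)"]),
    ci_low = unname(s$conf.int[i, "lower .95"]),
    ci_high = unname(s$conf.int[i, "upper .95"]),
    p = unname(s$coefficients[i, "Pr(>|z|)"]),
    n_high = sum(g == "high"),
    n_low = sum(g == "low"),
    n_events = sum(df[[event]])
  )
}

#' Kaplan-Meier medians and log-rank test for two groups
#'
#' Product-limit survival per group with the log-rank test. The median is the
#' standard Kaplan-Meier convention: the first time the survival estimate
#' drops to or below 0.5, with the midpoint reported when the curve sits
#' exactly at 0.5 over an interval; an undefined median (curve never reaches
#' 0.5) is reported as `NA` ("not reached").
#'
#' @inheritParams cox_hr
#' @return An object of class `haps_km` with elements `medians` (tibble:
#'   `group`, `n`, `events`, `median`), `p` (log-rank p-value) and `fit` (the
#'   underlying `survfit`). `tidy()`, `glance()` and `autoplot()` methods are
#'   provided.
#' @export
km_logrank <- function(data, group, time = "os_months", event = "os_event") {
  g <- .check_surv_inputs(data, time, event, group)
  if (min(table(g)) < 2) abort("each group needs at least 2 patients")
  df <- as.data.frame(data)
  df$.group <- g
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                ") ~ .group"))
  fit <- survival::survfit(f, data = df)
  sd <- survival::survdiff(f, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  tab <- summary(fit)$table
  medians <- tibble(
    group = sub("^\\.group=", "", rownames(tab)),
    n = unname(tab[, "records"]),
    events = unname(tab[, "events"]),
    median = unname(tab[, "median"])
  )
  structure(list(medians = medians, p = p, fit = fit),
            class = "haps_km")
}

#' @export
print.haps_km <- function(x, ...) {
  cat("Kaplan-Meier comparison\n")
  print(x$medians)
  cat(sprintf("log-rank p = %.4g\n", x$p))
  invisible(x)
}

#' @export
tidy.haps_km <- function(x, ...) x$medians

#' @export
glance.haps_km <- function(x, ...) {
  tibble(p_logrank = x$p, n = sum(x$medians$n),
         n_events = sum(x$medians$events))
}

# Improved Bonferroni-type approximation for the null distribution of a
# maximally selected standardized statistic over the quantile range
# (eps1, eps2) (Lausen & Schumacher / Miller & Siegmund).
.maxstat_p <- function(b, eps1, eps2) {
  if (b <= 1) return(1)
  span <- log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2)))
  p <- stats::dnorm(b) * (b - 1 / b) * span + 4 * stats::dnorm(b) / b
  min(max(p, 0), 1)
}

#' Scan score cut-offs for the hazard-ratio minimum
#'
#' Dichotomizes a continuous per-patient score at every candidate cut-off and
#' fits [cox_hr()] at each, mirroring the HR-curve procedure that fixed the
#' published HAPS cut-offs. The candidate grid is the set of unique score
#' values between the 10th and 90th percentiles, restricted to cut-offs
#' leaving at least `min_group_frac` of the cohort in each group. The chosen
#' cut-off minimizes the HR, with a one-standard-error tie rule: every
#' cut-off whose HR lies within one standard error (on the log scale, at the
#' minimizing cut-off) of the minimum is considered statistically tied, and
#' the tied cut-off closest to the cohort median score wins. Sampling noise
#' in a single-cohort HR is far larger than any fixed small percentage, so
#' tolerances below the SE would let noise dips pick the cut-off; the 1-SE
#' rule also reproduces the published practice of preferring an
#' almost-lowest-HR cut-off near the median score. Because the scan
#' maximizes over many correlated dichotomies, the existence of a cutpoint
#' is judged by the maximally-selected-statistic correction
#' (Lausen-Schumacher): when the corrected p-value of the maximal Wald
#' statistic is at or above 0.05 the selection is tagged
#' `"no significant cutpoint"`. Pointwise per-cut-off CIs are reported
#' uncorrected in the grid.
#'
#' @param data Clinical tibble containing the score column.
#' @param score Name of the continuous score column (e.g. `"haps"`).
#' @param time,event As in [cox_hr()].
#' @param min_group_frac Minimum fraction of the cohort per group (default
#'   0.10).
#' @param tie_tol `"1se"` (default) for the one-standard-error tie rule, or
#'   a numeric relative HR tolerance (e.g. `0.01`).
#' @return An object of class `haps_cutoff_scan`: `grid` (tibble of `cutoff`,
#'   `hr`, `se_log_hr`, `ci_low`, `ci_high`, `p`, `n_high`, `n_low`),
#'   `cutoff` (chosen), `hr` (at the chosen cut-off), `z_max` and
#'   `p_adjusted` (maximal Wald statistic and its corrected p-value),
#'   `rationale` (`"minimum HR"` or `"no significant cutpoint"`). `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
scan_cutoff <- function(data, score, time = "os_months", event = "os_event",
                        min_group_frac = 0.10, tie_tol = "1se") {
  if (!score %in% names(data)) {
    abort(paste0("column `", score, "` not found"))
  }
  s <- data[[score]]
  if (any(!is.finite(s))) abort("scores must be finite")
  n <- nrow(data)
  if (n < 20) abort("cut-off scanning needs at least 20 patients")
  if (length(unique(s)) < 2) abort("scores are constant; nothing to scan")
  if (sum(data[[event]]) == 0) abort("no events in the cohort")

  qs <- quantile(s, c(0.10, 0.90), names = FALSE, type = 7)
  grid <- sort(unique(s[s >= qs[1] & s <= qs[2]]))
  min_group <- max(2, ceiling(min_group_frac * n))
  admissible <- vapply(grid, function(cut) {
    nh <- sum(s >= cut)
    nh >= min_group && (n - nh) >= min_group
  }, logical(1))
  grid <- grid[admissible]
  if (length(grid) == 0) {
    abort("no admissible cut-offs after the group-size constraint")
  }

  # same estimator as cox_hr (survival's Efron partial likelihood), called
  # through coxph.fit to keep a dense grid fast
  y <- survival::Surv(data[[time]], data[[event]])
  rows <- purrr::map(grid, function(cut) {
    x <- matrix(as.numeric(s >= cut), ncol = 1)
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        x, y, strata = NULL, offset = NULL, init = 0,
        control = survival::coxph.control(), weights = NULL,
        method = "efron", rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients)) return(NULL)
    beta <- unname(fit$coefficients)
    se <- sqrt(unname(fit$var[1, 1]))
    tibble(
      cutoff = cut,
      hr = exp(beta),
      se_log_hr = se,
      ci_low = exp(beta - 1.96 * se),
      ci_high = exp(beta + 1.96 * se),
      p = 2 * stats::pnorm(-abs(beta / se)),
      n_high = sum(s >= cut),
      n_low = sum(s < cut)
    )
  })
  grid_tbl <- bind_rows(rows) |>
    select("cutoff", "hr", "se_log_hr", "ci_low", "ci_high", "p",
           "n_high", "n_low")
  if (nrow(grid_tbl) == 0) abort("no cut-off admitted a hazard-ratio fit")

  i_min <- which.min(grid_tbl$hr)
  hr_min <- grid_tbl$hr[i_min]
  tol_factor <- if (identical(tie_tol, "1se")) {
    exp(grid_tbl$se_log_hr[i_min])
  } else {
    1 + tie_tol
  }
  near <- grid_tbl[grid_tbl$hr <= hr_min * tol_factor, ]
  med <- median(s)
  chosen <- near$cutoff[which.min(abs(near$cutoff - med))]
  chosen_row <- grid_tbl[grid_tbl$cutoff == chosen, ][1, ]
  # The scan maximizes |z| over many correlated dichotomies, so a pointwise
  # CI excluding 1 somewhere is expected even under the null. Judge the
  # existence of a cutpoint by the maximally-selected-statistic correction
  # (Lausen-Schumacher approximation over the admissible quantile range).
  z_max <- max(abs(log(grid_tbl$hr)) / grid_tbl$se_log_hr)
  p_adj <- .maxstat_p(z_max, min_group_frac, 1 - min_group_frac)
  structure(list(
    grid = grid_tbl,
    cutoff = chosen,
    hr = chosen_row$hr,
    z_max = z_max,
    p_adjusted = p_adj,
    rationale = if (p_adj < 0.05) "minimum HR" else "no significant cutpoint",
    score = score,
    median_score = med
  ), class = "haps_cutoff_scan")
}

#' @export
print.haps_cutoff_scan <- function(x, ...) {
  cat(sprintf("Cut-off scan over %d candidates (%s)\n", nrow(x$grid),
              x$score))
  cat(sprintf("chosen cutoff %.4g (HR %.3f); %s\n", x$cutoff, x$hr,
              x$rationale))
  invisible(x)
}

#' @export
tidy.haps_cutoff_scan <- function(x, ...) x$grid

#' @export
glance.haps_cutoff_scan <- function(x, ...) {
  tibble(cutoff = x$cutoff, hr = x$hr, p_adjusted = x$p_adjusted,
         rationale = x$rationale, n_candidates = nrow(x$grid))
}

#' Classify HLA loss of heterozygosity per locus
#'
#' A locus is called LOH when the minor-allele copy number is below 0.5 and
#' the allelic-imbalance p-value is below 0.01 (conjunction of the two
#' published thresholds); `rule = "cn_only"` drops the imbalance requirement.
#'
#' @param loh Tibble with columns `patient_id`, `locus` (`"A"`, `"B"`,
#'   `"C"`), `minor_cn` (>= 0), `p_allelic_imbalance` (in \[0, 1\]). Every
#'   patient must carry one row per locus.
#' @param rule `"cn_and_p"` (default) or `"cn_only"`.
#' @param cn_threshold,p_threshold Thresholds (defaults 0.5 and 0.01).
#' @return `loh` with a `locus_status` column (`"LOH"`/`"intact"`).
#' @seealso [loh_patient_status()], [stratify_haps_loh()]
#' @export
classify_loh <- function(loh, rule = c("cn_and_p", "cn_only"),
                         cn_threshold = 0.5, p_threshold = 0.01) {
  rule <- match.arg(rule)
  required <- c("patient_id", "locus", "minor_cn", "p_allelic_imbalance")
  missing <- setdiff(required, names(loh))
  if (length(missing) > 0) {
    abort(paste0("LOH table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  counts <- table(loh$patient_id, factor(loh$locus, levels = c("A", "B", "C")))
  if (any(counts != 1)) {
    bad <- rownames(counts)[apply(counts != 1, 1, any)]
    abort(paste0("patient(s) with missing or duplicated locus entries: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(is.na(loh$minor_cn) | loh$minor_cn < 0)) {
    abort("`minor_cn` must be non-negative")
  }
  if (any(is.na(loh$p_allelic_imbalance) | loh$p_allelic_imbalance < 0 |
            loh$p_allelic_imbalance > 1)) {
    abort("`p_allelic_imbalance` must lie in [0, 1]")
  }
  is_loh <- loh$minor_cn < cn_threshold
  if (rule == "cn_and_p") {
    is_loh <- is_loh & loh$p_allelic_imbalance < p_threshold
  }
  loh |> mutate(locus_status = ifelse(is_loh, "LOH", "intact"))
}

#' Patient-level HLA-LOH status
#'
#' A patient is `"LOH"` when any classical class I locus is LOH.
#'
#' @param loh_classified Output of [classify_loh()].
#' @return Tibble with columns `patient_id`, `loh_status`.
#' @export
loh_patient_status <- function(loh_classified) {
  if (!"locus_status" %in% names(loh_classified)) {
    abort("input must come from classify_loh()")
  }
  loh_classified |>
    group_by(.data$patient_id) |>
    summarise(loh_status = ifelse(any(.data$locus_status == "LOH"),
                                  "LOH", "intact"),
              .groups = "drop")
}

#' Joint HAPS x HLA-LOH strata
#'
#' Combines the dichotomized score with patient-level LOH status. Four-mode
#' keeps all combinations; two-mode pools everything but
#' `"HAPShigh/HLAintact"` into `"other"` (intact presentation machinery plus
#' high presentation score versus the rest).
#'
#' @param haps_classified Tibble with `patient_id` and `haps_class` (from
#'   [classify_haps()]).
#' @param loh_status Tibble with `patient_id` and `loh_status` (from
#'   [loh_patient_status()]).
#' @param collapse `"four"` or `"two"`.
#' @return Tibble with columns `patient_id`, `haps_class`, `loh_status`,
#'   `stratum`.
#' @export
stratify_haps_loh <- function(haps_classified, loh_status,
                              collapse = c("four", "two")) {
  collapse <- match.arg(collapse)
  if (!"haps_class" %in% names(haps_classified)) {
    abort("`haps_classified` must carry a `haps_class` column")
  }
  if (!"loh_status" %in% names(loh_status)) {
    abort("`loh_status` must carry a `loh_status` column")
  }
  merged <- dplyr::full_join(
    select(haps_classified, "patient_id", "haps_class"),
    select(loh_status, "patient_id", "loh_status"),
    by = "patient_id")
  incomplete <- merged$patient_id[is.na(merged$haps_class) |
                                    is.na(merged$loh_status)]
  if (length(incomplete) > 0) {
    abort(paste0("patient(s) missing a HAPS class or LOH status: ",
                 paste(head(incomplete, 5), collapse = ", ")))
  }
  four <- paste0("HAPS", merged$haps_class, "/HLA",
                 ifelse(merged$loh_status == "LOH", "LOH", "intact"))
  merged$stratum <- if (collapse == "four") {
    four
  } else {
    ifelse(four == "HAPShigh/HLAintact", "HAPShigh/HLAintact", "other")
  }
  merged
}
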