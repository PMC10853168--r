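# ggplot2 visuals for the scan, ROC and Kaplan-Meier result objects.

#' @describeIn scan_cutoff Hazard-ratio curve over candidate cut-offs with
#'   95% CI ribbon and the chosen cut-off marked.
#' @param object A `haps_cutoff_scan`.
#' @param ... Unused.
#' @export
autoplot.haps_cutoff_scan <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$cutoff, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(object$score, "cut-off"),
                  y = "HR (high vs low, 95% CI)",
                  title = sprintf("Cut-off scan: chosen %.3g (%s)",
                                  object$cutoff, object$rationale)) +
    ggplot2::theme_minimal()
}

#' @describeIn youden_threshold ROC curve with the Youden-optimal point
#'   marked.
#' @param object A `haps_roc`.
#' @param ... Unused.
#' @export
autoplot.haps_roc <- function(object, ...) {
  grid <- object$grid |> arrange(.data$threshold)
  best <- grid[which.max(grid$youden), ]
  ggplot2::ggplot(grid, ggplot2::aes(x = 1 - .data$specificity,
                                     y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC %.3f); Youden threshold %.3g",
                                  object$auc, object$threshold)) +
    ggplot2::theme_minimal()
}

#' @describeIn km_logrank Kaplan-Meier step curves per group.
#' @param object A `haps_km`.
#' @param ... Unused.
#' @export
autoplot.haps_km <- function(object, ...) {
  fit <- object$fit
  strata <- rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  curve <- tibble(
    time = fit$time,
    surv = fit$surv,
    group = strata
  ) |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL,
                  title = sprintf("Kaplan-Meier (log-rank p = %.3g)",
                                  object$p)) +
    ggplot2::theme_minimal()
}
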