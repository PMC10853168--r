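# Three-factor response integration: a single-hidden-unit logistic network
# over (HAPS, TMB, TCR diversity) trained by resilient backpropagation on
# the sum-of-squared-errors criterion, thresholded at the Youden maximum.
#
# Architecture note: the reference parameterization carries one hidden
# intercept plus three input weights, and two output-layer parameters read
# as output bias and hidden-to-output weight; hence ONE logistic hidden
# unit feeding one logistic output. The frozen reference coefficients ship
# for forward-pass regression only and are not presented as retrainable
# truth.

.nn_features_default <- c("haps", "tmb", "tcr_diversity")

.as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("DCR", "PD"))) {
      abort('character labels must be "DCR" (benefit) / "PD"')
    }
    y <- as.integer(y == "DCR")
  }
  if (!all(y %in% c(0, 1))) abort("labels must be binary")
  if (length(unique(y)) < 2) {
    abort("both classes must be present")
  }
  as.integer(y)
}

#' Z-score standardization with stored parameters
#'
#' Fits per-feature means and standard deviations (`stats = NULL`) or applies
#' previously stored ones, so that validation data are scaled exactly as the
#' training data were.
#'
#' @param features Tibble of numeric feature columns.
#' @param feature_cols Columns to standardize.
#' @param stats `NULL` to fit, or a list with `center` and `scale` to apply.
#' @return List with `features` (standardized tibble), `center`, `scale`.
#' @export
nn_standardize <- function(features, feature_cols = .nn_features_default,
                           stats = NULL) {
  missing <- setdiff(feature_cols, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(features[, feature_cols])
  if (any(!is.finite(x))) abort("features must be finite")
  if (is.null(stats)) {
    if (nrow(x) < 2) abort("fitting standardization needs >= 2 patients")
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    flat <- feature_cols[scale == 0]
    if (length(flat) > 0) {
      abort(paste0("constant feature(s) cannot be standardized: ",
                   paste(flat, collapse = ", ")))
    }
  } else {
    center <- stats$center
    scale <- stats$scale
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  out <- features
  out[, feature_cols] <- as.data.frame(z)
  list(features = as_tibble(out), center = center, scale = scale)
}

.nn_forward <- function(z, pars) {
  h <- stats::plogis(pars$b_h + as.vector(z %*% pars$w_in))
  list(h = h, score = stats::plogis(pars$b_out + pars$w_out * h))
}

.nn_sse <- function(z, y, pars) {
  sum((.nn_forward(z, pars)$score - y)^2)
}

.nn_grad <- function(z, y, pars) {
  fw <- .nn_forward(z, pars)
  s <- fw$score
  h <- fw$h
  d_out <- 2 * (s - y) * s * (1 - s)
  d_h <- d_out * pars$w_out * h * (1 - h)
  c(
    w_in = as.vector(crossprod(z, d_h)),
    b_h = sum(d_h),
    w_out = sum(d_out * h),
    b_out = sum(d_out)
  )
}

#' Train the three-factor response network
#'
#' Standardizes the features, then minimizes the sum of squared errors of a
#' one-hidden-unit logistic network by resilient backpropagation (iRPROP-:
#' per-parameter step sizes grown by `eta_plus` while the gradient sign
#' persists and shrunk by `eta_minus` on a sign flip). Training stops when
#' the absolute change in SSE falls below `tol` or after `max_iter`
#' full-batch iterations. Initialization is seeded; the same seed gives
#' identical weights.
#'
#' @param features Tibble with the feature columns and the response column.
#' @param response Name of the label column; `"DCR"`/`"PD"` or 1/0
#'   (1 = benefit).
#' @param feature_cols Feature columns (default `haps`, `tmb`,
#'   `tcr_diversity`).
#' @param seed Mandatory integer seed for weight initialization.
#' @param max_iter Maximum full-batch iterations (default 20).
#' @param tol SSE-change stopping tolerance (default 0.01).
#' @param eta_plus,eta_minus,delta0,delta_max,delta_min Resilient-update
#'   hyperparameters.
#' @return An object of class `haps_nn`: weights (`w_in`, `b_h`, `w_out`,
#'   `b_out`), standardization (`center`, `scale`), `feature_cols`,
#'   `threshold` (unset; see [youden_threshold()]), `log` (per-iteration
#'   SSE), `converged`, `seed`. `predict()`, `tidy()` and `glance()` methods
#'   are provided.
#' @export
nn_train <- function(features, response = "response",
                     feature_cols = .nn_features_default,
                     seed, max_iter = 20, tol = 0.01,
                     eta_plus = 1.2, eta_minus = 0.5,
                     delta0 = 0.1, delta_max = 50, delta_min = 1e-6) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (!response %in% names(features)) {
    abort(paste0("response column `", response, "` not found"))
  }
  y <- .as_binary_label(features[[response]])
  if (nrow(features) < 10) {
    warn("fewer than 10 patients; the fit is unlikely to be stable")
  }
  std <- nn_standardize(features, feature_cols)
  z <- as.matrix(std$features[, feature_cols])

  p <- length(feature_cols)
  init <- withr::with_seed(seed, stats::runif(p + 3, -0.5, 0.5))
  theta <- setNames(init, c(paste0("w_in", seq_len(p)), "b_h", "w_out",
                            "b_out"))
  unpack <- function(th) list(w_in = th[seq_len(p)], b_h = th[p + 1],
                              w_out = th[p + 2], b_out = th[p + 3])

  delta <- rep(delta0, length(theta))
  g_prev <- rep(0, length(theta))
  sse_prev <- .nn_sse(z, y, unpack(theta))
  log_rows <- list(tibble(iter = 0L, sse = sse_prev))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- .nn_grad(z, y, unpack(theta))
    sign_change <- g * g_prev
    delta <- ifelse(sign_change > 0, pmin(delta * eta_plus, delta_max),
                    ifelse(sign_change < 0, pmax(delta * eta_minus,
                                                 delta_min), delta))
    g[sign_change < 0] <- 0
    theta <- theta - sign(g) * delta
    g_prev <- g
    sse <- .nn_sse(z, y, unpack(theta))
    log_rows[[it + 1]] <- tibble(iter = it, sse = sse)
    if (abs(sse - sse_prev) < tol) {
      converged <- TRUE
      sse_prev <- sse
      break
    }
    sse_prev <- sse
  }

  pars <- unpack(theta)
  structure(list(
    w_in = setNames(pars$w_in, feature_cols),
    b_h = unname(pars$b_h),
    w_out = unname(pars$w_out),
    b_out = unname(pars$b_out),
    center = std$center,
    scale = std$scale,
    feature_cols = feature_cols,
    threshold = NULL,
    log = bind_rows(log_rows),
    converged = converged,
    sse = sse_prev,
    seed = seed
  ), class = "haps_nn")
}

#' Frozen reference network
#'
#' The published coefficients of the three-factor model (hidden intercept
#' 1.9214; input weights 1.54006, 1.4383, 2.46875; output bias -0.42557 and
#' hidden-to-output weight -1.76532; decision threshold 0.436), wired into
#' the package's one-hidden-unit architecture with identity standardization.
#' Intended for forward-pass regression tests and for scoring features that
#' are already standardized; it is not a substitute for training on your own
#' cohort.
#'
#' @return A `haps_nn` object.
#' @examples
#' predict(nn_reference_model(),
#'         tibble::tibble(haps = 0, tmb = 0, tcr_diversity = 0))
#' @export
nn_reference_model <- function() {
  structure(list(
    w_in = setNames(c(1.54006, 1.4383, 2.46875), .nn_features_default),
    b_h = 1.9214,
    w_out = -1.76532,
    b_out = -0.42557,
    center = setNames(rep(0, 3), .nn_features_default),
    scale = setNames(rep(1, 3), .nn_features_default),
    feature_cols = .nn_features_default,
    threshold = 0.436,
    log = tibble(iter = integer(), sse = numeric()),
    converged = NA,
    sse = NA_real_,
    seed = NA_integer_
  ), class = "haps_nn")
}

#' Predict response scores from a fitted network
#'
#' @param object A `haps_nn` model.
#' @param newdata Tibble carrying the model's feature columns.
#' @param type `"score"` (default; value in (0, 1)) or `"class"`
#'   (`"DCR"`/`"PD"` using the model's threshold, which must be set).
#' @param ... Unused.
#' @return Numeric vector of scores, or character vector of classes.
#' @export
predict.haps_nn <- function(object, newdata, type = c("score", "class"),
                            ...) {
  type <- match.arg(type)
  std <- nn_standardize(newdata, object$feature_cols,
                        stats = list(center = object$center,
                                     scale = object$scale))
  z <- as.matrix(std$features[, object$feature_cols])
  score <- .nn_forward(z, object)$score
  if (type == "score") return(unname(score))
  if (is.null(object$threshold)) {
    abort("model has no decision threshold; run youden_threshold() first")
  }
  ifelse(score >= object$threshold, "DCR", "PD")
}

#' @export
print.haps_nn <- function(x, ...) {
  cat("Single-hidden-unit response network\n")
  cat("  input weights:", paste(sprintf("%s=%.4f", names(x$w_in), x$w_in),
                                collapse = ", "), "\n")
  cat(sprintf("  hidden intercept %.4f; output %.4f + %.4f * h\n",
              x$b_h, x$b_out, x$w_out))
  if (!is.null(x$threshold)) {
    cat(sprintf("  decision threshold %.3f\n", x$threshold))
  }
  invisible(x)
}

#' @export
tidy.haps_nn <- function(x, ...) {
  tibble(
    term = c(paste0("w_", names(x$w_in)), "b_hidden", "w_output", "b_output"),
    estimate = c(unname(x$w_in), x$b_h, x$w_out, x$b_out)
  )
}

#' @export
glance.haps_nn <- function(x, ...) {
  tibble(
    iterations = max(x$log$iter, 0),
    sse = x$sse,
    converged = x$converged,
    threshold = x$threshold %||% NA_real_,
    seed = x$seed
  )
}

.auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index decision threshold
#'
#' Evaluates sensitivity, specificity and Youden's
#' `J = sensitivity + specificity - 1` at every observed score (predicted
#' positive when `score >= threshold`) and returns the J-maximizing
#' threshold; ties resolve to the lowest threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (`"DCR"`/`"PD"`, 1/0 or logical; 1 = positive).
#' @return An object of class `haps_roc`: `grid` (tibble of `threshold`,
#'   `sensitivity`, `specificity`, `youden`), `threshold`, `j`, `auc`.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
youden_threshold <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` differ in length")
  }
  y <- .as_binary_label(labels)
  thresholds <- sort(unique(scores))
  grid <- purrr::map(thresholds, function(th) {
    pred <- scores >= th
    tibble(
      threshold = th,
      sensitivity = sum(pred & y == 1) / sum(y == 1),
      specificity = sum(!pred & y == 0) / sum(y == 0)
    )
  }) |>
    bind_rows() |>
    mutate(youden = .data$sensitivity + .data$specificity - 1)
  best <- which.max(grid$youden) # which.max returns the first (lowest) tie
  structure(list(
    grid = grid,
    threshold = grid$threshold[best],
    j = grid$youden[best],
    auc = .auc_rank(scores, y)
  ), class = "haps_roc")
}

#' @export
print.haps_roc <- function(x, ...) {
  cat(sprintf("Youden threshold %.4g (J = %.3f, AUC = %.3f)\n",
              x$threshold, x$j, x$auc))
  invisible(x)
}

#' @export
tidy.haps_roc <- function(x, ...) x$grid

#' @export
glance.haps_roc <- function(x, ...) {
  tibble(threshold = x$threshold, j = x$j, auc = x$auc)
}

#' Set a model's decision threshold from training data
#'
#' Convenience wrapper: scores `features` with the model, maximizes the
#' Youden index and stores the resulting threshold on the model.
#'
#' @param model A `haps_nn` model.
#' @param features Tibble with feature columns and the response column.
#' @param response Label column name.
#' @return The model with `threshold` set (and the `haps_roc` object in
#'   attribute `"roc"`).
#' @export
nn_calibrate_threshold <- function(model, features, response = "response") {
  scores <- predict(model, features)
  roc <- youden_threshold(scores, features[[response]])
  model$threshold <- roc$threshold
  attr(model, "roc") <- roc
  model
}

#' Permutation importance of the model's factors
#'
#' For each feature in turn, permutes that column `n_permutations` times
#' (seeded) and measures the mean drop in ranking AUC of the model's scores
#' against the labels. Features the model does not rely on drop the AUC by
#' approximately zero.
#'
#' @param model A fitted `haps_nn`.
#' @param features Tibble with feature columns and the response column.
#' @param response Label column name.
#' @param n_permutations Number of permutations per feature (default 100).
#' @param seed Mandatory integer seed.
#' @return Tibble of `feature`, `importance` (mean AUC drop), sorted
#'   descending; ties broken lexicographically.
#' @export
rank_importance <- function(model, features, response = "response",
                            n_permutations = 100, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (n_permutations < 1) abort("`n_permutations` must be at least 1")
  y <- .as_binary_label(features[[response]])
  base_auc <- .auc_rank(predict(model, features), y)
  n <- nrow(features)
  drops <- withr::with_seed(seed, {
    map_dbl(model$feature_cols, function(col) {
      perm_auc <- vapply(seq_len(n_permutations), function(k) {
        shuffled <- features
        shuffled[[col]] <- shuffled[[col]][sample.int(n)]
        .auc_rank(predict(model, shuffled), y)
      }, numeric(1))
      base_auc - mean(perm_auc)
    })
  })
  tibble(feature = model$feature_cols, importance = drops) |>
    arrange(desc(.data$importance), .data$feature)
}

#' Serialize a network to JSON
#'
#' Writes weights, standardization parameters, threshold, architecture tag,
#' seed and training log as explicit JSON fields; [read_nn_model()] restores
#' the model.
#'
#' @param model A `haps_nn` model.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_nn_model <- function(model, path) {
  payload <- list(
    architecture = "logistic-1-hidden-unit",
    feature_cols = model$feature_cols,
    w_in = as.list(model$w_in),
    b_h = model$b_h,
    w_out = model$w_out,
    b_out = model$b_out,
    center = as.list(model$center),
    scale = as.list(model$scale),
    threshold = model$threshold,
    seed = model$seed,
    converged = model$converged,
    sse = model$sse,
    log = model$log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Restore a network from JSON
#' @param path JSON file written by [write_nn_model()].
#' @return A `haps_nn` model.
#' @export
read_nn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$architecture, "logistic-1-hidden-unit")) {
    abort(paste0("unsupported architecture tag: ", p$architecture))
  }
  structure(list(
    w_in = setNames(unlist(p$w_in), p$feature_cols),
    b_h = p$b_h,
    w_out = p$w_out,
    b_out = p$b_out,
    center = setNames(unlist(p$center), p$feature_cols),
    scale = setNames(unlist(p$scale), p$feature_cols),
    feature_cols = p$feature_cols,
    threshold = p$threshold,
    log = as_tibble(p$log),
    converged = p$converged,
    sse = p$sse,
    seed = p$seed
  ), class = "haps_nn")
}
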