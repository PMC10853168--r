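# The three-factor integration network: standardization, resilient
# training, prediction, Youden thresholding, permutation importance.

make_features <- function(n, separation = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    tibble::tibble(
      haps = rnorm(n, y * separation),
      tmb = rnorm(n, y * separation),
      tcr_diversity = rnorm(n, y * separation),
      response = y
    )
  })
}

test_that("standardization fits, re-applies and rejects constant features", {
  f <- make_features(100, seed = 5)
  std <- nn_standardize(f)
  z <- as.matrix(std$features[, c("haps", "tmb", "tcr_diversity")])
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # applying stored parameters to the fitting set reproduces the transform
  again <- nn_standardize(f, stats = std)
  expect_equal(std$features, again$features)
  # already-standard data pass through nearly unchanged
  f2 <- f
  f2[, 1:3] <- as.data.frame(z)
  std2 <- nn_standardize(f2)
  expect_equal(std2$features, f2, tolerance = 1e-8)
  f$tmb <- 3
  expect_error(nn_standardize(f), "tmb")
})

test_that("reference forward pass reproduces the published coefficients' score", {
  model <- nn_reference_model()
  x0 <- tibble::tibble(haps = 0, tmb = 0, tcr_diversity = 0)
  s <- predict(model, x0)
  manual <- plogis(-0.42557 - 1.76532 * plogis(1.9214))
  expect_equal(s, manual, tolerance = 1e-12)
  expect_lt(abs(s - 0.1228), 1e-4)
  expect_identical(predict(model, x0, type = "class"), "PD")
})

test_that("scores are strictly decreasing in the hidden activation when the
           output weight is negative", {
  model <- nn_reference_model()
  expect_lt(model$w_out, 0)
  # all-positive weights: raising any input raises the hidden activation
  grid <- tibble::tibble(haps = seq(-3, 3, length.out = 25),
                         tmb = 0, tcr_diversity = 0)
  s <- predict(model, grid)
  expect_true(all(diff(s) < 0))
  # saturated hidden unit brackets intermediate scores
  lo <- predict(model, tibble::tibble(haps = 50, tmb = 50,
                                      tcr_diversity = 50))
  hi <- predict(model, tibble::tibble(haps = -50, tmb = -50,
                                      tcr_diversity = -50))
  expect_true(all(s > lo & s < hi))
})

test_that("prediction is invariant to row order and duplicates score equally", {
  model <- nn_reference_model()
  f <- make_features(30, seed = 6)
  s <- predict(model, f)
  expect_equal(predict(model, f[30:1, ]), s[30:1])
  dup <- f[c(1, 1), ]
  expect_equal(predict(model, dup)[1], predict(model, dup)[2])
})

test_that("training is deterministic under a fixed seed", {
  f <- make_features(60, separation = 1, seed = 7)
  m1 <- nn_train(f, seed = 11)
  m2 <- nn_train(f, seed = 11)
  expect_identical(m1[c("w_in", "b_h", "w_out", "b_out")],
                   m2[c("w_in", "b_h", "w_out", "b_out")])
  expect_identical(m1$log, m2$log)
  m3 <- nn_train(f, seed = 12)
  expect_false(identical(m1$w_in, m3$w_in))
})

test_that("training separates separable data and stays honest on null data", {
  sep <- make_features(200, separation = 2, seed = 8)
  fit <- nn_train(sep, seed = 21)
  auc_sep <- youden_threshold(predict(fit, sep), sep$response)$auc
  expect_gte(auc_sep, 0.95)

  aucs <- vapply(1:20, function(s) {
    nul <- make_features(200, separation = 0, seed = 100 + s)
    nul$response <- withr::with_seed(200 + s, sample(nul$response))
    fit <- nn_train(nul, seed = s)
    youden_threshold(predict(fit, nul), nul$response)$auc
  }, numeric(1))
  expect_gte(median(aucs), 0.45)
  expect_lte(median(aucs), 0.70)
})

test_that("training validates labels and logs its error trajectory", {
  f <- make_features(40, seed = 9)
  f$response <- 1
  expect_error(nn_train(f, seed = 1), "classes")
  f2 <- make_features(40, separation = 1, seed = 9)
  fit <- nn_train(f2, seed = 1)
  expect_gte(nrow(fit$log), 2)
  expect_identical(fit$log$iter[1], 0L)
  expect_true(all(is.finite(fit$log$sse)))
  f3 <- make_features(40, separation = 1, seed = 9)
  f3$response <- ifelse(f3$response == 1, "DCR", "PD")
  fit3 <- nn_train(f3, seed = 1)
  expect_identical(fit$w_in, fit3$w_in)
})

test_that("Youden threshold equals the brute-force scan", {
  withr::with_seed(41, {
    for (k in 1:50) {
      n <- sample(10:60, 1)
      scores <- round(runif(n), 2)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      res <- youden_threshold(scores, labels)
      ora <- youden_oracle(scores, labels)
      expect_equal(res$threshold, ora$threshold)
      expect_equal(res$j, ora$j)
    }
  })
})

test_that("Youden threshold closed cases", {
  # perfect separation: J = 1 at the lowest positive score
  res <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(res$j, 1)
  expect_equal(res$threshold, 0.8)
  expect_equal(res$auc, 1)
  res2 <- youden_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(res2$threshold, 0.6)
  expect_equal(res2$j, 1)
  # constant scores carry no information
  res3 <- youden_threshold(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(max(res3$grid$youden), 0)
  expect_error(youden_threshold(c(0.2, 0.8), c(1, 1)), "classes")
})

test_that("threshold calibration stores the Youden cut on the model", {
  f <- make_features(80, separation = 2, seed = 10)
  fit <- nn_train(f, seed = 3)
  fit <- nn_calibrate_threshold(fit, f)
  expect_true(fit$threshold > 0 && fit$threshold < 1)
  cls <- predict(fit, f, type = "class")
  expect_setequal(unique(cls), c("DCR", "PD"))
})

test_that("permutation importance ranks informative features first", {
  withr::with_seed(51, {
    n <- 300
    y <- rbinom(n, 1, 0.5)
    f <- tibble::tibble(
      haps = y + rnorm(n, 0, 0.1),   # label leaked into a feature
      tmb = rnorm(n),                # independent noise
      tcr_diversity = rnorm(n),
      response = y
    )
  })
  fit <- nn_train(f, seed = 5, max_iter = 40)
  imp <- rank_importance(fit, f, n_permutations = 30, seed = 61)
  expect_identical(imp$feature[1], "haps")
  noise_imp <- imp$importance[imp$feature %in% c("tmb", "tcr_diversity")]
  expect_true(all(abs(noise_imp) < 0.05))
  imp2 <- rank_importance(fit, f, n_permutations = 30, seed = 61)
  expect_identical(imp, imp2)
  expect_error(rank_importance(fit, f, n_permutations = 0, seed = 1), "1")
})

test_that("model JSON serialization round-trips", {
  f <- make_features(50, separation = 1, seed = 12)
  fit <- nn_calibrate_threshold(nn_train(f, seed = 9), f)
  path <- withr::local_tempfile(fileext = ".json")
  write_nn_model(fit, path)
  back <- read_nn_model(path)
  expect_equal(back$w_in, fit$w_in)
  expect_equal(back$b_h, fit$b_h)
  expect_equal(back$w_out, fit$w_out)
  expect_equal(back$b_out, fit$b_out)
  expect_equal(back$center, fit$center)
  expect_equal(back$scale, fit$scale)
  expect_equal(back$threshold, fit$threshold)
  expect_equal(predict(back, f), predict(fit, f))
})
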