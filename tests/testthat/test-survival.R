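# Cox/KM contracts, the cut-off scan, and LOH stratification.

test_that("Cox hazard ratio matches a direct partial-likelihood maximizer", {
  for (s in 1:20) {
    d <- random_survival_cohort(n = 40 + s, seed = 300 + s, hr = 0.6)
    # jitter away ties so the partial likelihood is unambiguous
    d$os_months <- d$os_months + seq_len(nrow(d)) * 1e-9
    res <- cox_hr(d, "grp")
    beta <- cox_beta_oracle(d$os_months, d$os_event, d$grp)
    expect_equal(log(res$hr), beta, tolerance = 1e-6)
  }
})

test_that("complementary labels give reciprocal hazard ratios", {
  d <- random_survival_cohort(n = 120, seed = 41, hr = 0.5)
  a <- cox_hr(d, "grp")
  d$flip <- 1 - d$grp
  b <- cox_hr(d, "flip")
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-8)
})

test_that("mirrored groups give HR 1 and a simulated 2x hazard is recovered", {
  base <- tibble::tibble(os_months = c(2, 5, 7, 11, 13, 17),
                         os_event = c(1, 1, 0, 1, 1, 0))
  d <- dplyr::bind_rows(dplyr::mutate(base, grp = 0),
                        dplyr::mutate(base, grp = 1))
  d$patient_id <- seq_len(nrow(d))
  expect_equal(cox_hr(d, "grp")$hr, 1, tolerance = 1e-8)

  big <- withr::with_seed(77, tibble::tibble(
    patient_id = 1:2000,
    grp = rep(0:1, each = 1000),
    os_months = rexp(2000, 0.05 * ifelse(rep(0:1, each = 1000) == 1, 2, 1)),
    os_event = 1
  ))
  expect_true(dplyr::between(cox_hr(big, "grp")$hr, 1.85, 2.15))
})

test_that("degenerate survival inputs error", {
  d <- random_survival_cohort(60, seed = 52)
  d$os_event <- 0
  expect_error(cox_hr(d, "grp"), "events")
  d2 <- random_survival_cohort(60, seed = 53)
  d2$grp <- 1
  expect_error(cox_hr(d2, "grp"), "non-empty")
})

test_that("adjusted Cox fit accepts additive covariates", {
  d <- random_survival_cohort(150, seed = 54, hr = 0.5)
  d$age <- withr::with_seed(1, rnorm(150, 60, 8))
  res <- cox_hr(d, "grp", adjust = "age")
  expect_true(is.finite(res$hr))
  expect_true(res$ci_low < res$hr & res$hr < res$ci_high)
})

test_that("KM medians follow the standard convention and log-rank matches the oracle", {
  # events at 2,4,6,8: the curve sits at 0.5 on [4,6), median = 5
  d <- tibble::tibble(
    patient_id = 1:8,
    os_months = rep(c(2, 4, 6, 8), 2),
    os_event = 1,
    grp = rep(c(0, 1), each = 4)
  )
  km <- km_logrank(d, "grp")
  expect_equal(km$medians$median, c(5, 5))
  expect_equal(km$p, 1, tolerance = 1e-8)

  for (s in 1:10) {
    d <- random_survival_cohort(n = 60, seed = 400 + s, hr = 0.5)
    d$os_months <- d$os_months + seq_len(nrow(d)) * 1e-9
    km <- km_logrank(d, "grp")
    expect_equal(km$p, logrank_p_oracle(d$os_months, d$os_event, d$grp),
                 tolerance = 1e-6)
  }
})

test_that("KM curves start at 1 and never increase; shifted groups order medians", {
  d <- random_survival_cohort(80, seed = 61)
  km <- km_logrank(d, "grp")
  for (i in seq_along(km$fit$strata)) {
    idx <- split(seq_along(km$fit$surv),
                 rep(seq_along(km$fit$strata), km$fit$strata))[[i]]
    s <- km$fit$surv[idx]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
  shifted <- tibble::tibble(
    patient_id = 1:12,
    os_months = c(c(2, 4, 6, 8, 10, 12), c(2, 4, 6, 8, 10, 12) + 20),
    os_event = 1,
    grp = rep(0:1, each = 6)
  )
  med <- km_logrank(shifted, "grp")$medians
  expect_lt(med$median[med$group == "low"], med$median[med$group == "high"])
})

test_that("not-reached medians are reported as NA", {
  d <- tibble::tibble(patient_id = 1:10,
                      os_months = c(1, rep(20, 4), 2, rep(25, 4)),
                      os_event = c(1, rep(0, 4), 1, rep(0, 4)),
                      grp = rep(0:1, each = 5))
  expect_true(all(is.na(km_logrank(d, "grp")$medians$median)))
})

test_that("cut-off scan recovers a generative threshold and respects its grid", {
  cfg <- cohort_config(n_patients = 400, seed = 71,
                       survival = list(hr_high = 0.4, censoring_rate = 0.2))
  pool <- simulate_alleles(cfg)
  hp <- compute_haps(
    hla_divergence(pool$genotypes, pool$alleles),
    tnb_per_locus(filter_binders(simulate_binding(pool$genotypes, cfg)),
                  pool$genotypes))
  clin <- simulate_survival(hp$haps, hp$patient_id, cfg)
  clin$haps <- hp$haps
  scan <- scan_cutoff(clin, "haps")
  theta <- median(hp$haps)
  grid <- sort(scan$grid$cutoff)
  expect_lte(abs(which(grid == scan$cutoff) - which.min(abs(grid - theta))),
             1)
  expect_identical(scan$rationale, "minimum HR")
  # chosen HR is the admissible minimum up to the 1-SE tie rule
  expect_lte(scan$hr,
             min(scan$grid$hr) * exp(scan$grid$se_log_hr[which.min(scan$grid$hr)]))
  # every admissible cutoff keeps >= 10% of the cohort per arm
  expect_true(all(pmin(scan$grid$n_high, scan$grid$n_low) >= 40))
})

test_that("cut-off scan rejects degenerate scores and collapses two-point grids", {
  d <- random_survival_cohort(100, seed = 81)
  d$score <- 1
  expect_error(scan_cutoff(d, "score"), "constant")
  d$score <- rep(c(0, 1), 50)
  scan <- scan_cutoff(d, "score")
  expect_identical(nrow(scan$grid), 1L)
  expect_identical(scan$cutoff, 1)
  expect_error(scan_cutoff(d[1:10, ], "score"), "20")
})

test_that("null scores are tagged as having no significant cutpoint", {
  hits <- 0
  for (s in 1:5) {
    d <- random_survival_cohort(300, seed = 500 + s)
    d$score <- withr::with_seed(600 + s, runif(300))
    scan <- scan_cutoff(d, "score")
    hits <- hits + (scan$rationale == "no significant cutpoint")
  }
  expect_gte(hits, 4)
})

test_that("LOH calls require both low copy number and allelic imbalance", {
  loh <- tibble::tibble(
    patient_id = rep(c("P1", "P2", "P3"), each = 3),
    locus = rep(c("A", "B", "C"), 3),
    minor_cn = c(0.4, 1, 1, 0.4, 1, 1, 1.0, 1, 1),
    p_allelic_imbalance = c(0.005, 0.5, 0.5, 0.02, 0.5, 0.5, 0.5, 0.5, 0.5)
  )
  res <- classify_loh(loh)
  expect_identical(res$locus_status[1], "LOH")    # cn 0.4, p 0.005
  expect_identical(res$locus_status[4], "intact") # cn 0.4, p 0.02
  expect_identical(res$locus_status[7], "intact") # cn 1.0, p 0.5
  cn_only <- classify_loh(loh, rule = "cn_only")
  expect_identical(cn_only$locus_status[4], "LOH")
  status <- loh_patient_status(res)
  expect_identical(status$loh_status, c("LOH", "intact", "intact"))
})

test_that("LOH classification demands complete locus coverage", {
  loh <- tibble::tibble(patient_id = "P1", locus = c("A", "B"),
                        minor_cn = 1, p_allelic_imbalance = 0.5)
  expect_error(classify_loh(loh), "P1")
})

test_that("joint strata cover four combinations and pool correctly in two-mode", {
  hapsc <- tibble::tibble(patient_id = paste0("P", 1:4),
                          haps_class = c("high", "high", "low", "low"))
  lohs <- tibble::tibble(patient_id = paste0("P", 1:4),
                         loh_status = c("intact", "LOH", "intact", "LOH"))
  four <- stratify_haps_loh(hapsc, lohs, collapse = "four")
  expect_setequal(four$stratum,
                  c("HAPShigh/HLAintact", "HAPShigh/HLALOH",
                    "HAPSlow/HLAintact", "HAPSlow/HLALOH"))
  two <- stratify_haps_loh(hapsc, lohs, collapse = "two")
  expect_identical(two$stratum[two$patient_id == "P1"],
                   "HAPShigh/HLAintact")
  expect_identical(two$stratum[two$patient_id == "P2"], "other")
  expect_error(stratify_haps_loh(hapsc[1:3, ], lohs), "P4")
})
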