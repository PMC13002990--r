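test_that("the weighted cost matches hand-computed residuals", {
  ds <- noiseless_dataset(sem = 0.5)
  # perfect agreement -> zero cost
  expect_equal(as.numeric(wlsCost(ds, defaultParameters())), 0,
               tolerance = 1e-10)
  # shift one observation by exactly its SEM -> cost 1
  ds1 <- ds
  ds1$observations$value[1] <- ds1$observations$value[1] + 0.5
  expect_equal(as.numeric(wlsCost(ds1, defaultParameters())), 1,
               tolerance = 1e-6)
  # the printed toy: y = (1,2,3), sem = (0.5,0.5,1), yhat = (1.5,2,2) -> 2
  y <- c(1, 2, 3); sem <- c(0.5, 0.5, 1); yhat <- c(1.5, 2, 2)
  expect_equal(sum(((y - yhat) / sem)^2), 2.0)
})

test_that("the cost is order-invariant and additive over studies", {
  ds <- noiseless_dataset(sem = 0.3)
  obs <- ds$observations
  obs$value <- obs$value + c(0.3, -0.6, 0.9, 0.3)
  ds_a <- markerDataset(obs, ds$experiments)
  perm <- markerDataset(obs[c(3, 1, 4, 2), ], ds$experiments)
  expect_equal(as.numeric(wlsCost(ds_a, defaultParameters())),
               as.numeric(wlsCost(perm, defaultParameters())),
               tolerance = 1e-10)
  # per-study breakdown sums to the total
  obs2 <- obs
  obs2$study_id <- c("s1", "s1", "s2", "s2")
  ds2 <- markerDataset(obs2, ds$experiments)
  total <- wlsCost(ds2, defaultParameters())
  expect_equal(sum(attr(total, "per_study")), as.numeric(total),
               tolerance = 1e-12)
})

test_that("chi-square thresholds and test reproduce the published cutoffs", {
  expect_equal(chi2Threshold(0.05, 674), 735.5, tolerance = 5e-4)
  expect_equal(chi2Threshold(0.05, 20), 31.41, tolerance = 5e-4)
  expect_equal(chi2Threshold(0.05, 1), 3.841, tolerance = 5e-4)
  expect_error(chi2Threshold(1.5, 10), "alpha")
  expect_error(chi2Threshold(0.05, 0), "df")
  # monotonicity in df and alpha
  dfs <- c(1, 5, 20, 100, 674)
  expect_true(all(diff(vapply(dfs, chi2Threshold, 0, alpha = 0.05)) > 0))
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(vapply(alphas, function(a) chi2Threshold(a, 20), 0)) < 0))
  # the published costs pass, the boundary passes, above rejects
  expect_true(chi2Test(642.7, 674)$pass)
  expect_true(chi2Test(28.04, 20)$pass)
  expect_false(chi2Test(800, 674)$pass)
  expect_true(chi2Test(chi2Threshold(0.05, 20), 20)$pass)
})

test_that("the global optimiser recovers a known quadratic minimum", {
  # 2-parameter quadratic surrogate with minimum at (2, -1)
  fn <- function(x) (x[1] - 2)^2 + 2 * (x[2] + 1)^2 + 0.5
  res <- globalOptim(fn, lower = c(-5, -5), upper = c(5, 5), seed = 11,
                     budget = 3000)
  expect_equal(res$par, c(2, -1), tolerance = 1e-3)
  expect_equal(res$value, 0.5, tolerance = 1e-5)
  # reproducible under the same seed
  res2 <- globalOptim(fn, lower = c(-5, -5), upper = c(5, 5), seed = 11,
                      budget = 3000)
  expect_identical(res$par, res2$par)
  # bounds respected
  expect_true(all(res$par >= -5 & res$par <= 5))
})

test_that("parameter estimation improves the cost and respects bounds", {
  truth <- defaultParameters()
  ds <- noiseless_dataset(truth, sem = 0.3,
                          times = c(60, 120, 180, 240, 300))
  start <- truth
  start["VmaxADH"] <- truth[["VmaxADH"]] * 3
  fit <- estimateParameters(ds, "VmaxADH", start = start, seed = 7,
                            budget = 120)
  start_cost <- as.numeric(wlsCost(ds, start, rtol = 1e-6, atol = 1e-8))
  expect_lte(fit$cost, start_cost)
  b <- parameterBounds(); rownames(b) <- b$parameter
  expect_gte(fit$params[["VmaxADH"]], b["VmaxADH", "lower"])
  expect_lte(fit$params[["VmaxADH"]], b["VmaxADH", "upper"])
  expect_equal(fit$df, 5)
  # with zero noise the fit should home in near the truth
  expect_equal(fit$params[["VmaxADH"]], truth[["VmaxADH"]], tolerance = 0.2)
  expect_error(estimateParameters(ds, "VmaxADH"), "seed")
})

test_that("detection-limit filtering drops early conjugate observations", {
  sched <- short_protocol()
  an <- test_subject()
  obs <- data.frame(
    study_id = "s", experiment_id = "e",
    observable = rep(c("yEtG", "yEtS", "yEtOH"), each = 4),
    time_min = rep(c(15, 30, 75, 90), 3),
    value = 1, sem = 1, n = NA_real_)
  ds <- markerDataset(obs, list(e = list(schedule = sched, anthro = an)))
  f <- filterDetectionLimits(ds)
  kept <- f$observations
  expect_equal(kept$time_min[kept$observable == "yEtG"], 90)
  expect_equal(kept$time_min[kept$observable == "yEtS"], c(75, 90))
  expect_equal(kept$time_min[kept$observable == "yEtOH"], c(15, 30, 75, 90))
})

test_that("dataset validation enforces schema and SEM positivity", {
  sched <- short_protocol()
  an <- test_subject()
  exps <- list(e = list(schedule = sched, anthro = an))
  obs <- data.frame(study_id = "s", experiment_id = "e", observable = "yEtOH",
                    time_min = 60, value = 1, sem = 0.1)
  expect_s3_class(markerDataset(obs, exps), "markerDataset")
  bad <- obs; bad$sem <- 0
  expect_error(markerDataset(bad, exps), "SEM")
  bad <- obs; bad$observable <- "yNope"
  expect_error(markerDataset(bad, exps), "unknown observable")
  bad <- obs; bad$time_min <- 1e4
  expect_error(markerDataset(bad, exps), "horizon")
  expect_error(markerDataset(obs, list()), "missing schedules")
})
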