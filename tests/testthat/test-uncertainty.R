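# closed-form profile machinery for a weighted linear model y = a*t + b:
# the feasible set {V <= T} is an ellipsoid around the WLS solution, and the
# envelope of x' theta over it is yhat(t) +/- sqrt((T - Vmin) * x' H^-1 x)
linear_toy <- function() {
  t <- c(0, 2, 4, 6, 8)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  sem <- c(0.2, 0.2, 0.3, 0.3, 0.2)
  X <- cbind(1, t)
  W <- diag(1 / sem^2)
  H <- t(X) %*% W %*% X
  theta_hat <- solve(H, t(X) %*% W %*% y)
  V_min <- sum(((y - X %*% theta_hat) / sem)^2)
  cost_fn <- function(th) sum(((y - X %*% th) / sem)^2)
  list(t = t, y = y, sem = sem, X = X, H = H, theta_hat = drop(theta_hat),
       V_min = V_min, cost_fn = cost_fn)
}

test_that("the penalised bound reproduces the 1-D quadratic crossing", {
  cost_fn <- function(th) (th - 1)^2
  prop <- function(th) th
  thr <- chi2Threshold(0.05, 1) # 3.841
  lo <- profileBoundCore(cost_fn, prop, par0 = 1, "min", thr,
                         lower = -10, upper = 10, seed = 3, budget = 3000)
  hi <- profileBoundCore(cost_fn, prop, par0 = 1, "max", thr,
                         lower = -10, upper = 10, seed = 4, budget = 3000)
  expect_equal(lo$value, 1 - sqrt(thr), tolerance = 1e-2)
  expect_equal(hi$value, 1 + sqrt(thr), tolerance = 1e-2)
  expect_true(lo$feasible)
  expect_true(hi$feasible)
  # bounds never cross the feasible start value
  expect_lte(lo$value, 1)
  expect_gte(hi$value, 1)
  # with no binding constraint the objective is the bare property, so the
  # minimum runs to the search-box edge (the penalty really is 0 inside)
  free <- profileBoundCore(cost_fn, prop, par0 = 1, "min", threshold = 1e9,
                           lower = -10, upper = 10, seed = 5, budget = 3000)
  expect_equal(free$value, -10, tolerance = 1e-2)
  expect_error(profileBoundCore(cost_fn, prop, par0 = 50, "min", thr,
                                -10, 10, seed = 1), "infeasible")
})

test_that("penalised linear-model bands match the analytic envelope", {
  toy <- linear_toy()
  thr <- chi2Threshold(0.05, length(toy$y))
  Hinv <- solve(toy$H)
  for (t_star in c(1, 5, 9)) {
    x <- c(1, t_star)
    yhat <- sum(x * toy$theta_hat)
    half <- sqrt((thr - toy$V_min) * drop(t(x) %*% Hinv %*% x))
    prop <- function(th) sum(x * th)
    lo <- profileBoundCore(toy$cost_fn, prop, toy$theta_hat, "min", thr,
                           lower = c(-10, -10), upper = c(10, 10),
                           seed = 17, budget = 4000)
    hi <- profileBoundCore(toy$cost_fn, prop, toy$theta_hat, "max", thr,
                           lower = c(-10, -10), upper = c(10, 10),
                           seed = 18, budget = 4000)
    expect_equal(lo$value, yhat - half, tolerance = 0.02)
    expect_equal(hi$value, yhat + half, tolerance = 0.02)
  }
})

test_that("penalised bounds agree with brute-force grid search on a toy", {
  toy <- linear_toy()
  thr <- chi2Threshold(0.05, length(toy$y))
  # hard-constrained brute force over a parameter grid
  a_grid <- seq(toy$theta_hat[2] - 1, toy$theta_hat[2] + 1, by = 0.005)
  b_grid <- seq(toy$theta_hat[1] - 1, toy$theta_hat[1] + 1, by = 0.005)
  grid <- as.matrix(expand.grid(b = b_grid, a = a_grid))
  V <- apply(grid, 1, toy$cost_fn)
  feas <- grid[V <= thr, , drop = FALSE]
  t_star <- 5
  preds <- feas[, "b"] + t_star * feas[, "a"]
  prop <- function(th) th[1] + t_star * th[2]
  lo <- profileBoundCore(toy$cost_fn, prop, toy$theta_hat, "min", thr,
                         lower = c(-10, -10), upper = c(10, 10),
                         seed = 23, budget = 4000)
  expect_equal(lo$value, min(preds), tolerance = 0.02)
})

test_that("widening the threshold never narrows a parameter bound", {
  cost_fn <- function(th) (th - 1)^2
  prop <- function(th) th
  vals <- vapply(c(1, 4, 9), function(thr) {
    profileBoundCore(cost_fn, prop, 1, "min", thr, -10, 10,
                     seed = 9, budget = 2000)$value
  }, 0)
  expect_true(all(diff(vals) <= 1e-6))
})

test_that("ensemble prediction bands contain the best fit and are monotone in T", {
  truth <- defaultParameters()
  ds <- noiseless_dataset(truth, sem = 0.5, times = c(60, 120, 180, 240))
  grid <- c(30, 90, 150, 210)
  thr1 <- chi2Threshold(0.05, 4)
  band <- predictionBand(ds, "yEtOH", grid, threshold = thr1, start = truth,
                         free = c("VmaxADH", "k_EtOHuptake"), seed = 5,
                         n_ensemble = 100, budget = 40, sd_log10 = 0.08)
  expect_true(all(band$lower <= band$best + 1e-9))
  expect_true(all(band$upper >= band$best - 1e-9))
  expect_true(all(band$upper - band$lower >= 0))
  # same proposal stream, wider threshold -> superset of accepted draws
  band2 <- predictionBand(ds, "yEtOH", grid, threshold = 4 * thr1,
                          start = truth, free = c("VmaxADH", "k_EtOHuptake"),
                          seed = 5, n_ensemble = 100, budget = 40,
                          sd_log10 = 0.08)
  expect_true(all(band2$lower <= band$lower + 1e-9))
  expect_true(all(band2$upper >= band$upper - 1e-9))
})

test_that("per-time-point optimised bands bracket the ensemble bands", {
  truth <- defaultParameters()
  ds <- noiseless_dataset(truth, sem = 0.5, times = c(60, 120, 180, 240))
  grid <- c(90, 180)
  thr <- chi2Threshold(0.05, 4)
  ens <- predictionBand(ds, "yEtOH", grid, threshold = thr, start = truth,
                        free = "VmaxADH", seed = 21, n_ensemble = 20,
                        budget = 40)
  opt <- predictionBand(ds, "yEtOH", grid, threshold = thr, start = truth,
                        free = "VmaxADH", method = "optimize", seed = 21,
                        budget = 250)
  # the ensemble is an inner approximation of the profile band
  expect_true(all(opt$lower <= ens$lower + 1e-6))
  expect_true(all(opt$upper >= ens$upper - 1e-6))
  expect_true(all(opt$lower <= opt$best & opt$best <= opt$upper))
})

test_that("feasible samples respect the cost constraint", {
  truth <- defaultParameters()
  ds <- noiseless_dataset(truth, sem = 0.5)
  thr <- chi2Threshold(0.05, 4)
  draws <- feasibleParameterSample(ds, truth, free = "VmaxADH",
                                   threshold = thr, n = 5, seed = 2,
                                   max_tries = 30)
  expect_gte(length(draws), 1)
  costs <- vapply(draws, function(p) {
    as.numeric(wlsCost(ds, p, rtol = 1e-6, atol = 1e-8))
  }, 0)
  expect_true(all(costs <= thr + 1e-9))
})
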