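test_that("population grids derive weight from BMI and height", {
  g <- populationGrid(populationSpec(n_grid = 2))
  expect_equal(min(g$weight[g$sex == "female"]), 18 * 1.5^2) # 40.5 kg
  expect_equal(max(g$weight[g$sex == "male"]), 32 * 1.95^2)  # 121.68 kg
  expect_true(all(g$age >= 20 & g$age <= 80))
  expect_true(all(g$bmi >= 18 & g$bmi <= 32))
  expect_true(all(g$height[g$sex == "female"] <= 1.8))
  expect_true(all(g$height[g$sex == "male"] >= 1.6))
})

test_that("a fixed absolute dose hits small individuals harder", {
  sw <- populationSweep(populationSpec(n_grid = 2),
                        buildWangProtocol(horizon = 360),
                        t_grid = seq(0, 360, 10))
  ind <- sw$individuals
  # peak BAC is non-increasing in TBW within each sex
  for (sx in unique(ind$sex)) {
    i <- ind[ind$sex == sx, ]
    i <- i[order(i$TBW_L), ]
    expect_true(all(diff(i$peak_BAC) <= 1e-9))
  }
  expect_lt(stats::cor(ind$TBW_L, ind$peak_BAC, method = "spearman"), -0.8)
  # identical anthropometrics (age only differs via TBW) give identical
  # trajectories for identical TBW inputs: determinism of the sweep
  sw2 <- populationSweep(populationSpec(n_grid = 2),
                         buildWangProtocol(horizon = 360),
                         t_grid = seq(0, 360, 10))
  expect_equal(sw$individuals$peak_BAC, sw2$individuals$peak_BAC)
})

make_band <- function(times, lower, upper) {
  structure(list(observable = "yEtOH", times = times, lower = lower,
                 upper = upper, best = (lower + upper) / 2),
            class = "uncertaintyBand")
}

test_that("deviation intervals implement non-overlap after the last drink", {
  tt <- seq(0, 200, 10)
  a <- make_band(tt, rep(1, 21), rep(2, 21))
  # identical bands -> empty
  expect_equal(nrow(deviationIntervals(a, a)[[1]]), 0)
  # constant disjoint bands -> the whole window
  b <- make_band(tt, rep(3, 21), rep(4, 21))
  iv <- deviationIntervals(a, b, window_start = 0)[[1]]
  expect_equal(nrow(iv), 1)
  expect_equal(unname(iv[1, ]), c(0, 200))
  # piecewise case: A = [1,2] before t=100 then [1,5]; B = [4,6] throughout
  lowA <- rep(1, 21); upA <- ifelse(tt < 100, 2, 5)
  a2 <- make_band(tt, lowA, upA)
  b2 <- make_band(tt, rep(4, 21), rep(6, 21))
  iv2 <- deviationIntervals(a2, b2, window_start = 0)[[1]]
  expect_equal(nrow(iv2), 1)
  expect_equal(unname(iv2[1, 1]), 0)
  expect_equal(unname(iv2[1, 2]), 90) # last grid point before the overlap
  # window clipping
  iv3 <- deviationIntervals(a2, b2, window_start = 50)[[1]]
  expect_equal(unname(iv3[1, 1]), 50)
})

test_that("deviation intervals are symmetric and shrink with the margin", {
  tt <- seq(0, 100, 5)
  a <- make_band(tt, rep(1, 21), rep(2, 21))
  b <- make_band(tt, rep(2.5, 21), rep(4, 21))
  ab <- deviationIntervals(a, b)
  ba <- deviationIntervals(b, a)
  expect_equal(ab[[1]], ba[[1]])
  # margin 0 separates, margin 0.3 closes the 0.5 gap
  expect_equal(nrow(ab[[1]]), 1)
  expect_equal(nrow(deviationIntervals(a, b, margin = 0.3)[[1]]), 0)
  # mismatched grids rejected
  c_band <- make_band(seq(0, 100, 10), rep(1, 11), rep(2, 11))
  expect_error(deviationIntervals(a, c_band), "grids")
})

test_that("plausibility verdicts behave at the edges", {
  an <- test_subject()
  sched <- short_protocol(240)
  claimed <- list(schedule = sched, anthro = an)
  # empty sample list -> indeterminate
  empty <- plausibilityReport(claimed, data.frame(observable = character(0),
                                                  time_min = numeric(0),
                                                  value = numeric(0),
                                                  sem = numeric(0)))
  expect_equal(empty$verdict, "indeterminate")
  # noiseless self-generated samples -> all inside, consistent
  traj <- simulate(sched, an, t_grid = c(0, 60, 120, 180),
                   rtol = 1e-6, atol = 1e-8)
  idx <- match(c(60, 120, 180), traj$times)
  samples <- data.frame(
    observable = rep(c("yEtOH", "yUAC"), each = 3),
    time_min = rep(c(60, 120, 180), 2),
    value = c(traj$observables[idx, "yEtOH"], traj$observables[idx, "yUAC"]),
    sem = 0.5)
  rep1 <- plausibilityReport(claimed, samples)
  expect_true(all(rep1$samples$inside))
  expect_equal(rep1$verdict, "consistent")
  # grossly shifted samples -> inconsistent
  bad <- samples
  bad$value <- bad$value + 100
  rep2 <- plausibilityReport(claimed, bad)
  expect_equal(rep2$verdict, "inconsistent")
  # horizon check
  outside <- samples
  outside$time_min[1] <- 1e4
  expect_error(plausibilityReport(claimed, outside), "horizon")
})

test_that("self-generated noisy samples are overwhelmingly inside", {
  set.seed(42)
  an <- test_subject()
  sched <- short_protocol(240)
  claimed <- list(schedule = sched, anthro = an)
  tt <- c(60, 120, 180, 240)
  traj <- simulate(sched, an, t_grid = c(0, tt), rtol = 1e-6, atol = 1e-8)
  idx <- match(tt, traj$times)
  inside_total <- 0; n_total <- 0
  for (r in 1:20) {
    sem <- 0.05 * max(traj$observables[, "yEtOH"])
    samples <- data.frame(
      observable = "yEtOH", time_min = tt,
      value = traj$observables[idx, "yEtOH"] + stats::rnorm(length(tt), 0, sem),
      sem = sem)
    rep_r <- plausibilityReport(claimed, samples)
    inside_total <- inside_total + sum(rep_r$samples$inside)
    n_total <- n_total + nrow(samples)
  }
  expect_gte(inside_total / n_total, 0.9)
})
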