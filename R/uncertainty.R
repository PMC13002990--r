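#' Profile-style extremal bounds via L1-penalised relaxation
#'
#' An uncertainty bound for a scalar property (a parameter, or a model
#' prediction at one time point) is its extremal value subject to the weighted
#' cost staying below the chi-square threshold. The hard constraint is relaxed
#' into the objective as an L1 penalty with an offset:
#' minimise `p + penalty` where `penalty = |p| + |p0| * (1 + (V - T))` whenever
#' `V > T` and 0 otherwise (`p0` is the property value at the feasible start).
#' Maximisation substitutes `p` with `-p`. The penalty is non-smooth, so the
#' problems are solved with the same bounded global optimiser used for
#' estimation, warm-started from the feasible start.
#'
#' `profileBoundCore()` works on an arbitrary cost/property pair and is the
#' computational kernel; [profileParameterBound()] and [predictionBand()] are
#' the model-facing interfaces.
#'
#' @param cost_fn function of the search vector returning the cost V.
#' @param property_fn function of the search vector returning the scalar
#'   property p.
#' @param par0 feasible start (numeric vector) with `cost_fn(par0) <=
#'   threshold`.
#' @param direction `"min"` or `"max"`.
#' @param threshold the chi-square cost threshold T.
#' @param lower,upper search box.
#' @param seed integer seed.
#' @param budget objective-evaluation budget.
#' @param constraint_tol accepted relative constraint violation at the
#'   reported bound (default 0.1% of T).
#' @param refine_coord optional index of a search coordinate that coincides
#'   with the property (as when bounding a parameter): after the global
#'   search, the feasibility crossing along that coordinate is sharpened by
#'   bisection, which resolves needle-shaped feasible sets that a sampling
#'   optimiser cannot.
#' @return list with `value` (the bound), `par`, `cost` (cost at the bound),
#'   `feasible` (cost within `threshold * (1 + constraint_tol)`), `direction`.
#' @export
profileBoundCore <- function(cost_fn, property_fn, par0,
                             direction = c("min", "max"), threshold,
                             lower, upper, seed, budget = 600,
                             constraint_tol = 1e-3, refine_coord = NULL) {
  direction <- match.arg(direction)
  V0 <- cost_fn(par0)
  if (!is.finite(V0) || V0 > threshold) {
    stop("infeasible start: cost at par0 (", format(V0),
         ") exceeds the threshold (", format(threshold), ")")
  }
  sgn <- if (direction == "min") 1 else -1
  p0 <- sgn * property_fn(par0)
  objective <- function(x) {
    V <- cost_fn(x)
    if (!is.finite(V)) return(Inf)
    p <- sgn * property_fn(x)
    if (V > threshold) {
      p + abs(p) + abs(p0) * (1 + (V - threshold))
    } else {
      p
    }
  }
  res <- globalOptim(objective, lower, upper, seed = seed, budget = budget,
                     start = par0)
  # the start itself is always a valid (feasible) candidate
  if (objective(par0) < res$value) res$par <- par0
  if (!is.null(refine_coord)) {
    res$par <- refineCrossing(cost_fn, res$par, par0, refine_coord,
                              if (direction == "min") -1 else 1,
                              threshold, lower, upper)
  }
  Vb <- cost_fn(res$par)
  val <- property_fn(res$par)
  # never report a bound on the wrong side of the feasible start value
  if (direction == "min") val <- min(val, property_fn(par0)) else {
    val <- max(val, property_fn(par0))
  }
  list(value = val, par = res$par, cost = Vb,
       feasible = is.finite(Vb) && Vb <= threshold * (1 + constraint_tol),
       direction = direction)
}

# sharpen the feasibility crossing V = T along one coordinate by expansion
# then bisection; x_cand (global-search result) and x0 (feasible start) seed
# the search, dir is -1/+1 for the lower/upper crossing
refineCrossing <- function(cost_fn, x_cand, x0, j, dir, threshold,
                           lower, upper, iters = 40L) {
  x0 <- as.numeric(x0); x_cand <- as.numeric(x_cand)
  feas <- if (is.finite(cost_fn(x_cand)) && cost_fn(x_cand) <= threshold &&
              dir * x_cand[j] > dir * x0[j]) x_cand else x0
  edge <- if (dir < 0) lower[j] else upper[j]
  # expand towards the box edge until infeasible (or the edge is feasible)
  step <- max(abs(edge - feas[j]) * 1e-3, 1e-8)
  infeas <- NULL
  while (is.null(infeas)) {
    xt <- feas
    xt[j] <- feas[j] + dir * step
    if (dir * xt[j] >= dir * edge) {
      xt[j] <- edge
      if (cost_fn(xt) <= threshold) return(xt) # feasible all the way
      infeas <- xt
      break
    }
    if (cost_fn(xt) <= threshold) {
      feas <- xt
      step <- step * 2
    } else {
      infeas <- xt
    }
  }
  for (i in seq_len(iters)) {
    xm <- feas
    xm[j] <- (feas[j] + infeas[j]) / 2
    if (cost_fn(xm) <= threshold) feas <- xm else infeas <- xm
  }
  feas
}

#' Profile bound for a model parameter
#'
#' @param dataset a [markerDataset()].
#' @param m parameter name to bound.
#' @param direction `"min"` or `"max"`.
#' @param threshold chi-square cost threshold; defaults to
#'   `chi2Threshold(0.05, nrow(observations))`.
#' @param start feasible full parameter vector (e.g. a fit result).
#' @param free parameters allowed to vary (must include `m`); defaults to `m`
#'   alone.
#' @param bounds estimation box, as from [parameterBounds()].
#' @param seed integer seed.
#' @param budget objective-evaluation budget.
#' @param rtol,atol integrator tolerances for the cost.
#' @return as [profileBoundCore()], with `value` on the natural parameter
#'   scale.
#' @export
profileParameterBound <- function(dataset, m, direction = c("min", "max"),
                                  threshold = NULL, start = defaultParameters(),
                                  free = m, bounds = parameterBounds(),
                                  seed, budget = 300,
                                  rtol = 1e-6, atol = 1e-8) {
  direction <- match.arg(direction)
  stopifnot(m %in% free, all(free %in% names(start)))
  if (is.null(threshold)) {
    threshold <- chi2Threshold(0.05, nrow(dataset$observations))
  }
  rownames(bounds) <- bounds$parameter
  lo <- log10(bounds[free, "lower"])
  hi <- log10(bounds[free, "upper"])
  assemble <- function(x) {
    p <- start
    p[free] <- 10^x
    p
  }
  cost_fn <- function(x) as.numeric(wlsCost(dataset, assemble(x),
                                            rtol = rtol, atol = atol))
  property_fn <- function(x) assemble(x)[[m]]
  x0 <- pmin(pmax(log10(start[free]), lo), hi)
  profileBoundCore(cost_fn, property_fn, x0, direction, threshold,
                   lo, hi, seed = seed, budget = budget,
                   refine_coord = match(m, free))
}

#' Time-resolved prediction uncertainty band
#'
#' For each time point the simulated observable is minimised and maximised
#' subject to the cost constraint. Two strategies are available:
#' `"optimize"` solves the penalised problem per time point (the reference
#' formulation; time points are independent, so results match sequential
#' evaluation); `"ensemble"` samples parameter vectors from the feasible set
#' (cost below the threshold) and takes the pointwise envelope of their
#' simulations — a cheaper inner approximation of the same band, used for
#' scenario screening.
#'
#' @param dataset a [markerDataset()] defining the cost constraint.
#' @param observable observable name to band.
#' @param t_grid output times (min).
#' @param scenario list with `schedule` and `anthro` to simulate (defaults to
#'   the dataset's first experiment).
#' @param threshold chi-square cost threshold.
#' @param start feasible full parameter vector.
#' @param free parameters allowed to vary.
#' @param method `"ensemble"` (default) or `"optimize"`.
#' @param seed integer seed.
#' @param budget per-time-point evaluation budget (`"optimize"`) or feasible
#'   sampling attempts (`"ensemble"`).
#' @param n_ensemble ensemble size target.
#' @param sd_log10 log10-scale spread of the ensemble proposals.
#' @param bounds estimation box.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `uncertaintyBand`: list with `observable`,
#'   `times`, `lower`, `upper`, `best`.
#' @export
predictionBand <- function(dataset, observable, t_grid, scenario = NULL,
                           threshold = NULL, start = defaultParameters(),
                           free = NULL, method = c("ensemble", "optimize"),
                           seed, budget = 200, n_ensemble = 30,
                           sd_log10 = 0.05, bounds = parameterBounds(),
                           rtol = 1e-6, atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(observable %in% observableNames())
  if (is.null(scenario)) scenario <- dataset$experiments[[1]]
  if (is.null(threshold)) {
    threshold <- chi2Threshold(0.05, nrow(dataset$observations))
  }
  if (is.null(free)) {
    free <- c("VmaxADH", "k_EtOHuptake", "VmaxEtG", "VmaxEtS", "VmaxGastric")
  }
  simulate_obs <- function(params) {
    traj <- simulate(scenario$schedule, scenario$anthro, params,
                     t_grid = unique(c(0, t_grid)), rtol = rtol, atol = atol)
    idx <- match(t_grid, traj$times)
    traj$observables[idx, observable]
  }
  best <- simulate_obs(start)

  if (method == "ensemble") {
    draws <- feasibleParameterSample(dataset, start = start, free = free,
                                     threshold = threshold, n = n_ensemble,
                                     seed = seed, sd_log10 = sd_log10,
                                     max_tries = budget,
                                     rtol = rtol, atol = atol)
    sims <- vapply(draws, simulate_obs, numeric(length(t_grid)))
    sims <- cbind(best, sims)
    lower <- apply(sims, 1, min)
    upper <- apply(sims, 1, max)
  } else {
    rownames(bounds) <- bounds$parameter
    lo <- log10(bounds[free, "lower"])
    hi <- log10(bounds[free, "upper"])
    assemble <- function(x) { p <- start; p[free] <- 10^x; p }
    cost_fn <- function(x) as.numeric(wlsCost(dataset, assemble(x),
                                              rtol = rtol, atol = atol))
    x0 <- pmin(pmax(log10(start[free]), lo), hi)
    lower <- upper <- numeric(length(t_grid))
    for (j in seq_along(t_grid)) {
      prop <- function(x) simulate_obs(assemble(x))[j]
      bl <- profileBoundCore(cost_fn, prop, x0, "min", threshold, lo, hi,
                             seed = seed + j, budget = budget)
      bu <- profileBoundCore(cost_fn, prop, x0, "max", threshold, lo, hi,
                             seed = seed + j + 10000L, budget = budget)
      lower[j] <- bl$value
      upper[j] <- bu$value
    }
    lower <- pmin(lower, best)
    upper <- pmax(upper, best)
  }
  structure(list(observable = observable, times = t_grid,
                 lower = lower, upper = upper, best = best),
            class = "uncertaintyBand")
}

#' @export
print.uncertaintyBand <- function(x, ...) {
  cat(sprintf("uncertainty band for %s: %d time points, mean width %.3g\n",
              x$observable, length(x$times), mean(x$upper - x$lower)))
  invisible(x)
}

#' Sample parameter vectors from the feasible set
#'
#' Log-normal proposals around a feasible start, accepted when their cost
#' stays below the threshold. Always includes the start itself.
#'
#' @inheritParams predictionBand
#' @param n target number of accepted draws.
#' @param max_tries proposal budget.
#' @return list of named parameter vectors (length <= n + 1).
#' @export
feasibleParameterSample <- function(dataset, start, free, threshold, n = 30,
                                    seed, sd_log10 = 0.05, max_tries = 200,
                                    rtol = 1e-6, atol = 1e-8) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  draws <- list(start)
  tries <- 0
  while (length(draws) < n + 1 && tries < max_tries) {
    tries <- tries + 1
    p <- start
    p[free] <- 10^(log10(start[free]) + stats::rnorm(length(free), 0, sd_log10))
    v <- as.numeric(wlsCost(dataset, p, rtol = rtol, atol = atol))
    if (is.finite(v) && v <= threshold) draws[[length(draws) + 1]] <- p
  }
  draws
}

#' Export a band as a tidy table
#' @param band an [predictionBand()] result.
#' @param path optional CSV path.
#' @return data.frame with columns `observable`, `time_min`, `lower`, `upper`,
#'   `best`.
#' @export
bandToTable <- function(band, path = NULL) {
  df <- data.frame(observable = band$observable, time_min = band$times,
                   lower = band$lower, upper = band$upper, best = band$best,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
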