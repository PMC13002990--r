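#' Observation dataset
#'
#' Bundles a table of SEM-weighted observations with the per-experiment
#' schedules and anthropometrics needed to simulate them. Observations carry
#' a study id, an experiment id, the observable name (one of
#' [observableNames()]), the sampling time (min), the measured value, its
#' standard error of the mean and optionally the number of repeats.
#'
#' @param observations data.frame with columns `study_id`, `experiment_id`,
#'   `observable`, `time_min`, `value`, `sem` and optionally `n`.
#' @param experiments named list keyed by experiment id; each element is a
#'   list with `schedule` (an [inputSchedule()]) and `anthro`
#'   (an [anthropometrics()]).
#' @return an object of class `markerDataset`.
#' @export
markerDataset <- function(observations, experiments) {
  req <- c("study_id", "experiment_id", "observable", "time_min", "value", "sem")
  miss <- setdiff(req, names(observations))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"n" %in% names(observations)) observations$n <- NA_real_
  bad <- which(!observations$observable %in% observableNames())
  if (length(bad)) {
    stop("unknown observable(s) in rows ", paste(bad, collapse = ", "),
         "; allowed: ", paste(observableNames(), collapse = ", "))
  }
  bad <- which(!is.finite(observations$sem) | observations$sem <= 0)
  if (length(bad)) stop("non-positive SEM in rows ", paste(bad, collapse = ", "))
  miss_exp <- setdiff(unique(observations$experiment_id), names(experiments))
  if (length(miss_exp)) {
    stop("experiments missing schedules: ", paste(miss_exp, collapse = ", "))
  }
  for (eid in unique(observations$experiment_id)) {
    hor <- experiments[[eid]]$schedule$horizon
    tt <- observations$time_min[observations$experiment_id == eid]
    if (any(tt < 0 | tt > hor)) {
      stop("observation times outside horizon for experiment ", eid)
    }
  }
  structure(list(observations = observations, experiments = experiments),
            class = "markerDataset")
}

#' @export
print.markerDataset <- function(x, ...) {
  cat(sprintf("marker dataset: %d observations, %d experiment(s), %d study(ies)\n",
              nrow(x$observations), length(unique(x$observations$experiment_id)),
              length(unique(x$observations$study_id))))
  invisible(x)
}

#' Detection-limit exclusion filter
#'
#' EtG and EtS are reported as zero until they exceed the assay detection
#' limit; early time points are therefore excluded from estimation. The
#' defaults keep EtS observations only when time > 30 min and EtG only when
#' time > 75 min.
#'
#' @param dataset a [markerDataset()].
#' @param limits named numeric vector of per-observable start times (min);
#'   observations at `time_min <= limit` are dropped.
#' @return the filtered [markerDataset()].
#' @export
filterDetectionLimits <- function(dataset, limits = c(yEtS = 30, yEtG = 75)) {
  obs <- dataset$observations
  keep <- rep(TRUE, nrow(obs))
  for (nm in names(limits)) {
    keep <- keep & !(obs$observable == nm & obs$time_min <= limits[[nm]])
  }
  markerDataset(obs[keep, , drop = FALSE], dataset$experiments)
}

#' SEM-weighted least-squares cost
#'
#' `V(theta) = sum_i sum_k sum_j ((y - yhat) / SEM)^2` over studies i,
#' observables k and time points j. Each experiment is simulated once at the
#' union of its observation times. A failed simulation yields `+Inf` with the
#' failure message attached (optimiser-safe).
#'
#' @param dataset a [markerDataset()].
#' @param params named parameter vector.
#' @param rtol,atol integrator tolerances passed to [simulate()].
#' @return total cost (scalar) with attributes `per_study` (named breakdown)
#'   and `df` (number of observations).
#' @export
wlsCost <- function(dataset, params, rtol = 1e-8, atol = 1e-10) {
  obs <- dataset$observations
  resid2 <- numeric(nrow(obs))
  for (eid in unique(obs$experiment_id)) {
    rows <- which(obs$experiment_id == eid)
    ex <- dataset$experiments[[eid]]
    tt <- sort(unique(obs$time_min[rows]))
    traj <- try(simulate(ex$schedule, ex$anthro, params,
                         t_grid = unique(c(0, tt)), rtol = rtol, atol = atol),
                silent = TRUE)
    if (inherits(traj, "try-error")) {
      out <- Inf
      attr(out, "diagnostic") <- conditionMessage(attr(traj, "condition"))
      attr(out, "df") <- nrow(obs)
      return(out)
    }
    for (r in rows) {
      i <- which(abs(traj$times - obs$time_min[r]) < 1e-9)[1]
      yhat <- traj$observables[i, obs$observable[r]]
      resid2[r] <- ((obs$value[r] - yhat) / obs$sem[r])^2
    }
  }
  total <- sum(resid2)
  attr(total, "per_study") <- tapply(resid2, obs$study_id, sum)
  attr(total, "df") <- nrow(obs)
  total
}

#' Chi-square model-rejection threshold and test
#'
#' The model is rejected when the weighted cost exceeds the inverse
#' chi-square CDF at `1 - alpha` with degrees of freedom equal to the number
#' of data points (not reduced by the parameter count).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (number of observations), integer >= 1.
#' @return `chi2Threshold()`: the threshold value.
#' @examples
#' chi2Threshold(0.05, 674) # 735.5
#' chi2Threshold(0.05, 20)  # 31.41
#' @export
chi2Threshold <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(df) || df < 1 || df != round(df)) stop("df must be a positive integer")
  stats::qchisq(1 - alpha, df)
}

#' @rdname chi2Threshold
#' @param cost non-negative cost value to test.
#' @return `chi2Test()`: list with `pass` (TRUE unless cost strictly exceeds
#'   the threshold) and `threshold`.
#' @export
chi2Test <- function(cost, df, alpha = 0.05) {
  stopifnot(cost >= 0)
  thr <- chi2Threshold(alpha, df)
  list(pass = cost <= thr, threshold = thr)
}

#' Estimate model parameters against a dataset
#'
#' Global bounded minimisation of [wlsCost()] over a subset of parameters,
#' searched in log10 space (values span ten orders of magnitude). The
#' degrees of freedom of the resulting chi-square test equal the number of
#' observations.
#'
#' @param dataset a [markerDataset()].
#' @param free character vector of parameter names to estimate.
#' @param start named parameter vector used for the fixed parameters and as
#'   the optimiser start.
#' @param bounds data.frame as from [parameterBounds()].
#' @param method `"de"` (differential evolution) or `"sann"` (simulated
#'   annealing).
#' @param seed integer seed (mandatory).
#' @param budget approximate maximum number of cost evaluations.
#' @param alpha significance level of the chi-square test.
#' @param rtol,atol integrator tolerances used in the cost.
#' @param ... passed to [globalOptim()].
#' @return An object of class `fitResult`: list with `params` (full vector),
#'   `free`, `cost`, `df`, `threshold`, `pass`, `trace`, `evals`, `seed`.
#' @export
estimateParameters <- function(dataset, free, start = defaultParameters(),
                               bounds = parameterBounds(),
                               method = c("de", "sann"), seed, budget = 500,
                               alpha = 0.05, rtol = 1e-6, atol = 1e-8, ...) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(free %in% names(start)))
  rownames(bounds) <- bounds$parameter
  lo <- log10(bounds[free, "lower"])
  hi <- log10(bounds[free, "upper"])
  objective <- function(x) {
    p <- start
    p[free] <- 10^x
    as.numeric(wlsCost(dataset, p, rtol = rtol, atol = atol))
  }
  x0 <- pmin(pmax(log10(start[free]), lo), hi)
  start_cost <- objective(x0)
  res <- globalOptim(objective, lo, hi, seed = seed, budget = budget,
                     start = x0, method = method, ...)
  # the start is always a candidate: never return worse than where we began
  if (is.finite(start_cost) && start_cost < res$value) {
    res$par <- x0
    res$value <- start_cost
  }
  # local polish: the WLS cost is smooth in the parameters and often
  # needle-sharp on the log10 scale, which a coarse global search cannot
  # resolve; a short bounded local refinement around the incumbent fixes that
  polish <- try(if (length(free) == 1) {
    stats::optimize(objective,
                    lower = max(lo, res$par - 0.5),
                    upper = min(hi, res$par + 0.5), tol = 1e-7)
  } else {
    o <- stats::optim(res$par, function(x) objective(pmin(pmax(x, lo), hi)),
                      method = "Nelder-Mead",
                      control = list(maxit = max(50L, as.integer(budget / 2))))
    list(minimum = pmin(pmax(o$par, lo), hi), objective = o$value)
  }, silent = TRUE)
  if (!inherits(polish, "try-error") && is.finite(polish$objective) &&
      polish$objective < res$value) {
    res$par <- polish$minimum
    res$value <- polish$objective
  }
  p <- start
  p[free] <- 10^res$par
  df <- nrow(dataset$observations)
  test <- chi2Test(res$value, df, alpha)
  structure(list(params = p, free = free, cost = res$value, df = df,
                 threshold = test$threshold, pass = test$pass,
                 trace = res$trace, evals = res$evals, seed = seed),
            class = "fitResult")
}

#' @export
print.fitResult <- function(x, ...) {
  cat(sprintf("fit result: cost %.4g on df %d (threshold %.4g) -> %s\n",
              x$cost, x$df, x$threshold, if (x$pass) "pass" else "reject"))
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}
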