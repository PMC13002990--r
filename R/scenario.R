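#' Population specification for sensitivity sweeps
#'
#' Defaults span age 20--80 years, BMI 18--32 kg/m2, heights 1.5--1.8 m
#' (female) and 1.6--1.95 m (male). Body weight is derived as BMI x height^2.
#'
#' @param sexes sexes to include.
#' @param age_range,bmi_range numeric ranges.
#' @param height_range named list of per-sex height ranges (m).
#' @param n_grid points per axis for the full-factorial grid.
#' @param method `"grid"` (full factorial, default) or `"lhs"` (Latin
#'   hypercube; requires the lhs package).
#' @param n_sample sample count for `"lhs"`.
#' @param seed integer seed (used by `"lhs"`).
#' @return an object of class `populationSpec`.
#' @export
populationSpec <- function(sexes = c("male", "female"),
                           age_range = c(20, 80), bmi_range = c(18, 32),
                           height_range = list(female = c(1.5, 1.8),
                                               male = c(1.6, 1.95)),
                           n_grid = 3, method = c("grid", "lhs"),
                           n_sample = 20, seed = NULL) {
  method <- match.arg(method)
  stopifnot(diff(age_range) > 0, diff(bmi_range) > 0,
            all(vapply(height_range, diff, 0) > 0))
  structure(list(sexes = sexes, age_range = age_range, bmi_range = bmi_range,
                 height_range = height_range, n_grid = n_grid,
                 method = method, n_sample = n_sample, seed = seed),
            class = "populationSpec")
}

#' Enumerate the individuals of a population specification
#'
#' @param spec a [populationSpec()].
#' @return data.frame with columns `sex`, `age`, `bmi`, `height`, `weight`
#'   (`weight = bmi * height^2`).
#' @export
populationGrid <- function(spec) {
  out <- list()
  for (sex in spec$sexes) {
    hr <- spec$height_range[[sex]]
    if (spec$method == "grid") {
      g <- expand.grid(
        age = seq(spec$age_range[1], spec$age_range[2], length.out = spec$n_grid),
        bmi = seq(spec$bmi_range[1], spec$bmi_range[2], length.out = spec$n_grid),
        height = seq(hr[1], hr[2], length.out = spec$n_grid)
      )
    } else {
      if (!requireNamespace("lhs", quietly = TRUE)) {
        stop("method 'lhs' requires the lhs package")
      }
      if (is.null(spec$seed)) stop("seed required for lhs sampling")
      set.seed(as.integer(spec$seed))
      u <- lhs::randomLHS(spec$n_sample, 3)
      g <- data.frame(
        age = spec$age_range[1] + u[, 1] * diff(spec$age_range),
        bmi = spec$bmi_range[1] + u[, 2] * diff(spec$bmi_range),
        height = hr[1] + u[, 3] * diff(hr)
      )
    }
    g$sex <- sex
    out[[sex]] <- g
  }
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  g$weight <- g$bmi * g$height^2
  g[, c("sex", "age", "bmi", "height", "weight")]
}

#' Population sensitivity sweep
#'
#' Simulates a protocol for each individual of a population and annotates
#' each trajectory with the individual's total body water (TBW, L) — the main
#' axis along which a fixed absolute ethanol dose dilutes.
#'
#' @param spec a [populationSpec()].
#' @param protocol an [inputSchedule()] shared by all individuals, or a
#'   function of body weight returning one.
#' @param params named parameter vector.
#' @param t_grid output grid (min); default 5-min spacing.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `populationSweep`: list with `individuals`
#'   (data.frame including `TBW_L` and peak observables) and `trajectories`
#'   (list, ordered as the rows).
#' @export
populationSweep <- function(spec, protocol, params = defaultParameters(),
                            t_grid = NULL, rtol = 1e-6, atol = 1e-8) {
  grid <- populationGrid(spec)
  trajs <- vector("list", nrow(grid))
  tbw <- peak_bac <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    anthro <- anthropometrics(grid$sex[i], grid$weight[i], grid$height[i],
                              grid$age[i])
    sched <- if (is.function(protocol)) protocol(grid$weight[i]) else protocol
    if (is.null(t_grid)) t_grid_i <- seq(0, sched$horizon, by = 5) else t_grid_i <- t_grid
    trajs[[i]] <- simulate(sched, anthro, params, t_grid = t_grid_i,
                           rtol = rtol, atol = atol)
    tbw[i] <- trajs[[i]]$volumes$TBW_L
    peak_bac[i] <- max(trajs[[i]]$observables[, "yEtOH"])
  }
  grid$TBW_L <- tbw
  grid$peak_BAC <- peak_bac
  structure(list(individuals = grid, trajectories = trajs),
            class = "populationSweep")
}

#' @export
print.populationSweep <- function(x, ...) {
  cat(sprintf("population sweep: %d individuals, TBW %.1f-%.1f L, peak BAC %.1f-%.1f mg/dL\n",
              nrow(x$individuals), min(x$individuals$TBW_L),
              max(x$individuals$TBW_L), min(x$individuals$peak_BAC),
              max(x$individuals$peak_BAC)))
  invisible(x)
}

# contiguous TRUE runs of a mask over a time grid -> intervals matrix
maskToIntervals <- function(times, mask) {
  if (!any(mask)) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("t_start", "t_end"))))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(t_start = times[starts[keep]], t_end = times[ends[keep]])
}

#' Deviation intervals between two scenarios' uncertainty bands
#'
#' Time regions where the (margin-inflated) bands of two scenarios are
#' disjoint, clipped to times at or after the end of the last drink — the
#' window in which marker profiles can discriminate drinking histories. The
#' non-overlap rule is this package's operationalisation of "deviating
#' behaviour"; the margin makes it more conservative.
#'
#' @param bandsA,bandsB named lists of [predictionBand()] results (same
#'   observables, same time grid), or two single bands.
#' @param window_start analysis window start (min), typically the end of the
#'   last drink across both scenarios.
#' @param margin non-negative widening applied to both bands before the
#'   disjointness test.
#' @return An object of class `scenarioComparison`: named list of interval
#'   matrices (columns `t_start`, `t_end`) per observable, with the window
#'   start and margin attached.
#' @export
deviationIntervals <- function(bandsA, bandsB, window_start = 0, margin = 0) {
  single <- inherits(bandsA, "uncertaintyBand")
  if (single) {
    bandsA <- stats::setNames(list(bandsA), bandsA$observable)
    bandsB <- stats::setNames(list(bandsB), bandsB$observable)
  }
  stopifnot(margin >= 0, identical(sort(names(bandsA)), sort(names(bandsB))))
  out <- list()
  for (nm in names(bandsA)) {
    a <- bandsA[[nm]]; b <- bandsB[[nm]]
    if (!isTRUE(all.equal(a$times, b$times))) {
      stop("bands for ", nm, " are on different time grids")
    }
    disjoint <- (a$upper + margin < b$lower - margin) |
      (b$upper + margin < a$lower - margin)
    disjoint <- disjoint & a$times >= window_start
    out[[nm]] <- maskToIntervals(a$times, disjoint)
  }
  structure(out, class = "scenarioComparison",
            window_start = window_start, margin = margin)
}

#' @export
print.scenarioComparison <- function(x, ...) {
  cat("scenario comparison (window start", attr(x, "window_start"), "min):\n")
  for (nm in names(x)) {
    iv <- x[[nm]]
    if (nrow(iv) == 0) {
      cat(sprintf("  %s: no deviation\n", nm))
    } else {
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("[%g, %g]", iv[, 1], iv[, 2]), collapse = " ")))
    }
  }
  invisible(x)
}

#' Plausibility of a claimed drinking scenario against samples
#'
#' Simulates the claimed scenario with its prediction bands and flags each
#' measured sample as inside or outside its marker's band (widened by
#' `z * sem` to allow for measurement error). The verdict is band-based only:
#' `consistent` when at least 95% of samples fall inside and no marker drops
#' below 80%, `inconsistent` when the overall rate falls below 80% or any
#' marker below 50%, `indeterminate` otherwise (including an empty sample
#' list).
#'
#' @param claimed list with `schedule` and `anthro` describing the claim.
#' @param samples data.frame with columns `observable`, `time_min`, `value`,
#'   `sem`.
#' @param params named parameter vector.
#' @param bands optional named list of [predictionBand()]s for the claimed
#'   scenario; when NULL, zero-width bands at the best-fit trajectory are
#'   used (parameter uncertainty ignored).
#' @param z measurement allowance in SEM units (default 1.96).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `plausibilityReport`: list with `samples`
#'   (input plus `lower`, `upper`, `inside`), `per_marker` (inside fractions),
#'   `fraction_inside`, `verdict`.
#' @export
plausibilityReport <- function(claimed, samples, params = defaultParameters(),
                               bands = NULL, z = 1.96,
                               rtol = 1e-6, atol = 1e-8) {
  if (nrow(samples) == 0) {
    return(structure(list(samples = samples, per_marker = numeric(0),
                          fraction_inside = NA_real_, verdict = "indeterminate"),
                     class = "plausibilityReport"))
  }
  hor <- claimed$schedule$horizon
  if (any(samples$time_min < 0 | samples$time_min > hor)) {
    stop("samples outside the simulation horizon")
  }
  tt <- sort(unique(samples$time_min))
  traj <- simulate(claimed$schedule, claimed$anthro, params,
                   t_grid = unique(c(0, tt)), rtol = rtol, atol = atol)
  lower <- upper <- numeric(nrow(samples))
  for (r in seq_len(nrow(samples))) {
    nm <- samples$observable[r]
    t_r <- samples$time_min[r]
    if (!is.null(bands) && nm %in% names(bands)) {
      b <- bands[[nm]]
      j <- which.min(abs(b$times - t_r))
      lower[r] <- b$lower[j]; upper[r] <- b$upper[j]
    } else {
      i <- which(abs(traj$times - t_r) < 1e-9)[1]
      lower[r] <- upper[r] <- traj$observables[i, nm]
    }
  }
  sem <- if ("sem" %in% names(samples)) samples$sem else 0
  inside <- samples$value >= lower - z * sem & samples$value <= upper + z * sem
  samples$lower <- lower; samples$upper <- upper; samples$inside <- inside
  per_marker <- tapply(inside, samples$observable, mean)
  frac <- mean(inside)
  verdict <- if (frac >= 0.95 && all(per_marker >= 0.8)) "consistent"
  else if (frac < 0.8 || any(per_marker < 0.5)) "inconsistent"
  else "indeterminate"
  structure(list(samples = samples, per_marker = per_marker,
                 fraction_inside = frac, verdict = verdict),
            class = "plausibilityReport")
}

#' @export
print.plausibilityReport <- function(x, ...) {
  cat(sprintf("plausibility report: verdict %s (%.0f%% of %d samples inside)\n",
              x$verdict, 100 * x$fraction_inside, nrow(x$samples)))
  for (nm in names(x$per_marker)) {
    cat(sprintf("  %s: %.0f%% inside\n", nm, 100 * x$per_marker[[nm]]))
  }
  invisible(x)
}
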