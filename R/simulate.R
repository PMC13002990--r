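#' Simulate the model over an intake schedule
#'
#' Integrates the model ODEs piecewise between scheduled event boundaries
#' (drink starts/ends, meal starts/ends, urinations), applying the discrete
#' drink-start and urination transforms at the boundaries. All events are
#' scheduled, so each boundary is a hard integration restart; no root finding
#' is involved. Output states at an event time are the post-event values.
#'
#' @param schedule an [inputSchedule()].
#' @param anthro an [anthropometrics()] object.
#' @param params named parameter vector. Non-negative values are accepted
#'   (zeroed rate constants are legitimate for conservation experiments).
#' @param t_grid output time grid (min); defaults to 1-min spacing over the
#'   horizon.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param options list of model options: `food_elim_factor` (default 1),
#'   `PEth0`, `PEth_bound0`.
#' @param engine `"c"` (compiled derivatives, default) or `"r"` (the
#'   reference R implementation); both compute identical derivatives and the
#'   test suite asserts their agreement.
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix, one row per time), `audit` (cumulative-flux bookkeeping matrix),
#'   `observables` (matrix), `event_log` (data.frame of applied events),
#'   plus the schedule, anthropometrics, parameters and derived volumes.
#' @export
simulate <- function(schedule, anthro, params = defaultParameters(),
                     t_grid = NULL, rtol = 1e-8, atol = 1e-10,
                     options = list(), engine = c("c", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(schedule, "inputSchedule"), inherits(anthro, "anthropometrics"))
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("parameters must be finite and non-negative")
  }
  horizon <- schedule$horizon
  if (is.null(t_grid)) t_grid <- seq(0, horizon, by = 1)
  t_grid <- sort(unique(t_grid))
  if (any(t_grid < 0) || any(t_grid > horizon)) stop("t_grid outside horizon")
  if (t_grid[1] > 0) t_grid <- c(0, t_grid)

  vols <- deriveVolumes(anthro, params)
  y <- fullInitialState(anthro, params,
                        PEth0 = if (is.null(options$PEth0)) 0 else options$PEth0,
                        PEth_bound0 = if (is.null(options$PEth_bound0)) 0 else options$PEth_bound0)

  dr_start <- vapply(schedule$drinks, `[[`, 0, "start")
  dr_end <- dr_start + vapply(schedule$drinks, `[[`, 0, "duration")
  ml_start <- vapply(schedule$meals, `[[`, 0, "start")
  ml_end <- ml_start + vapply(schedule$meals, `[[`, 0, "duration")
  ur_t <- vapply(schedule$urinations, `[[`, 0, "time")
  bounds <- sort(unique(pmin(c(0, horizon, dr_start, dr_end, ml_start, ml_end, ur_t),
                             horizon)))

  nfull <- length(y)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = nfull,
                dimnames = list(NULL, names(y)))
  ev_time <- numeric(0); ev_type <- character(0)
  eps <- 1e-9

  for (i in seq_len(length(bounds) - 1)) {
    b0 <- bounds[i]; b1 <- bounds[i + 1]
    # discrete events at the segment start
    if (any(abs(ur_t - b0) < eps)) {
      y <- applyUrination(y)
      ev_time <- c(ev_time, b0); ev_type <- c(ev_type, "urination")
    }
    if (any(abs(dr_start - b0) < eps)) {
      y <- applyNewDrink(y)
      ev_time <- c(ev_time, b0); ev_type <- c(ev_type, "drink_start")
    }
    # piecewise-constant inputs on (b0, b1)
    mid <- (b0 + b1) / 2
    inputs <- list(volDrinkPerTime = 0, kcalLiquidPerVol = 0, EtOHConc = 0,
                   mealKcalPerMin = 0)
    act <- which(dr_start <= mid & mid < dr_end)
    if (length(act)) {
      d <- schedule$drinks[[act[1]]]
      inputs$volDrinkPerTime <- d$volume / d$duration
      inputs$kcalLiquidPerVol <- d$kcal_per_L
      inputs$EtOHConc <- d$vv_fraction
    }
    actm <- which(ml_start <= mid & mid < ml_end)
    if (length(actm)) {
      inputs$mealKcalPerMin <- sum(vapply(schedule$meals[actm],
                                          function(m) m$kcal / m$duration, 0))
    }
    seg_grid <- t_grid[t_grid > b0 + eps & t_grid < b1 - eps]
    times <- unique(c(b0, seg_grid, b1))
    sol <- try(if (engine == "c") {
      deSolve::ode(y = y, times = times, func = "alcotwin_derivs",
                   parms = rhsParmsVector(params, vols, inputs, options),
                   dllname = "alcotwin", initfunc = "alcotwin_initmod",
                   method = "lsoda", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = y, times = times,
                   func = function(t, yy, parms) {
                     modelRHS(t, yy, params, vols, inputs, options)
                   },
                   parms = NULL, method = "lsoda",
                   rtol = rtol, atol = atol)
    }, silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times)) {
      stop(sprintf("integrator failure in segment [%g, %g]: %s", b0, b1,
                   if (inherits(sol, "try-error")) conditionMessage(attr(sol, "condition"))
                   else "incomplete solution"))
    }
    # record grid points: the segment start (post-event) and interior points;
    # the segment end is recorded by the next segment (or below for the last)
    keep <- which(abs(t_grid - b0) < eps)
    if (length(keep)) out[keep, ] <- sol[1, -1]
    for (tt in seg_grid) {
      k <- which(abs(t_grid - tt) < eps)
      r <- which(abs(times - tt) < eps)
      out[k, ] <- sol[r, -1]
    }
    y <- sol[nrow(sol), -1]
    names(y) <- names(fullInitialState())
    if (i == length(bounds) - 1) {
      keep <- which(abs(t_grid - b1) < eps)
      if (length(keep)) out[keep, ] <- y
    }
  }

  sn <- stateNames()
  states <- out[, sn, drop = FALSE]
  audit <- out[, auditNames(), drop = FALSE]
  structure(list(
    times = t_grid,
    states = states,
    audit = audit,
    observables = observables(states, vols),
    event_log = data.frame(time = ev_time, type = ev_type,
                           stringsAsFactors = FALSE),
    schedule = schedule, anthro = anthro, params = params, volumes = vols
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points over [%g, %g] min, %d event(s)\n",
              length(x$times), min(x$times), max(x$times), nrow(x$event_log)))
  cat(sprintf("  peak BAC %.2f mg/dL, peak UAC %.2f mg/dL\n",
              max(x$observables[, "yEtOH"]), max(x$observables[, "yUAC"])))
  invisible(x)
}

# flat parameter vector handed to the compiled derivative function; the
# layout must match the enum in src/model_rhs.c
rhsParmsVector <- function(params, vols, inputs, options = list()) {
  c(unname(params[parameterNames()]),
    vols$V_blood, vols$V_blood_central, vols$V_blood_peripheral,
    vols$V_plasma_peripheral, vols$V_liver, vols$TBW,
    inputs$volDrinkPerTime, inputs$kcalLiquidPerVol, inputs$EtOHConc,
    inputs$mealKcalPerMin,
    if (is.null(options$food_elim_factor)) 1 else options$food_elim_factor,
    if (is.null(options$vol_stomach0)) 1e-3 else options$vol_stomach0)
}

#' Ethanol mass balance audit of a trajectory
#'
#' Compares cumulative ingested ethanol against the sum of all compartment
#' masses plus cumulative eliminations (gastric ADH, hepatic ADH, CYP2E1, the
#' EtG and EtS synthesis paths) and voided urine. Fixed-volume compartments
#' are counted as concentration x volume; the tissue compartment, whose
#' volume varies with the extra-water state while its printed rate equation
#' carries no dilution term, is counted by its cumulative net influx.
#'
#' @param trajectory a [simulate()] result.
#' @return An object of class `massAudit`: data.frame with one row per time
#'   point (`time`, `ingested`, `accounted`, `residual_rel`) plus a
#'   `max_residual` attribute.
#' @export
massAudit <- function(trajectory) {
  s <- trajectory$states
  a <- trajectory$audit
  v <- trajectory$volumes
  compartments <-
    s[, "ConcEtOH_Stomach"] * 10 * s[, "Vol_Stomach"] +
    s[, "EtOH_Pool"] +
    s[, "MassEtOH_Intestines"] +
    s[, "BloodConcCentral"] * v$V_blood_central +
    s[, "BloodConcPeripheral"] * v$V_blood_peripheral +
    a[, "cumTissueNet"] +
    s[, "LiverConc"] * v$V_liver +
    s[, "UrineMassEtOH"]
  eliminated <- a[, "cumElimStoADH"] + a[, "cumElimADH"] + a[, "cumElimCYP2E1"] +
    a[, "cumEtGsynth"] + a[, "cumEtSsynth"]
  accounted <- compartments + eliminated + a[, "cumVoidedEtOH"]
  ingested <- a[, "cumIngested"]
  scale <- pmax(ingested, .Machine$double.eps)
  res <- data.frame(time = trajectory$times, ingested = ingested,
                    accounted = accounted,
                    residual_rel = (ingested - accounted) / scale)
  structure(res, class = c("massAudit", "data.frame"),
            max_residual = max(abs(res$residual_rel)))
}

#' @export
print.massAudit <- function(x, ...) {
  cat(sprintf("mass audit: %d time points, max |relative residual| = %.3g\n",
              nrow(x), attr(x, "max_residual")))
  invisible(x)
}

#' Export a trajectory as a tidy table
#'
#' @param trajectory a [simulate()] result.
#' @param path optional CSV path; when given the table is also written there.
#' @param what `"observables"` (default) or `"states"`.
#' @return a data.frame with columns `time`, `variable`, `value` (invisibly
#'   when `path` is given).
#' @export
trajectoryToTable <- function(trajectory, path = NULL,
                              what = c("observables", "states")) {
  what <- match.arg(what)
  m <- trajectory[[what]]
  df <- data.frame(
    time = rep(trajectory$times, ncol(m)),
    variable = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
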