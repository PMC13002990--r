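#' Kinetic parameter set
#'
#' The model has 34 named kinetic parameters. [defaultParameters()] returns the
#' published best-fit values; [parameterBounds()] returns the box constraints
#' used during estimation. Values are stored at full printed precision.
#'
#' Units follow the model's internal convention: time in minutes, volumes of
#' body water/blood/bladder in dL, stomach volume in L, masses in mg,
#' concentrations in mg/dL.
#'
#' @return `defaultParameters()`: a named numeric vector of length 34.
#' @export
defaultParameters <- function() {
  p <- c(
    VmaxGastric             = 0.10028847533601028,
    KmGastric               = 0.8115471295053232,
    k_kcalscaling           = 0.026009077044725923,
    km_kcal                 = 7219.025648168511,
    n_kcal                  = 2.9350431505014307,
    k_poolIn                = 0.049215056963481905,
    k_poolOut               = 0.00011026963373147828,
    VmaxADHSto              = 383.0316652068957,
    KmADHSto                = 1750.8565753331234,
    k_EtOHuptake            = 0.05085931578651339,
    k_equalize              = 3.364285096106452,
    k_equalize_liver        = 0.5664934932515018,
    VmaxADH                 = 17.490115599723829,
    VmaxCYP2E1              = 0.7715882956131286,
    KmADH                   = 12.13180346563429,
    KmCYP2E1                = 45.98540429542478,
    k_food_clearance        = 0.1350242774593947,
    k_acetate               = 1.1650870599405063,
    k_blood_plasma_ratio    = 0.6871729866586396,
    k_urine_water           = 5.961711956546037,
    k_basal_vasopressin     = 0.3849587409310818,
    k_vasopressin_BAC       = 74740.43401768291,
    k_clearance_vasopressin = 0.0006626630440471179,
    k_kidney_permability    = 2.5215624280668018e-05,
    VmaxEtG                 = 0.6461457040480787,
    KmEtG                   = 29854.322456892394,
    VmaxEtS                 = 0.011876595138349037,
    KmEtS                   = 414.40740948670106,
    k_EtG_urine             = 0.0024879684263205454,
    k_EtS_urine             = 0.014152433882270748,
    k_PEth                  = 0.13959486810293995,
    k_PEth_clearance        = 0.001460712263112933,
    k_PEth_bind             = 0.07805739912357477,
    k_PEth_release          = 0.002851044320061577
  )
  p
}

#' @rdname defaultParameters
#' @return `parameterNames()`: character vector of the 34 parameter names in
#'   canonical order.
#' @export
parameterNames <- function() names(defaultParameters())

#' @rdname defaultParameters
#' @return `parameterBounds()`: a data.frame with columns `parameter`, `lower`,
#'   `upper` (the estimation box constraints).
#' @export
parameterBounds <- function() {
  nm <- parameterNames()
  lower <- rep(1e-5, length(nm))
  upper <- rep(1e5, length(nm))
  names(lower) <- names(upper) <- nm
  lower["KmGastric"] <- 27.66;  upper["KmGastric"] <- 1844
  lower["n_kcal"]    <- 1e-1;   upper["n_kcal"]    <- 4
  lower["k_poolOut"] <- 1e-7
  lower["KmADHSto"]  <- 276.6;  upper["KmADHSto"]  <- 1844
  lower["KmADH"]     <- 9.22e-1; upper["KmADH"]    <- 9.22
  lower["KmCYP2E1"]  <- 36.88;  upper["KmCYP2E1"]  <- 46.1
  lower["k_blood_plasma_ratio"] <- 1e-1
  upper["k_blood_plasma_ratio"] <- 1
  for (k in c("k_PEth", "k_PEth_clearance", "k_PEth_bind", "k_PEth_release")) {
    lower[k] <- 1e-7
    upper[k] <- 1e3
  }
  data.frame(parameter = nm, lower = unname(lower), upper = unname(upper),
             stringsAsFactors = FALSE)
}

#' Validate a parameter vector
#'
#' Checks names, positivity and bound ordering. A default value lying outside
#' its own estimation bounds triggers a warning, not an error: two published
#' values (KmGastric, KmADH) sit outside their printed literature bounds.
#'
#' @param params named numeric vector (see [defaultParameters()]).
#' @param warn_bounds warn when a value falls outside its estimation bounds.
#' @return `params`, invisibly, after validation.
#' @export
validateParameters <- function(params, warn_bounds = TRUE) {
  ref <- parameterNames()
  if (!all(ref %in% names(params))) {
    stop("missing parameters: ", paste(setdiff(ref, names(params)), collapse = ", "))
  }
  extra <- setdiff(names(params), ref)
  if (length(extra)) stop("unknown parameters: ", paste(extra, collapse = ", "))
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all parameters must be positive and finite")
  }
  if (warn_bounds) {
    b <- parameterBounds()
    v <- params[b$parameter]
    out <- v < b$lower | v > b$upper
    if (any(out)) {
      warning("parameter value(s) outside estimation bounds: ",
              paste(b$parameter[out], collapse = ", "))
    }
  }
  invisible(params)
}

#' Read or write a parameter set as JSON
#'
#' Parameter files are flat JSON objects keyed by the canonical parameter
#' names; values are stored unrounded.
#'
#' @param path file path.
#' @param params named numeric vector.
#' @return `readParameters()` returns a validated named numeric vector.
#' @export
readParameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- unlist(x)
  p <- p[parameterNames()]
  validateParameters(p, warn_bounds = FALSE)
  p
}

#' @rdname readParameters
#' @export
writeParameters <- function(params, path) {
  validateParameters(params, warn_bounds = FALSE)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(as.list(params[parameterNames()]), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
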