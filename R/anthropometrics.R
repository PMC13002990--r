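#' Subject anthropometrics
#'
#' @param sex `"male"` or `"female"`.
#' @param weight body weight in kg (> 0).
#' @param height height in metres (1.0--2.5).
#' @param age age in years (0--120, exclusive).
#' @return An object of class `anthropometrics`.
#' @examples
#' anthropometrics("male", weight = 106.6, height = 1.86, age = 28)
#' @export
anthropometrics <- function(sex = c("male", "female"), weight, height, age) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(weight), length(weight) == 1, is.finite(weight),
            is.numeric(height), length(height) == 1, is.finite(height),
            is.numeric(age), length(age) == 1, is.finite(age))
  if (weight <= 0) stop("weight must be positive")
  if (height < 1.0 || height > 2.5) stop("height must be in [1.0, 2.5] m")
  if (age <= 0 || age >= 120) stop("age must be in (0, 120) years")
  structure(list(sex = sex, weight = weight, height = height, age = age),
            class = "anthropometrics")
}

#' @export
print.anthropometrics <- function(x, ...) {
  cat(sprintf("anthropometrics: %s, %.1f kg, %.2f m, %g y\n",
              x$sex, x$weight, x$height, x$age))
  invisible(x)
}

#' Derive physiological volumes from anthropometrics
#'
#' Blood volume follows the Nadler polynomial (height in metres, cubed); total
#' body water (TBW) follows the Watson linear form (height in cm) divided by
#' 0.84, so that the ethanol distribution volume exceeds plain Watson water.
#' Liver volume follows Vauthey's weight-linear formula. The central blood
#' compartment is a fixed 15% of blood volume; peripheral plasma is the
#' peripheral blood volume scaled by the blood--plasma water ratio parameter.
#'
#' All internal volumes are in dL (litres x 10); the `_L` fields repeat blood
#' volume and TBW in litres for reporting.
#'
#' @param anthro an [anthropometrics()] object.
#' @param params named parameter vector; only `k_blood_plasma_ratio` is used.
#' @return An object of class `derivedVolumes`: a list with elements
#'   `V_blood`, `V_blood_central`, `V_blood_peripheral`, `V_plasma_peripheral`,
#'   `TBW`, `V_liver` (all dL), `V_blood_L`, `TBW_L` (litres),
#'   `central_fraction`, `watson_scale`.
#' @examples
#' deriveVolumes(anthropometrics("male", 106.6, 1.86, 28))
#' @export
deriveVolumes <- function(anthro, params = defaultParameters()) {
  stopifnot(inherits(anthro, "anthropometrics"))
  w <- anthro$weight
  h <- anthro$height
  h_cm <- h * 100
  if (anthro$sex == "male") {
    v_blood_L <- 0.3669 * h^3 + 0.03219 * w + 0.6041
    tbw_L <- (2.447 - 0.09516 * anthro$age + 0.1074 * h_cm + 0.3362 * w) / 0.84
  } else {
    v_blood_L <- 0.3561 * h^3 + 0.03308 * w + 0.1833
    tbw_L <- (-2.097 + 0.1069 * h_cm + 0.2466 * w) / 0.84
  }
  v_liver <- (18.51 * w + 191.8) / 100 # dL
  vols <- list(
    V_blood = v_blood_L * 10,
    V_blood_central = 0.15 * v_blood_L * 10,
    V_blood_peripheral = 0.85 * v_blood_L * 10,
    V_plasma_peripheral = unname(params["k_blood_plasma_ratio"]) * 0.85 * v_blood_L * 10,
    TBW = tbw_L * 10,
    V_liver = v_liver,
    V_blood_L = v_blood_L,
    TBW_L = tbw_L,
    central_fraction = 0.15,
    watson_scale = 0.84
  )
  if (any(unlist(vols[1:6]) <= 0) || vols$TBW <= vols$V_blood + vols$V_liver) {
    stop("invalid anthropometrics: derived volumes are non-physiological")
  }
  structure(vols, class = "derivedVolumes")
}

#' @export
print.derivedVolumes <- function(x, ...) {
  cat(sprintf(paste0("derived volumes: blood %.1f L (central %.2f dL, ",
                     "peripheral %.2f dL), TBW %.1f L, liver %.2f dL\n"),
              x$V_blood_L, x$V_blood_central, x$V_blood_peripheral,
              x$TBW_L, x$V_liver))
  invisible(x)
}
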