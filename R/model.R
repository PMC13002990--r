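#' @keywords internal
#' @useDynLib alcotwin, .registration = TRUE
"_PACKAGE"

# ethanol density, g/L at room temperature; converts beverage volume x v/v
# fraction to ethanol mass
ETHANOL_DENSITY_G_L <- 789

#' Caloric inhibition of gastric emptying
#'
#' Liquid calories in the stomach slow gastric emptying through an inhibitory
#' Hill term: the returned multiplier is
#' `1 - x^n / (x^n + km_kcal^n)` with `x = Kcal_Liquid / k_kcalscaling` and
#' `n = n_kcal`. It equals 1 on an empty caloric load, 0.5 when the rescaled
#' load equals the half-saturation constant, and decreases monotonically
#' towards 0 for energy-dense drinks.
#'
#' @param kcal_liquid current liquid caloric load (kcal), non-negative.
#' @param params named parameter vector.
#' @return a scalar in (0, 1].
#' @export
kcalEffect <- function(kcal_liquid, params = defaultParameters()) {
  if (any(kcal_liquid < 0)) stop("kcal_liquid must be non-negative")
  x <- kcal_liquid / params[["k_kcalscaling"]]
  n <- params[["n_kcal"]]
  xn <- x^n
  1 - xn / (xn + params[["km_kcal"]]^n)
}

#' Gastric emptying rate
#'
#' Michaelis-Menten in the stomach volume above the fasted residual, times the
#' caloric inhibition factor: `VmaxGastric * VolChange / (VolChange +
#' KmGastric) * kcalEffect`. `VolChange` is clipped at zero so the rate is
#' never negative.
#'
#' @param vol_stomach current stomach volume (L).
#' @param kcal_liquid current liquid caloric load (kcal).
#' @param params named parameter vector.
#' @param vol_stomach0 fasted residual stomach volume (L).
#' @return emptying rate in L/min.
#' @export
gastricEmptyingRate <- function(vol_stomach, kcal_liquid,
                                params = defaultParameters(),
                                vol_stomach0 = 1e-3) {
  vol_change <- pmax(vol_stomach - vol_stomach0, 0)
  params[["VmaxGastric"]] * vol_change / (vol_change + params[["KmGastric"]]) *
    kcalEffect(kcal_liquid, params)
}

# Full right-hand side of the model ODEs.
#
# `inputs` holds the piecewise-constant segment inputs:
#   volDrinkPerTime (L/min), kcalLiquidPerVol (kcal/L), EtOHConc (v/v
#   fraction of the drink), mealKcalPerMin (kcal/min).
# `options$food_elim_factor` multiplies hepatic ethanol elimination while
# solid calories are present (default 1 = off, an exposed hook with no
# published kinetics). Returns derivatives for the dynamical states plus the
# cumulative-flux audit states.
modelRHS <- function(t, state, params, vols, inputs, options = list()) {
  s <- state
  p <- params
  food_factor <- if (!is.null(options$food_elim_factor)) options$food_elim_factor else 1
  vol_sto0 <- if (!is.null(options$vol_stomach0)) options$vol_stomach0 else 1e-3

  V_bc <- vols$V_blood_central
  V_bp <- vols$V_blood_peripheral
  V_pp <- vols$V_plasma_peripheral
  V_liver <- vols$V_liver
  V_tissue <- vols$TBW - vols$V_blood - V_liver + s[["TissueExtraWater"]]

  ## --- gastric emptying (liquid phase) ---
  r_vol_empty <- gastricEmptyingRate(s[["Vol_Stomach"]], s[["Kcal_Liquid"]],
                                     p, vol_sto0)
  dVol_Stomach <- inputs$volDrinkPerTime - r_vol_empty
  dKcal_Liquid <- inputs$volDrinkPerTime * inputs$kcalLiquidPerVol
  dKcal_remain <- inputs$volDrinkPerTime * inputs$kcalLiquidPerVol -
    r_vol_empty * s[["Kcal_remain"]] / s[["Vol_Stomach"]]

  ## --- stomach ethanol (legacy sub-models: mucosal pool, gastric ADH) ---
  r_EtOH_in <- inputs$volDrinkPerTime * inputs$EtOHConc * ETHANOL_DENSITY_G_L * 1000
  M_sto <- s[["ConcEtOH_Stomach"]] * 10 * s[["Vol_Stomach"]]
  r_empty_EtOH <- r_vol_empty * 10 * s[["ConcEtOH_Stomach"]]
  C_sto <- s[["ConcEtOH_Stomach"]]
  r_sto_ADH <- p[["VmaxADHSto"]] * C_sto / (C_sto + p[["KmADHSto"]])
  r_pool_in <- p[["k_poolIn"]] * M_sto
  r_pool_out <- p[["k_poolOut"]] * s[["EtOH_Pool"]]
  dM_sto <- r_EtOH_in - r_empty_EtOH - r_sto_ADH - r_pool_in + r_pool_out
  dConcEtOH_Stomach <- (dM_sto - C_sto * 10 * dVol_Stomach) /
    (10 * s[["Vol_Stomach"]])
  dEtOH_Pool <- r_pool_in - r_pool_out

  ## --- absorption and circulation ---
  r_uptake <- s[["MassEtOH_Intestines"]] * p[["k_EtOHuptake"]]
  dMassEtOH_Intestines <- r_empty_EtOH - r_uptake
  C_c <- s[["BloodConcCentral"]]
  C_p <- s[["BloodConcPeripheral"]]
  r_circ <- p[["k_equalize"]] * (C_c - C_p)
  r_liver <- p[["k_equalize_liver"]] * (C_p - s[["LiverConc"]])
  r_tissue_per <- C_p - s[["TissueConc"]]

  ## --- urine transport ---
  r_tissueurine <- s[["TissueExtraWater"]] / s[["Vasopressin"]] * p[["k_urine_water"]]
  r_urine <- r_tissueurine * (C_p * V_bp) / V_pp + 0.01 * C_p
  r_urinereturn <- p[["k_kidney_permability"]] * s[["Vasopressin"]] *
    (s[["UrineMassEtOH"]] / s[["UrineVolume"]] - C_p * V_bp / V_pp) *
    s[["UrineVolume"]]

  dBloodConcCentral <- r_uptake / V_bc - r_circ
  dBloodConcPeripheral <- r_circ * (V_bc / V_bp) - r_tissue_per - r_liver +
    (-r_urine + r_urinereturn) / V_bp

  ## --- hepatic elimination and conjugate synthesis ---
  C_l <- s[["LiverConc"]]
  r_elim <- (p[["VmaxADH"]] * C_l / (C_l + p[["KmADH"]]) +
             p[["VmaxCYP2E1"]] * C_l / (C_l + p[["KmCYP2E1"]])) *
    (if (s[["Kcal_Solid"]] > 0) food_factor else 1)
  r_elim_ADH_part <- p[["VmaxADH"]] * C_l / (C_l + p[["KmADH"]]) *
    (if (s[["Kcal_Solid"]] > 0) food_factor else 1)
  r_EtG <- p[["VmaxEtG"]] * C_l / (C_l + p[["KmEtG"]])
  r_EtS <- p[["VmaxEtS"]] * C_l / (C_l + p[["KmEtS"]])
  dLiverConc <- r_liver * V_bp / V_liver - r_elim - r_EtG - r_EtS

  r_EtG_lp <- s[["LiverEtG"]] - s[["PeripheralEtG"]]
  r_EtS_lp <- s[["LiverEtS"]] - s[["PeripheralEtS"]]
  r_EtG_urine <- p[["k_EtG_urine"]] * s[["PeripheralEtG"]]
  r_EtS_urine <- p[["k_EtS_urine"]] * s[["PeripheralEtS"]]
  dLiverEtG <- r_EtG - r_EtG_lp
  dPeripheralEtG <- r_EtG_lp * V_liver / V_bp - r_EtG_urine
  dLiverEtS <- r_EtS - r_EtS_lp
  dPeripheralEtS <- r_EtS_lp * V_liver / V_bp - r_EtS_urine

  ## --- tissue water and vasopressin ---
  dTissueConc <- r_tissue_per * V_bp / V_tissue
  dTissueExtraWater <- r_vol_empty * 10 - r_tissueurine
  dVasopressin <- p[["k_basal_vasopressin"]] /
    (1 + p[["k_vasopressin_BAC"]] * C_p) -
    s[["Vasopressin"]] * p[["k_clearance_vasopressin"]]

  ## --- bladder ---
  dUrineMassEtOH <- r_urine - r_urinereturn
  dUrineVolume <- 0.01 + r_tissueurine
  dUrineMassEtG <- r_EtG_urine * V_bp
  dUrineMassEtS <- r_EtS_urine * V_bp

  ## --- legacy: solid meal kcal, acetate, PEth ---
  dKcal_Solid <- inputs$mealKcalPerMin - p[["k_food_clearance"]] * s[["Kcal_Solid"]]
  dMaxKcal_Solid <- inputs$mealKcalPerMin
  dPlasma_Acetate <- p[["k_acetate"]] *
    (r_elim * V_liver / V_pp - s[["Plasma_Acetate"]])
  dPEth <- p[["k_PEth"]] * C_p - p[["k_PEth_clearance"]] * s[["PEth"]] -
    p[["k_PEth_bind"]] * s[["PEth"]] + p[["k_PEth_release"]] * s[["PEth_Bound"]]
  dPEth_Bound <- p[["k_PEth_bind"]] * s[["PEth"]] -
    p[["k_PEth_release"]] * s[["PEth_Bound"]]

  d <- c(dVol_Stomach, dKcal_Liquid, dKcal_remain, dMaxKcal_Solid, dKcal_Solid,
         dEtOH_Pool, dConcEtOH_Stomach, dMassEtOH_Intestines,
         dBloodConcCentral, dBloodConcPeripheral, dTissueConc, dLiverConc,
         dLiverEtG, dPeripheralEtG, dLiverEtS, dPeripheralEtS,
         dPlasma_Acetate, dTissueExtraWater, dVasopressin,
         dUrineMassEtOH, dUrineVolume, dUrineMassEtG, dUrineMassEtS,
         dPEth, dPEth_Bound, 1,
         ## audit states: cumulative fluxes in mg
         r_EtOH_in, r_sto_ADH,
         r_elim_ADH_part * V_liver, (r_elim - r_elim_ADH_part) * V_liver,
         r_EtG * V_liver, r_EtS * V_liver,
         r_tissue_per * V_bp, 0)
  if (any(!is.finite(d))) {
    stop("integration failure: non-finite derivative at t = ", t)
  }
  list(d)
}

#' Map a model state to the observable vector
#'
#' Observables: gastric volume (L); BAC = peripheral blood ethanol (mg/dL);
#' BrAC in g/210 L via the fixed affine breath--blood correlation
#' `0.840 * (BloodConcCentral/1000) + 0.00367` and in g/dL as
#' `BloodConcCentral/1000`; plasma acetate in mM (mg/dL divided by 10.2);
#' PEth (umol/L); UAC = bladder ethanol mass over urine volume (mg/dL);
#' blood EtG and EtS (mg/dL).
#'
#' @param state named state vector (or a matrix with named columns).
#' @param volumes a [deriveVolumes()] result (unused by the mapping itself but
#'   kept for interface symmetry).
#' @return named numeric vector (or matrix) of the 9 observables.
#' @export
observables <- function(state, volumes = NULL) {
  grab <- function(nm) if (is.matrix(state)) state[, nm] else state[[nm]]
  uv <- grab("UrineVolume")
  if (any(uv <= 0)) stop("undefined UAC: urine volume must be positive")
  out <- cbind(
    yGastricVolume = grab("Vol_Stomach"),
    yEtOH = grab("BloodConcPeripheral"),
    yBrAC_g210L = 0.840 * (grab("BloodConcCentral") / 1000) + 0.00367,
    yBrAC_gdL = grab("BloodConcCentral") / 1000,
    yAcetate = grab("Plasma_Acetate") / 10.2,
    yPEth = grab("PEth"),
    yUAC = grab("UrineMassEtOH") / uv,
    yEtG = grab("PeripheralEtG"),
    yEtS = grab("PeripheralEtS")
  )
  if (!is.matrix(state)) out <- out[1, ]
  out
}

#' Observable names
#' @return character vector of the 9 observable names.
#' @export
observableNames <- function() {
  c("yGastricVolume", "yEtOH", "yBrAC_g210L", "yBrAC_gdL", "yAcetate",
    "yPEth", "yUAC", "yEtG", "yEtS")
}
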