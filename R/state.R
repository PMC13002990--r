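#' Model state vector
#'
#' The dynamical state comprises 26 named quantities: stomach volume (L) and
#' caloric bookkeeping (kcal), the stomach ethanol pool and intestinal ethanol
#' mass (mg), ethanol concentrations in stomach, central/peripheral blood,
#' tissue and liver (mg/dL), liver/peripheral EtG and EtS (mg/dL), plasma
#' acetate (mg/dL), extra tissue water (dL), vasopressin (model units), bladder
#' masses (mg) and urine volume (dL), PEth free/bound (umol/L), and elapsed
#' time (min).
#'
#' @return `stateNames()`: character vector of the 26 state names.
#' @export
stateNames <- function() {
  c("Vol_Stomach", "Kcal_Liquid", "Kcal_remain", "MaxKcal_Solid", "Kcal_Solid",
    "EtOH_Pool", "ConcEtOH_Stomach", "MassEtOH_Intestines",
    "BloodConcCentral", "BloodConcPeripheral", "TissueConc", "LiverConc",
    "LiverEtG", "PeripheralEtG", "LiverEtS", "PeripheralEtS",
    "Plasma_Acetate", "TissueExtraWater", "Vasopressin",
    "UrineMassEtOH", "UrineVolume", "UrineMassEtG", "UrineMassEtS",
    "PEth", "PEth_Bound", "timeElapsed")
}

# cumulative-flux bookkeeping states carried alongside the dynamical state;
# used by massAudit() and zero-cost to integrate
auditNames <- function() {
  c("cumIngested", "cumElimStoADH", "cumElimADH", "cumElimCYP2E1",
    "cumEtGsynth", "cumEtSsynth", "cumTissueNet", "cumVoidedEtOH")
}

#' Initial state of the model
#'
#' The subject starts fasted with no residual alcohol: a 0.001 L residual
#' stomach volume, a 0.05 dL residual bladder volume, and vasopressin at its
#' drug-free steady state (basal influx / clearance, the mass-balance value at
#' time zero with zero BAC). PEth and its bound form default to 0 but can be
#' seeded for subjects with prior chronic exposure.
#'
#' @param anthro an [anthropometrics()] object (unused by the defaults but
#'   kept in the signature so subject-specific initialisation can hook in).
#' @param params named parameter vector.
#' @param PEth0,PEth_bound0 optional basal PEth levels (umol/L).
#' @return named numeric state vector (see [stateNames()]).
#' @export
initialState <- function(anthro = NULL, params = defaultParameters(),
                         PEth0 = 0, PEth_bound0 = 0) {
  s <- stats::setNames(numeric(length(stateNames())), stateNames())
  s["Vol_Stomach"] <- 1.0e-3
  s["UrineVolume"] <- 0.05
  s["Vasopressin"] <- unname(params["k_basal_vasopressin"] /
                             params["k_clearance_vasopressin"])
  s["PEth"] <- PEth0
  s["PEth_Bound"] <- PEth_bound0
  s
}

# full integration vector: dynamical state + audit states (all zero at t0)
fullInitialState <- function(anthro = NULL, params = defaultParameters(), ...) {
  c(initialState(anthro, params, ...),
    stats::setNames(numeric(length(auditNames())), auditNames()))
}
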