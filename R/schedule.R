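#' Intake schedule events
#'
#' A schedule is an ordered collection of drink, meal and urination events plus
#' a simulation horizon. Drinks deliver beverage volume uniformly over their
#' duration, carrying ethanol (via their v/v fraction) and liquid calories;
#' meals deliver solid calories uniformly over their duration; urinations empty
#' the bladder down to its 0.05 dL residual.
#'
#' @param start,time event start time (min).
#' @param duration event duration (min, > 0 for drinks).
#' @param volume beverage volume (L, >= 0).
#' @param vv_fraction ethanol volume fraction in [0, 1].
#' @param kcal_per_L caloric density of the beverage (kcal/L).
#' @param kcal meal energy (kcal, >= 0).
#' @return `drinkEvent()`/`mealEvent()`/`urinationEvent()` return event lists
#'   used by [inputSchedule()].
#' @export
drinkEvent <- function(start, duration, volume, vv_fraction, kcal_per_L = 0) {
  stopifnot(duration > 0, volume >= 0, vv_fraction >= 0, vv_fraction <= 1,
            kcal_per_L >= 0, start >= 0)
  list(type = "drink", start = start, duration = duration, volume = volume,
       vv_fraction = vv_fraction, kcal_per_L = kcal_per_L)
}

#' @rdname drinkEvent
#' @export
mealEvent <- function(time, kcal, duration = 1) {
  stopifnot(kcal >= 0, duration > 0, time >= 0)
  list(type = "meal", start = time, duration = duration, kcal = kcal)
}

#' @rdname drinkEvent
#' @export
urinationEvent <- function(time) {
  stopifnot(time >= 0)
  list(type = "urination", time = time)
}

#' Assemble and validate an input schedule
#'
#' @param drinks list of [drinkEvent()]s (no two may overlap in time).
#' @param meals list of [mealEvent()]s.
#' @param urinations list of [urinationEvent()]s, strictly increasing times.
#' @param horizon simulation horizon (min); all events must fall inside.
#' @return an object of class `inputSchedule`.
#' @export
inputSchedule <- function(drinks = list(), meals = list(),
                          urinations = list(), horizon = 720) {
  stopifnot(horizon > 0)
  ord <- function(evts) evts[order(vapply(evts, `[[`, 0, "start"))]
  if (length(drinks)) {
    drinks <- ord(drinks)
    st <- vapply(drinks, `[[`, 0, "start")
    en <- st + vapply(drinks, `[[`, 0, "duration")
    if (any(en > horizon) || any(st < 0)) stop("drink outside [0, horizon]")
    if (length(drinks) > 1 && any(st[-1] < en[-length(en)] - 1e-9)) {
      stop("drinks overlap")
    }
  }
  if (length(meals)) {
    meals <- ord(meals)
    if (any(vapply(meals, `[[`, 0, "start") +
            vapply(meals, `[[`, 0, "duration") > horizon)) {
      stop("meal outside [0, horizon]")
    }
  }
  if (length(urinations)) {
    ut <- vapply(urinations, `[[`, 0, "time")
    if (is.unsorted(ut, strictly = TRUE)) stop("urination times must be strictly increasing")
    if (any(ut > horizon)) stop("urination outside [0, horizon]")
  }
  structure(list(drinks = drinks, meals = meals, urinations = urinations,
                 horizon = horizon), class = "inputSchedule")
}

#' @export
print.inputSchedule <- function(x, ...) {
  cat(sprintf("input schedule: %d drink(s), %d meal(s), %d urination(s), horizon %g min\n",
              length(x$drinks), length(x$meals), length(x$urinations), x$horizon))
  invisible(x)
}

#' Total ingested ethanol mass of a schedule
#' @param schedule an [inputSchedule()].
#' @return ethanol mass in mg.
#' @export
scheduleEthanolMass <- function(schedule) {
  if (!length(schedule$drinks)) return(0)
  sum(vapply(schedule$drinks,
             function(d) d$volume * d$vv_fraction * ETHANOL_DENSITY_G_L * 1000, 0))
}

#' Convert an ethanol dose to a beverage volume
#'
#' `dose` (g ethanol per kg body weight) times weight gives the ethanol mass;
#' dividing by 789 g/L (ethanol density) times the v/v fraction gives the
#' beverage volume to pour.
#'
#' @param dose g ethanol / kg body weight, >= 0.
#' @param weight body weight (kg).
#' @param vv_fraction beverage ethanol fraction (0, 1].
#' @return beverage volume in L.
#' @examples
#' doseToVolume(0.51, 106.6, 0.13) # ~0.53 L of 13 v/v% wine
#' @export
doseToVolume <- function(dose, weight, vv_fraction) {
  stopifnot(dose >= 0, weight > 0)
  if (vv_fraction <= 0 || vv_fraction > 1) stop("vv_fraction must be in (0, 1]")
  dose * weight / (ETHANOL_DENSITY_G_L * vv_fraction)
}

# beverage conventions used by the protocol builders: v/v fractions and
# caloric densities (kcal/L); spirits are taken as calorie-free
beverageDefaults <- function() {
  list(
    beer    = list(vv = 0.05, kcal_per_L = 440),
    wine    = list(vv = 0.13, kcal_per_L = 830),
    whiskey = list(vv = 0.40, kcal_per_L = 0),
    vodka   = list(vv = 0.40, kcal_per_L = 0)
  )
}

# split a drink into four 10-min blocks with 5-min sampling gaps over 60 min
fourBlockDrink <- function(start, volume, vv, kcal_per_L) {
  lapply(0:3, function(i) {
    drinkEvent(start + i * 15, 10, volume / 4, vv, kcal_per_L)
  })
}

#' Build the dual-drink study protocol
#'
#' First drink: beer at 0.51 g/kg consumed in four 10-min blocks with 5-min
#' sampling gaps over 60 min. Second drink: the chosen beverage at 0.25, 0.51
#' or 0.85 g/kg, consumed over 15 min (low dose) or 30 min (medium/high).
#' Meals of 300 kcal (session start) and 500 kcal (180 min). Options encode
#' two study-protocol assumptions: 40 v/v% spirits are diluted with an equal
#' volume of non-alcoholic beverage (volume doubled, concentration halved),
#' and the high-dose vodka drinking window starts 10 min later and lasts
#' 20 min.
#'
#' @param weight subject body weight (kg).
#' @param second_type `"whiskey"`, `"vodka"`, `"beer"` or `"wine"`.
#' @param second_dose second-drink ethanol dose, one of 0.25, 0.51, 0.85 g/kg.
#' @param second_start start of the second drink (min).
#' @param dilute_spirits apply the equal-volume non-alcoholic dilution to
#'   40 v/v% spirits.
#' @param shift_high_vodka apply the delayed, shortened high-dose vodka window.
#' @param urination_interval minutes between urinations (NULL for none).
#' @param horizon simulation horizon (min).
#' @param beverages beverage conventions (v/v and kcal/L per type).
#' @return an [inputSchedule()].
#' @export
buildDualDrinkProtocol <- function(weight,
                                   second_type = c("whiskey", "vodka", "beer", "wine"),
                                   second_dose = 0.51,
                                   second_start = 120,
                                   dilute_spirits = TRUE,
                                   shift_high_vodka = TRUE,
                                   urination_interval = 30,
                                   horizon = 720,
                                   beverages = beverageDefaults()) {
  second_type <- match.arg(second_type)
  if (!second_dose %in% c(0.25, 0.51, 0.85)) {
    stop("second_dose must be one of 0.25, 0.51, 0.85 g/kg")
  }
  beer <- beverages$beer
  vol1 <- doseToVolume(0.51, weight, beer$vv)
  drinks <- fourBlockDrink(0, vol1, beer$vv, beer$kcal_per_L)

  bev <- beverages[[second_type]]
  vv2 <- bev$vv
  kcal2 <- bev$kcal_per_L
  vol2 <- doseToVolume(second_dose, weight, vv2)
  if (dilute_spirits && second_type %in% c("whiskey", "vodka")) {
    vol2 <- vol2 * 2
    vv2 <- vv2 / 2
  }
  dur2 <- if (second_dose == 0.25) 15 else 30
  st2 <- second_start
  if (shift_high_vodka && second_type == "vodka" && second_dose == 0.85) {
    st2 <- st2 + 10
    dur2 <- 20
  }
  drinks <- c(drinks, list(drinkEvent(st2, dur2, vol2, vv2, kcal2)))

  meals <- list(mealEvent(0, 300), mealEvent(180, 500))
  urinations <- if (is.null(urination_interval)) list() else {
    lapply(seq(urination_interval, horizon, by = urination_interval),
           urinationEvent)
  }
  inputSchedule(drinks, meals, urinations, horizon)
}

#' Build the single-drink validation protocol
#'
#' A single 0.119 L drink of 40 v/v% calorie-free spirits consumed over
#' 30 min, paired with a 500 kcal meal over the same 30 min.
#'
#' @param weight subject body weight (kg); the drink volume is fixed, so this
#'   only matters downstream through the anthropometrics.
#' @param horizon simulation horizon (min).
#' @return an [inputSchedule()].
#' @export
buildWangProtocol <- function(weight = NULL, horizon = 720) {
  inputSchedule(
    drinks = list(drinkEvent(0, 30, 0.119, 0.40, 0)),
    meals = list(mealEvent(0, 500, duration = 30)),
    urinations = list(),
    horizon = horizon
  )
}

#' Named subject protocols for the forensic showcase
#'
#' The claimed dual challenge: 0.85 g/kg of 13 v/v% wine in four 10-min blocks
#' over 60 min, then 0.51 g/kg of 20 v/v% vodka over 30 min, with meals of
#' 300/500/500 kcal at 90/180/540 min (male) or 30/180/540 min (female). The
#' alternative ("hipflask") challenge: a single 1.0 g/kg dose of 40 v/v% vodka
#' over 30 min.
#'
#' @param subject `"male"` or `"female"` (sets the meal times).
#' @param weight body weight (kg).
#' @param second_start start of the vodka drink (min).
#' @param horizon simulation horizon (min).
#' @param urination_interval minutes between urinations.
#' @return an [inputSchedule()].
#' @export
buildClaimProtocol <- function(subject = c("male", "female"), weight,
                               second_start = 120, horizon = 720,
                               urination_interval = 60) {
  subject <- match.arg(subject)
  vol1 <- doseToVolume(0.85, weight, 0.13)
  drinks <- fourBlockDrink(0, vol1, 0.13, beverageDefaults()$wine$kcal_per_L)
  vol2 <- doseToVolume(0.51, weight, 0.20)
  drinks <- c(drinks, list(drinkEvent(second_start, 30, vol2, 0.20, 0)))
  meal_t <- if (subject == "male") c(90, 180, 540) else c(30, 180, 540)
  meals <- Map(mealEvent, meal_t, c(300, 500, 500))
  urinations <- lapply(seq(urination_interval, horizon, by = urination_interval),
                       urinationEvent)
  inputSchedule(drinks, meals, urinations, horizon)
}

#' @rdname buildClaimProtocol
#' @export
buildAlternativeProtocol <- function(weight, second_start = 0, horizon = 720,
                                     urination_interval = 60) {
  vol <- doseToVolume(1.0, weight, 0.40)
  drinks <- list(drinkEvent(second_start, 30, vol, 0.40, 0))
  urinations <- lapply(seq(urination_interval, horizon, by = urination_interval),
                       urinationEvent)
  inputSchedule(drinks, list(), urinations, horizon)
}

#' Discrete event transforms
#'
#' `applyNewDrink()` implements the drink-start update: the liquid caloric
#' load is reset to the remaining-kcal bookkeeping state. `applyUrination()`
#' implements voiding: each bladder mass is scaled by `0.05/UrineVolume` and
#' the urine volume is reset to the 0.05 dL post-void residual, so urine
#' concentrations (UAC and urinary EtG/EtS) are unchanged across the event.
#'
#' @param state named state vector.
#' @return the transformed state. `applyUrination()` additionally accumulates
#'   the voided ethanol mass into the `cumVoidedEtOH` audit state when present,
#'   and warns (no-op) if the bladder is already at or below residual volume.
#' @export
applyNewDrink <- function(state) {
  state["Kcal_Liquid"] <- state[["Kcal_remain"]]
  state
}

#' @rdname applyNewDrink
#' @export
applyUrination <- function(state) {
  uv <- state[["UrineVolume"]]
  if (uv < 0.05) {
    warning("urine volume below residual (0.05 dL); urination skipped")
    return(state)
  }
  frac <- 0.05 / uv
  if ("cumVoidedEtOH" %in% names(state)) {
    state["cumVoidedEtOH"] <- state[["cumVoidedEtOH"]] +
      state[["UrineMassEtOH"]] * (1 - frac)
  }
  state["UrineMassEtOH"] <- state[["UrineMassEtOH"]] * frac
  state["UrineMassEtG"] <- state[["UrineMassEtG"]] * frac
  state["UrineMassEtS"] <- state[["UrineMassEtS"]] * frac
  state["UrineVolume"] <- 0.05
  state
}

#' Read or write a schedule as YAML or JSON
#'
#' The on-disk schema mirrors the model's input naming: drinks carry
#' `EtOHConc` (v/v fraction), `volDrinkPerTime` implied by volume/duration and
#' `kcalLiquidPerVol`; meals carry `MealKcal`; urinations are a list of
#' `urinate` times.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param schedule an [inputSchedule()].
#' @return `readSchedule()` returns an [inputSchedule()].
#' @export
readSchedule <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  drinks <- lapply(x$drinks, function(d) {
    drinkEvent(d$start, d$duration, d$volume, d$EtOHConc,
               if (is.null(d$kcalLiquidPerVol)) 0 else d$kcalLiquidPerVol)
  })
  meals <- lapply(x$meals, function(m) {
    mealEvent(m$start, m$MealKcal, if (is.null(m$duration)) 1 else m$duration)
  })
  urinations <- lapply(x$urinate, urinationEvent)
  inputSchedule(drinks, meals, urinations,
                if (is.null(x$horizon)) 720 else x$horizon)
}

#' @rdname readSchedule
#' @export
writeSchedule <- function(schedule, path) {
  x <- list(
    horizon = schedule$horizon,
    drinks = lapply(schedule$drinks, function(d) {
      list(start = d$start, duration = d$duration, volume = d$volume,
           EtOHConc = d$vv_fraction, kcalLiquidPerVol = d$kcal_per_L,
           volDrinkPerTime = d$volume / d$duration)
    }),
    meals = lapply(schedule$meals, function(m) {
      list(start = m$start, MealKcal = m$kcal, duration = m$duration)
    }),
    urinate = vapply(schedule$urinations, `[[`, 0, "time")
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}
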