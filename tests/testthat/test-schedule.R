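test_that("dose-to-volume conversion uses the ethanol density", {
  expect_equal(doseToVolume(0.51, 106.6, 0.13), 0.530, tolerance = 1e-3)
  expect_equal(doseToVolume(1.0, 106.6, 0.40), 0.338, tolerance = 1e-3)
  expect_equal(doseToVolume(0, 70, 0.4), 0)
  expect_error(doseToVolume(0.5, 70, 0), "vv_fraction")
  # round trip dose -> volume -> dose
  for (dose in c(0.25, 0.51, 0.85)) {
    vol <- doseToVolume(dose, 70, 0.4)
    expect_equal(vol * 0.4 * 789 / 70, dose, tolerance = 1e-9)
  }
})

test_that("dual-drink builder encodes the study protocol", {
  s <- buildDualDrinkProtocol(70, "vodka", 0.25)
  second <- s$drinks[[5]]
  expect_equal(second$duration, 15)
  s <- buildDualDrinkProtocol(70, "whiskey", 0.85)
  expect_equal(s$drinks[[5]]$duration, 30)
  # first drink: four 10-min beer blocks with 5-min gaps
  starts <- vapply(s$drinks[1:4], `[[`, 0, "start")
  expect_equal(starts, c(0, 15, 30, 45))
  expect_true(all(vapply(s$drinks[1:4], `[[`, 0, "duration") == 10))
  # total first-drink ethanol mass equals the prescribed dose
  mass1 <- sum(vapply(s$drinks[1:4],
                      function(d) d$volume * d$vv_fraction * 789 * 1000, 0))
  expect_equal(mass1, 0.51 * 70 * 1000, tolerance = 1e-6)
  # meals at session start (300 kcal) and 180 min (500 kcal)
  expect_equal(vapply(s$meals, `[[`, 0, "start"), c(0, 180))
  expect_equal(vapply(s$meals, `[[`, 0, "kcal"), c(300, 500))
  expect_error(buildDualDrinkProtocol(70, "vodka", 0.3), "second_dose")
})

test_that("spirit dilution doubles volume and halves concentration", {
  undiluted <- buildDualDrinkProtocol(70, "vodka", 0.51, dilute_spirits = FALSE)
  diluted <- buildDualDrinkProtocol(70, "vodka", 0.51, dilute_spirits = TRUE)
  expect_equal(diluted$drinks[[5]]$volume, 2 * undiluted$drinks[[5]]$volume)
  expect_equal(diluted$drinks[[5]]$vv_fraction,
               undiluted$drinks[[5]]$vv_fraction / 2)
  # ethanol mass unchanged by dilution
  expect_equal(scheduleEthanolMass(diluted), scheduleEthanolMass(undiluted))
  # beer is not diluted
  beer <- buildDualDrinkProtocol(70, "beer", 0.51)
  expect_equal(beer$drinks[[5]]$vv_fraction, 0.05)
})

test_that("the high-dose vodka window is shifted and shortened", {
  s <- buildDualDrinkProtocol(70, "vodka", 0.85, second_start = 120)
  expect_equal(s$drinks[[5]]$start, 130)
  expect_equal(s$drinks[[5]]$duration, 20)
  # whiskey at the same dose keeps the nominal window
  w <- buildDualDrinkProtocol(70, "whiskey", 0.85, second_start = 120)
  expect_equal(w$drinks[[5]]$start, 120)
  expect_equal(w$drinks[[5]]$duration, 30)
})

test_that("the single-drink validation protocol is fixed", {
  s <- buildWangProtocol(80)
  expect_length(s$drinks, 1)
  expect_equal(s$drinks[[1]]$volume, 0.119)
  expect_equal(s$drinks[[1]]$vv_fraction, 0.40)
  expect_equal(s$drinks[[1]]$kcal_per_L, 0)
  expect_equal(s$drinks[[1]]$duration, 30)
  expect_equal(s$meals[[1]]$kcal, 500)
  expect_equal(s$meals[[1]]$duration, 30)
})

test_that("schedule validation rejects malformed inputs", {
  expect_error(inputSchedule(list(drinkEvent(0, 60, 1, 0.05),
                                  drinkEvent(30, 30, 1, 0.05))), "overlap")
  expect_error(inputSchedule(urinations = list(urinationEvent(60),
                                               urinationEvent(30))),
               "increasing")
  expect_error(inputSchedule(list(drinkEvent(700, 60, 1, 0.05)),
                             horizon = 720), "horizon")
})

test_that("drink-start and urination events transform the state as specified", {
  s <- initialState()
  s["Kcal_remain"] <- 120
  s2 <- applyNewDrink(s)
  expect_equal(s2[["Kcal_Liquid"]], 120)
  expect_equal(s2[setdiff(names(s2), "Kcal_Liquid")],
               s[setdiff(names(s), "Kcal_Liquid")])
  expect_equal(applyNewDrink(s2), s2) # idempotent

  s <- initialState()
  s["UrineVolume"] <- 5
  s["UrineMassEtOH"] <- 100
  s["UrineMassEtG"] <- 10
  s["UrineMassEtS"] <- 1
  uac_before <- observables(s)[["yUAC"]]
  s3 <- applyUrination(s)
  expect_equal(s3[["UrineMassEtOH"]], 1)
  expect_equal(s3[["UrineVolume"]], 0.05)
  expect_equal(s3[["UrineMassEtG"]], 0.1)
  expect_equal(s3[["UrineMassEtS"]], 0.01)
  # concentrations preserved across the void
  expect_equal(observables(s3)[["yUAC"]], uac_before)
  # at residual volume the event is a no-op
  s4 <- initialState()
  expect_equal(applyUrination(s4), s4)
  s4["UrineVolume"] <- 0.01
  expect_warning(s5 <- applyUrination(s4), "residual")
  expect_equal(s5, s4)
})

test_that("schedules round-trip through YAML and JSON", {
  s <- buildDualDrinkProtocol(70, "wine", 0.51)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeSchedule(s, f)
    s2 <- readSchedule(f)
    expect_equal(length(s2$drinks), length(s$drinks))
    expect_equal(scheduleEthanolMass(s2), scheduleEthanolMass(s), tolerance = 1e-9)
    expect_equal(vapply(s2$meals, `[[`, 0, "kcal"),
                 vapply(s$meals, `[[`, 0, "kcal"))
    expect_equal(s2$horizon, s$horizon)
    unlink(f)
  }
})
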