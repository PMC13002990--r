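# shared fixtures; everything is built in code so tests stay text-only

male_subject <- function() anthropometrics("male", 106.6, 1.86, 28)
female_subject <- function() anthropometrics("female", 62.7, 1.69, 22)
test_subject <- function() anthropometrics("male", 70, 1.78, 35)

# short dual-drink protocol used by most simulation tests
short_protocol <- function(horizon = 360) {
  buildDualDrinkProtocol(70, "vodka", 0.51, horizon = horizon)
}

# parameters with every ethanol elimination/synthesis channel switched off
elimination_free_params <- function() {
  p <- defaultParameters()
  p[c("VmaxADHSto", "VmaxADH", "VmaxCYP2E1", "VmaxEtG", "VmaxEtS")] <- 0
  p
}

# tiny deterministic dataset on the short protocol (zero-noise observations
# straight from the model trajectory, SEM fixed)
noiseless_dataset <- function(params = defaultParameters(), sem = 0.5,
                              times = c(60, 120, 180, 240),
                              observable = "yEtOH") {
  anthro <- test_subject()
  sched <- short_protocol()
  traj <- simulate(sched, anthro, params, t_grid = c(0, times),
                   rtol = 1e-8, atol = 1e-10)
  idx <- match(times, traj$times)
  obs <- data.frame(study_id = "s1", experiment_id = "e1",
                    observable = observable, time_min = times,
                    value = traj$observables[idx, observable], sem = sem,
                    n = NA_real_)
  markerDataset(obs, list(e1 = list(schedule = sched, anthro = anthro)))
}
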