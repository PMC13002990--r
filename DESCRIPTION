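Package: alcotwin
Title: Physiological Digital Twin for Alcohol Intake Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-compartment kinetic model of ethanol and its fast and slow
    markers (blood and breath alcohol, urine alcohol, ethyl glucuronide, ethyl
    sulphate, phosphatidylethanol) driven by drink, meal and urination
    schedules. Provides anthropometric volume derivation, piecewise event-aware
    ODE simulation with mass auditing, SEM-weighted least-squares estimation
    with chi-square model rejection, profile-style uncertainty bounds via an
    L1-penalised relaxation, population sensitivity sweeps, forensic scenario
    discrimination ("hipflask" analysis), and a synthetic-study generator for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: lhs, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
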