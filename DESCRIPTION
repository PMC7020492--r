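Package: pasturetemp
Title: Leaf Energy Budget Coupling for Pasture Heat-Stress Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes leaf temperature from standard weather variables with a
    linearized leaf energy budget (isothermal net radiation, boundary-layer,
    radiative and vapour conductances), validated against a nonlinear
    energy-balance solver.  Couples the resulting leaf temperatures into a
    minimal daily pasture photosynthesis model with a trapezoidal temperature
    response, a soil-water growth-limiting factor, high-temperature stress
    onset/full thresholds and a thermal-time (T-sum) recovery function.
    Includes the two-pass procedure that substitutes leaf temperature for the
    daily maximum air temperature via a soil-moisture to stomatal-conductance
    lookup, model-adequacy statistics (concordance correlation, modelling
    efficiency, mean prediction error, RMSE/MAE, response ratios, limited
    homeothermy regression), and synthetic growth-chamber and field weather
    generators so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
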