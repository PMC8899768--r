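Package: oxisim
Title: In Silico Simulation of Gut Oxalate Consumption by an Engineered
    Bacterial Therapeutic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physiologically based simulation of urinary oxalate lowering by
    an orally dosed, oxalate-consuming engineered bacterium. Couples a
    multi-compartment gastrointestinal chyme-transit model (power-exponential
    gastric emptying with windowed intestinal and colonic emptying) to
    Michaelis-Menten substrate consumption with dynamic gastric-pH damage,
    oxygen inhibition and extended colonic activity, first-order oxalate
    absorption calibrated to a dietary absorption fraction, and a plasma /
    urinary excretion balance with closed-form approach to steady state.
    Includes calibration fitting routines, synthetic-data generators with
    known ground truth, dose-regimen scenario simulation for healthy subjects
    and enteric-hyperoxaluria patients, dietary sweeps, population
    variability, and an extreme-values parameter sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
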