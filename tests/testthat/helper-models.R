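# Shared fixtures: a default model and a cheap calibrated absorption block.
default_model <- function() iss_model()

# Calibration is moderately expensive; compute once per test run.
cached_calibration <- local({
  cache <- new.env(parent = emptyenv())
  function(diet = 200, population = "healthy", model = default_model()) {
    key <- paste(diet, population, sep = "_")
    if (is.null(cache[[key]])) {
      a <- model$absorption
      a$population <- population
      cache[[key]] <- calibrate_absorption_constants(
        diet, model$transit, a, model$systemic
      )
    }
    cache[[key]]
  }
})

# Random transit parameter sets for property-style tests.
random_transit_params <- function() {
  transit_params(
    total_gastric_emptying_volume = stats::runif(1, 300, 1200),
    total_secretions_volume = stats::runif(1, 1000, 3000),
    total_si_emptying_volume = stats::runif(1, 200, 800),
    total_colon_emptying_volume = stats::runif(1, 20, 120),
    gastric_half_emptying_time = stats::runif(1, 60, 170),
    gastric_shape = stats::runif(1, 1.3, 2.3),
    tau_gastric = 240,
    tau_si = stats::runif(1, 150, 350),
    tau_colon = stats::runif(1, 1000, 2400),
    k_si_fluid_abs = stats::runif(1, 0.005, 0.02),
    k_colon_fluid_abs = stats::runif(1, 5e-4, 3e-3)
  )
}
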