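# Shared fixtures, built in code. Ensembles used by several acceptance
# checks are computed once per test run and cached here.
.cache <- new.env(parent = emptyenv())

cached_ensemble <- function(scenario, n = 500, seed = 1) {
  key <- paste0("ens_", scenario, "_", n, "_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- run_ensemble(scenario, n = n, seed = seed)
  }
  .cache[[key]]
}

# standard-man trajectory on the scenario-Y central pattern, full horizon
cached_central_y <- function() {
  if (is.null(.cache$central_y)) {
    sc <- exposure_scenario("Y")
    prof <- inhaled_concentration_profile(central_pattern(sc), sc)
    .cache$central_y <- simulate_pbpk(standard_man(), prof)
  }
  .cache$central_y
}

cached_sensitivity <- function() {
  if (is.null(.cache$sens)) .cache$sens <- sensitivity_analysis()
  .cache$sens
}

table1 <- list(
  v = c(lung = 1.44, vrg = 2.09, fat = 15.43, muscle = 17.45, liver = 1.48),
  q = c(alv = 8.90, co = 6.32, vrg = 3.20, fat = 0.34, muscle = 1.15,
        liver = 1.64),
  pc = c(blood_air = 1.08, lung = 1.24, vrg = 1.24, fat = 3.94,
         muscle = 1.34, liver = 0.88)
)
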