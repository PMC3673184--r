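# Shared fixtures: parameters are loaded once per test run.

.helper_env <- new.env()

test_params <- function() {
  if (is.null(.helper_env$params)) .helper_env$params <- default_parameters()
  .helper_env$params
}

# Degenerate one-pathway parameterization: gut -> B1 -> B3 -> urine at rate
# lambda, everything else off.  Admits the closed-form cumulative urine
# A * r * (t - (1 - exp(-lambda t)) / lambda) for constant intake r.
single_pool_params <- function(lambda = 1e-4) {
  p <- test_params()
  p$k[] <- 0
  p$k[["k_B1B3"]] <- 1.0
  p$k[["k_B3U"]] <- lambda
  p
}

# Anchored parameter set for the Bangkok male group (20-39 pair).
anchored_bkk_male <- function() {
  if (is.null(.helper_env$anchored)) {
    .helper_env$anchored <- anchor_scale(test_params(), 56, 0.33, 30,
                                         "male", "Bangkok")
  }
  .helper_env$anchored
}

constant_profile <- function(intake, age, inhaled = 0) {
  exposure_profile(rep(intake, round(age * 365)),
                   rep(inhaled, round(age * 365)), age)
}
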