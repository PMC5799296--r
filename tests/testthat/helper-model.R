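# One calibrated model shared across the whole suite (calibration is
# deterministic, so every test sees the identical object).
.model_cache <- new.env(parent = emptyenv())

cached_model <- function() {
  if (is.null(.model_cache$model)) {
    .model_cache$model <- calibrate_tdp43()
  }
  .model_cache$model
}

# an uncalibrated but self-consistent small parameter set with an exact
# baseline attached, for tests that need a cheap steady state
quick_params <- function(...) {
  p <- tdp43nar:::params_from_shape(
    shape = list(n_hill = 4, k_frag = 0.001, k_agg = 0.01, agg_K = 0.3,
                 frag_enh = 500, k_fa = 0.5),
    constraints = calibration_constraints(), ...)
  p
}

expect_state_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b[names(a)])), tol)
}
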