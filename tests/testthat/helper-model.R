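# Shared fixtures, built once per test run. Calibration is cheap (< 1 s) but
# used by most files, so the calibrated model is cached in the helper
# environment.
.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- calibrate_model()
  .fixtures$model
}

test_reference_dog <- function() {
  if (is.null(.fixtures$dog)) .fixtures$dog <- make_individual(test_model(), 10.5)
  .fixtures$dog
}

# concentration at an exact grid time
conc_at <- function(profile, t_h) {
  stats::approx(profile$time_h, profile$conc_ug_ml, xout = t_h)$y
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
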