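# Shared fixtures, built once per test run and cached (everything is
# generated in code; no stored data).

.fx <- new.env(parent = emptyenv())

fx_sched <- function() {
  if (is.null(.fx$sched)) .fx$sched <- default_schedule()
  .fx$sched
}

# canonical synthetic plasma input (1 s sampling over the 2 h acquisition)
fx_cp <- function() {
  if (is.null(.fx$cp)) .fx$cp <- make_input_function()
  .fx$cp
}

# default 32^3 phantom under the package's standard study conditions
fx_sim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulate_dynamic_pet(phantom_spec())
  .fx$sim
}

# image-derived left-ventricle input of the default phantom
fx_cplv <- function() {
  if (is.null(.fx$cplv))
    .fx$cplv <- lv_input_function(fx_sim()$image, fx_sched())
  .fx$cplv
}

# fit protocol for recovery studies: wd pinned at the generating value
# (restores identifiability, see vignette), always multi-started
fx_recovery_cfg <- function(model = "irreversible", ...) {
  fit_config(model, fixed = c(wd = 0.60), restarts = 8,
             restart_epsilon = 1e-5, ...)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual / expected - 1) <= rel_tol),
              label = sprintf("max relative deviation %.3g (tol %.3g)",
                              max(abs(actual / expected - 1)), rel_tol))
}
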