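# Synthetic input functions, noisy TACs and 4D phantoms.

test_that("the bolus input function satisfies its construction constraints", {
  spec <- input_function_spec()
  cp <- make_input_function(spec)
  expect_equal(eval_input(cp, 0), 0)
  expect_equal(eval_input(cp, spec$peak_time), spec$peak_value)
  expect_equal(max(cp$values), spec$peak_value)      # single early peak
  expect_true(all(cp$values >= 0))
  late <- eval_input(cp, 7200)
  expect_gt(late, 0)                                  # small positive plateau
  expect_lt(late, 0.25 * spec$peak_value)
})

test_that("the sampled input integral matches the analytic value within 0.1%", {
  spec <- input_function_spec()
  cp <- make_input_function(spec)
  # independent closed form: triangle + sum of exponential integrals
  analytic <- 0.5 * spec$peak_value * spec$peak_time +
    sum(spec$amplitudes * 60 / spec$lambdas *
          (1 - exp(-spec$lambdas * (7200 - spec$peak_time) / 60)))
  expect_lt(abs(input_cumint(cp, 7200) / analytic - 1), 1e-3)
})

test_that("invalid input-function specs are rejected", {
  expect_error(input_function_spec(peak_time = 0),
               class = "fmisopet_invalid_spec")
  expect_error(input_function_spec(lambdas = c(0.1, 0.25, 4)),
               class = "fmisopet_invalid_spec")
  expect_error(input_function_spec(fractions = c(0.5, 0.4, 0.2)),
               class = "fmisopet_invalid_spec")
})

test_that("simulated TACs are exact at zero noise and seeded-reproducible", {
  p <- preset_params("MDA-1h")
  cp <- fx_cp()
  sched <- fx_sched()
  model <- frame_average_signal(p, cp, sched)
  expect_equal(simulate_tac(p, cp, sched)$values, model$values)
  a <- simulate_tac(p, cp, sched, noise_sigma0 = 3, seed = 5)
  b <- simulate_tac(p, cp, sched, noise_sigma0 = 3, seed = 5)
  d <- simulate_tac(p, cp, sched, noise_sigma0 = 3, seed = 6)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
  expect_error(simulate_tac(p, cp, sched, noise_sigma0 = -1),
               class = "fmisopet_invalid_spec")
})

test_that("replicate noise is zero-mean with the counting-statistics scale", {
  p <- preset_params("MDA-1h")
  cp <- fx_cp()
  sched <- fx_sched()
  model <- frame_average_signal(p, cp, sched)
  reps <- simulate_tac(p, cp, sched, noise_sigma0 = 3, seed = 2, n_rep = 1000)
  mat <- vapply(reps, function(r) r$values, numeric(52))
  sds <- 3 * sqrt(pmax(model$values, 0) / frame_durations(sched))
  se <- sds / sqrt(1000)
  dev <- abs(rowMeans(mat) - model$values)
  expect_true(all(dev <= 3.5 * se + 1e-12))          # CLT band per frame
  expect_rel_equal(apply(mat, 1, stats::sd)[20:52], sds[20:52], 0.25)
})

test_that("phantom regions partition the grid and the core fraction is exact", {
  sim <- fx_sim()
  m <- sim$masks
  total <- m$core + m$rim + m$muscle + m$blood
  expect_true(all(total == 1))                        # disjoint cover
  expect_equal(m$tumor, m$core | m$rim)
  n_tum <- sum(m$tumor)
  expect_equal(sum(m$core), round(0.3 * n_tum))       # exact by construction
  expect_equal(dim(sim$image), c(32, 32, 32, 52))
})

test_that("phantom generation is bit-reproducible for a fixed spec", {
  s1 <- simulate_dynamic_pet(phantom_spec(shape = c(12, 12, 12), seed = 4))
  s2 <- simulate_dynamic_pet(phantom_spec(shape = c(12, 12, 12), seed = 4))
  expect_identical(s1$image, s2$image)
  s3 <- simulate_dynamic_pet(phantom_spec(shape = c(12, 12, 12), seed = 5))
  expect_false(identical(s3$image, s1$image))
})

test_that("a zero-noise phantom round-trips region TACs through extraction", {
  sim <- simulate_dynamic_pet(phantom_spec(shape = c(16, 16, 16),
                                           noise_sigma0 = 0))
  for (rg in c("rim", "core", "muscle")) {
    got <- extract_tac(sim$image, sim$masks[[rg]], sim$schedule)
    want <- frame_average_signal(sim$truth$params[[rg]], sim$cp,
                                 sim$schedule)
    expect_lt(max(abs(got$values - want$values)) / max(want$values), 1e-3)
  }
})

test_that("scenario presets carry the reference parameter means", {
  p <- preset_params("MDA-1h")
  expect_equal(c(p$K1, p$k2, p$k3), c(0.0255, 0.00286, 0.03314))
  u <- preset_params("U87MG-1h")
  expect_equal(c(u$K1, u$k2, u$k3), c(0.1095, 0.0602, 0.0109))
  expect_equal(u$wp + u$wd + u$wa, 1)
  expect_error(preset_params("nope"), class = "fmisopet_invalid_spec")
})

test_that("truth maps carry the observable slope and the generating k3", {
  sim <- fx_sim()
  core_p <- sim$truth$params$core
  expect_equal(unique(sim$truth$k3[sim$masks$core]), core_p$k3)
  expect_equal(unique(sim$truth$ki[sim$masks$core]),
               core_p$wa * macro_influx_rate(core_p))
  expect_equal(unique(sim$truth$ki[sim$masks$blood]), 0)
})
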