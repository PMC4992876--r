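# ROI thresholding, TAC extraction, LV input recovery, static T/B scoring.

test_that("thresholding a uniform volume selects the whole box", {
  vol <- array(3, c(8, 8, 8))
  box <- list(lo = c(2, 2, 2), hi = c(5, 5, 5))
  mask <- threshold_roi(vol, box, frac = 0.5)
  expect_equal(sum(mask), 4^3)
  expect_true(all(which(mask, arr.ind = TRUE) >= 2) &&
                all(which(mask, arr.ind = TRUE) <= 5))
})

test_that("a hot sphere is segmented to within 15% of its volume", {
  dm <- c(24, 24, 24)
  centre <- c(12, 12, 12); r <- 6
  ax <- seq_len(24)
  d2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, "+"),
              (ax - centre[3])^2, "+")
  vol <- array(1, dm); vol[d2 <= r^2] <- 10
  mask <- threshold_roi(vol, frac = 0.5)
  expect_true(all(d2[mask] <= r^2))               # mask within sphere support
  expect_lt(abs(sum(mask) / sum(d2 <= r^2) - 1), 0.15)
})

test_that("a 0.99 threshold keeps only the top level of a two-level phantom", {
  vol <- array(1, c(6, 6, 6))
  vol[1:2, 1, 1] <- 5
  mask <- threshold_roi(vol, frac = 0.99)
  expect_equal(sum(mask), 2)
  expect_true(all(vol[mask] == 5))
})

test_that("threshold masks shrink monotonically with frac", {
  vol <- with_seed(3, array(runif(16^3), c(16, 16, 16)))
  vol[6:10, 6:10, 6:10] <- vol[6:10, 6:10, 6:10] + 2   # one hot blob
  prev <- NULL
  for (f in c(0.3, 0.5, 0.7, 0.9)) {
    m <- threshold_roi(vol, frac = f, keep_largest = FALSE)
    if (!is.null(prev)) expect_true(all(!m | prev))  # m subset of prev
    prev <- m
  }
})

test_that("only the largest connected component is kept", {
  vol <- array(0, c(10, 10, 10))
  vol[2:5, 2:5, 2:5] <- 10     # 64 voxels
  vol[8:9, 8:9, 8:9] <- 10     # 8 voxels, disconnected
  mask <- threshold_roi(vol, frac = 0.5)
  expect_equal(sum(mask), 64)
  expect_false(mask[8, 8, 8])
})

test_that("invalid boxes and fractions are rejected", {
  vol <- array(1, c(4, 4, 4))
  expect_error(threshold_roi(vol, list(lo = c(1, 1, 1), hi = c(9, 4, 4))),
               class = "fmisopet_invalid_spec")
  expect_error(threshold_roi(vol, frac = 0), class = "fmisopet_invalid_spec")
  expect_error(threshold_roi(vol, frac = 1), class = "fmisopet_invalid_spec")
})

test_that("TAC extraction averages masked voxels and is linear", {
  sched <- build_frame_schedule(list(c(5, 60)))
  dm <- c(4, 4, 4, 5)
  img <- with_seed(9, array(runif(prod(dm)), dm))
  mask <- array(FALSE, dm[1:3]); mask[2, 3, 1] <- TRUE
  expect_equal(extract_tac(img, mask, sched)$values, img[2, 3, 1, ])
  # uniform image -> constant TAC
  imgc <- array(4.2, dm)
  maskc <- array(TRUE, dm[1:3])
  expect_equal(extract_tac(imgc, maskc, sched)$values, rep(4.2, 5))
  # linearity in intensity
  m2 <- array(FALSE, dm[1:3]); m2[1:2, 1, 1] <- TRUE
  t1 <- extract_tac(img, m2, sched)$values
  t3 <- extract_tac(array(3 * img, dm), m2, sched)$values
  expect_equal(t3, 3 * t1)
  # grid and consistency errors
  expect_error(extract_tac(img, array(TRUE, c(3, 4, 4)), sched),
               class = "fmisopet_grid")
  expect_error(extract_tac(img, maskc, build_frame_schedule(list(c(4, 60)))),
               class = "fmisopet_consistency")
  expect_error(extract_tac(img, array(FALSE, dm[1:3]), sched),
               class = "fmisopet_empty_roi")
})

test_that("the LV input function is recovered exactly from a noiseless phantom", {
  sim <- simulate_dynamic_pet(phantom_spec(shape = c(16, 16, 16),
                                           noise_sigma0 = 0))
  cp_rec <- lv_input_function(sim$image, sim$schedule)
  mask <- attr(cp_rec, "mask")
  expect_equal(array(mask, dim(mask)), sim$masks$blood)
  # the blood-pool voxel series is the frame-averaged C_p; recovery is exact
  truth <- frame_average_signal(kinetic_params(0, 0, 0, wp = 1, wd = 0),
                                sim$cp, sim$schedule)
  rec <- attr(cp_rec, "tac")
  expect_lt(max(abs(rec$values - truth$values)) / max(truth$values), 0.005)
})

test_that("schedules without an early frame cannot define the LV ROI", {
  img <- array(1, c(4, 4, 4, 2))
  sched <- build_frame_schedule(list(c(2, 120)))
  expect_error(lv_input_function(img, sched), class = "fmisopet_invalid_spec")
})

test_that("static T/B scoring reproduces the worked scenarios", {
  # non-hypoxic glioma scenario: 0.75 / 0.82 -> ~0.9
  s1 <- static_summary(0.75, 0.82)
  expect_equal(s1$tb_ratio, 0.75 / 0.82)
  expect_lt(abs(s1$tb_ratio - 0.9), 0.05)
  expect_false(s1$hypoxic)
  # intrinsically hypoxic scenario: 1.92 / 0.65 -> ~3
  s2 <- static_summary(1.92, 0.65)
  expect_lt(abs(s2$tb_ratio - 3), 0.06)
  expect_true(s2$hypoxic)
  # the 1.2 cutoff is strict
  s3 <- static_summary(1.2 * 0.7, 0.7)
  expect_equal(s3$tb_ratio, 1.2)
  expect_false(s3$hypoxic)
  expect_error(static_summary(1, 0), class = "fmisopet_invalid_blood")
})
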