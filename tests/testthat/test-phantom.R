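test_that("projection of a zero-activity phantom is identically zero", {
  spec <- box_phantom(activity = 0)
  expect_true(all(build_projection(spec, "posterior")$pixels == 0))
  expect_true(all(build_projection(spec, "anterior")$pixels == 0))
})

test_that("posterior box projection matches the closed-form slab integral", {
  spec <- box_phantom(activity = 100, x = 6, a = 4)
  post <- build_projection(spec, "posterior")
  expect_equal(sum(post$pixels),
               slab_rate_oracle(10.9, 100, 0.119, d = 4, x = 6),
               tolerance = 1e-12)
  # per-pixel numeric summation oracle: subdivide the chord into slivers
  n_sub <- 4000
  dz <- 6 / n_sub
  depths <- 4 + (seq_len(n_sub) - 0.5) * dz
  numeric_total <- 10.9 * 100 * sum(exp(-0.119 * depths)) * dz / 6
  expect_equal(sum(post$pixels), numeric_total, tolerance = 1e-6)
})

test_that("anterior/posterior totals differ by the depth-asymmetry factor", {
  x <- 6; a <- 3; trunk <- 20
  spec <- box_phantom(activity = 50, x = x, a = a, trunk = trunk)
  post <- sum(build_projection(spec, "posterior")$pixels)
  ant <- sum(build_projection(spec, "anterior")$pixels)
  expect_equal(ant / post, exp(-0.119 * (trunk - x - 2 * a)),
               tolerance = 1e-12)
})

test_that("detected rate is linear in compartment activity", {
  s1 <- box_phantom(activity = 70)
  s2 <- box_phantom(activity = 140)
  expect_equal(2 * sum(build_projection(s1, "posterior")$pixels),
               sum(build_projection(s2, "posterior")$pixels),
               tolerance = 1e-12)
})

test_that("posterior rate strictly decreases with source depth", {
  totals <- vapply(c(0, 2, 5, 9, 13), function(a) {
    sum(build_projection(box_phantom(a = a), "posterior")$pixels)
  }, 0)
  expect_true(all(diff(totals) < 0))
})

test_that("anterior image of a laterally symmetric phantom is its own mirror", {
  cam <- default_camera()
  kid <- box_region("k", 5, 14, 7, 12, 6, 4, 80)   # cols 7..12 centred on 20
  spec <- phantom_spec(20, 0.5, 24, 20, list(kid), cam)
  ant <- build_projection(spec, "anterior")$pixels
  expect_equal(ant, ant[, ncol(ant):1])
})

test_that("compartments outside the slab are rejected by name", {
  cam <- default_camera()
  bad <- box_region("deep_kidney", 1, 2, 1, 2, thickness_x = 6,
                    depth_a = 15, activity = 1)
  expect_error(phantom_spec(20, 0.5, 24, 20, list(bad), cam),
               "deep_kidney")
})

test_that("ellipsoid projection conserves total emission and respects chords", {
  cam <- camera_model(10.9, 0, 20)   # mu = 0: every decay is detected
  ell <- ellipsoid_region("kid", 10, 10, 6, 4, thickness_x = 5,
                          depth_a = 3, activity = 40)
  spec <- phantom_spec(20, 0.5, 24, 20, list(ell), cam)
  post <- build_projection(spec, "posterior")
  expect_equal(sum(post$pixels), 10.9 * 40, tolerance = 1e-12)
  expect_true(max(ell$chords) <= 5)
})

test_that("Poisson sampling is seed-deterministic and mean-accurate", {
  spec <- box_phantom()
  rate <- build_projection(spec, "posterior")
  expect_identical(sample_counts(rate, 7)$pixels,
                   sample_counts(rate, 7)$pixels)
  zero <- build_projection(box_phantom(activity = 0), "posterior")
  expect_true(all(sample_counts(zero, 1)$pixels == 0))
  # law of large numbers on a single pixel of mean 1e4
  one_px <- planardose:::new_rate_image(matrix(500), "posterior", NA,
                                        0.5, 20)   # 500 cps * 20 s = 1e4
  draws <- vapply(1:1000, function(s) sample_counts(one_px, s)$pixels[1], 0)
  expect_lt(abs(mean(draws) - 1e4) / 1e4, 0.01)
})

test_that("calibration series follows the generating exponential", {
  cam <- default_camera()
  s <- make_calibration_series(cam, depths = c(2, 3, 4), 330, 300)
  expect_equal(s$counts[2] / s$counts[1], exp(-0.119), tolerance = 1e-12)
  expect_equal(s$counts[3] / s$counts[2], exp(-0.119), tolerance = 1e-12)
  expect_true(all(make_calibration_series(cam, 1:5, 330, 300,
                                          seed = 3)$counts ==
                  make_calibration_series(cam, 1:5, 330, 300,
                                          seed = 3)$counts))
  expect_error(make_calibration_series(cam, numeric(0), 330, 300))
})

test_that("patient series applies kinetics and physical decay", {
  spec <- box_phantom(activity = 1)
  lp <- lu177_lambda_phys()
  times <- c(1, 24, 48, 168)
  kin <- list(kidney = monoexp_kinetics(100, 0.005))
  ser <- make_patient_series(spec, kin, times, noiseless = TRUE,
                             lambda_phys = lp)
  roi <- kidney_roi(spec)
  rates <- vapply(ser, function(fr) roi_rate(fr$posterior, roi)$total_cps, 0)
  # underlying activity decays with lambda_bio + lambda_phys
  expect_equal(rates / rates[1],
               exp(-(0.005 + lp) * (times - 1)), tolerance = 1e-9)
  # lambda_bio = 0: purely physical decay at the camera
  ser0 <- make_patient_series(spec, list(kidney = monoexp_kinetics(100, 0)),
                              times, noiseless = TRUE, lambda_phys = lp)
  r0 <- vapply(ser0, function(fr) roi_rate(fr$posterior, roi)$total_cps, 0)
  expect_equal(r0 / r0[1], exp(-lp * (times - 1)), tolerance = 1e-9)
})

test_that("biphasic kinetics rise from zero and peak strictly after t = 0", {
  kin <- biphasic_kinetics(100, log(2) / 80, log(2) / 2)
  t_peak <- log((log(2) / 2) / (log(2) / 80)) /
    (log(2) / 2 - log(2) / 80)
  expect_gt(t_peak, 0)
  expect_gt(kinetic_activity(kin, t_peak), kinetic_activity(kin, 0.01))
  expect_gt(kinetic_activity(kin, t_peak), kinetic_activity(kin, 168))
  opt <- optimize(function(t) kinetic_activity(kin, t), c(0, 168),
                  maximum = TRUE)
  expect_equal(opt$maximum, t_peak, tolerance = 1e-4)
  expect_error(monoexp_kinetics(-5, 0.01))
})
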