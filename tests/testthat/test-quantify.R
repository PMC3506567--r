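test_that("roi_rate matches a brute-force pixel sum", {
  set.seed(4)
  m <- matrix(rpois(25, 40), 5, 5)
  img <- planardose:::new_count_image(m, "posterior", NA, 0.5, 10)
  roi <- roi_mask(rbind(c(0, 0), c(1, 3), c(4, 4), c(2, 2)))
  brute <- (m[1, 1] + m[2, 4] + m[5, 5] + m[3, 3]) / 10
  r <- roi_rate(img, roi)
  expect_equal(r$total_cps, brute)
  expect_equal(r$mean_cpp, brute / 4)
  # uniform image: total = c*n/dwell, mean = c/dwell
  u <- planardose:::new_count_image(matrix(7, 5, 5), "posterior", NA, 0.5, 1)
  expect_equal(roi_rate(u, roi)$total_cps, 28)
  expect_error(roi_rate(img, roi_mask(rbind(c(0, 9)))), "outside")
})

test_that("ROI mirroring flips columns and is an involution", {
  roi <- roi_mask(rbind(c(3, 0), c(5, 100)))
  m <- mirror_roi(roi, 256)
  expect_equal(m$pixels[1, ], c(3, 255))
  expect_equal(m$pixels[2, ], c(5, 155))
  expect_equal(mirror_roi(m, 256)$pixels, roi$pixels)
  # laterally centred symmetric mask maps to itself (as a set)
  sym <- roi_mask(rbind(c(2, 4), c(2, 5)))
  ms <- mirror_roi(sym, 10)
  expect_setequal(paste(ms$pixels[, 1], ms$pixels[, 2]),
                  paste(sym$pixels[, 1], sym$pixels[, 2]))
})

test_that("partial-ROI extrapolation scales by pixel fraction", {
  expect_equal(extrapolate_partial(50, 10, 20), 100)
  expect_equal(extrapolate_partial(77, 15, 15), 77)
  expect_error(extrapolate_partial(50, 0, 20))
  # exact on a uniform source: partial and full ROI agree
  spec <- box_phantom(activity = 60)
  post <- build_projection(spec, "posterior")
  full <- kidney_roi(spec)
  part <- roi_mask(full$pixels[1:12, ], kind = "partial-kidney")
  expect_equal(extrapolate_partial(roi_rate(post, part)$total_cps, 12,
                                   nrow(full$pixels)),
               roi_rate(post, full)$total_cps, tolerance = 1e-12)
})

test_that("background subtraction scales by the non-kidney thickness fraction", {
  r <- background_correct(10, 4, trunk_T = 20, thickness_x = 6,
                          n_kidney_pixels = 50)
  expect_equal(r$per_pixel_cps, 10 - 4 * 14 / 20)
  expect_equal(r$total_cps, 7.2 * 50)
  expect_false(r$clamped)
  expect_equal(background_correct(10, 0, 20, 6, 50)$per_pixel_cps, 10)
  expect_equal(background_correct(10, 4, 20, 0, 50)$per_pixel_cps, 6)
  neg <- background_correct(1, 10, 20, 6, 50)
  expect_equal(neg$total_cps, 0)
  expect_true(neg$clamped)
  expect_error(background_correct(10, 4, 20, 21, 50), "exceeds")
})

test_that("conjugate-view estimate evaluates the attenuation-corrected geometric mean", {
  calib <- default_calib()
  mu <- 0.119; x <- 6; Tt <- 20
  expected <- sqrt(100 * 100) * exp(mu * Tt / 2) * (mu * x) /
    (10.9 * (exp(mu * x / 2) - exp(-mu * x / 2)))
  est <- activity_cv(100, 100, Tt, x, calib)
  expect_equal(est$activity, expected, tolerance = 1e-12)
  expect_equal(est$activity, 29.5270, tolerance = 1e-4)
  # x -> 0 limit: thickness factor -> 1
  expect_equal(activity_cv(100, 100, 20, 0, calib)$activity,
               100 * exp(mu * 10) / 10.9, tolerance = 1e-12)
  expect_error(activity_cv(100, 100, 20, 25, calib))
})

test_that("posterior-only estimate corrects depth and self-attenuation", {
  calib <- default_calib()
  mu <- 0.119; x <- 6
  expected <- 100 * exp(mu * 4) * (mu * x) / (10.9 * (1 - exp(-mu * x)))
  est <- activity_pa(100, 4, x, calib)
  expect_equal(est$activity, expected, tolerance = 1e-12)
  expect_equal(est$activity, 20.66, tolerance = 1e-3)
  expect_equal(activity_pa(100, 0, 0, calib)$activity, 100 / 10.9,
               tolerance = 1e-12)
})

test_that("CV inverts the noiseless forward model at every depth", {
  calib <- default_calib()
  for (a in c(0, 1, 3, 5, 8, 12)) {
    spec <- box_phantom(activity = 100, x = 6, a = a)
    post <- build_projection(spec, "posterior")
    ant <- build_projection(spec, "anterior")
    roi <- kidney_roi(spec)
    rp <- roi_rate(post, roi)$total_cps
    ra <- roi_rate(ant, mirror_roi(roi, spec$grid_cols))$total_cps
    expect_lt(abs(activity_cv(ra, rp, 20, 6, calib)$activity / 100 - 1),
              1e-9)
  }
})

test_that("PA is exact at the true depth and biased by exp(mu*da) otherwise", {
  calib <- default_calib()
  spec <- box_phantom(activity = 100, x = 6, a = 4)
  rp <- roi_rate(build_projection(spec, "posterior"), kidney_roi(spec))$total_cps
  expect_lt(abs(activity_pa(rp, 4, 6, calib)$activity / 100 - 1), 1e-9)
  for (da in c(-2, -1, 0.5, 1, 2)) {
    est <- activity_pa(rp, 4 + da, 6, calib)$activity
    expect_equal(est / 100, exp(0.119 * da), tolerance = 1e-9)
  }
})

test_that("both estimators are homogeneous of degree one in counts", {
  calib <- default_calib()
  expect_equal(activity_cv(300, 500, 20, 6, calib)$activity,
               10 * activity_cv(30, 50, 20, 6, calib)$activity,
               tolerance = 1e-12)
  expect_equal(activity_pa(840, 4, 6, calib)$activity,
               8.4 * activity_pa(100, 4, 6, calib)$activity,
               tolerance = 1e-12)
})
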