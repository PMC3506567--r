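tab <- load_cohort_table()

test_that("packaged cohort table loads with the full patient set and markers", {
  expect_equal(length(unique(tab$patient)), 33)
  expect_equal(nrow(tab), 66 * 5)
  expect_equal(sum(!is.na(tab$d_per_a)), 163)
  # marker semantics: NA/ND/NP parsed as missing with reason preserved
  p5r <- tab[tab$patient == 5 & tab$kidney == "right", ]
  expect_true(all(p5r$marker == "NP"))
  expect_true(all(is.na(p5r$d_per_a)))
  p1l <- tab[tab$patient == 1 & tab$kidney == "left" & tab$cycle == 1, ]
  expect_equal(p1l$marker, "NA")
  # a malformed numeric cell is rejected with its location
  bad <- tempfile(fileext = ".tsv")
  w <- attr(tab, "wide"); w$cycle1[3] <- "0.3.8"
  utils::write.table(w, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort_table(bad), "0\\.3\\.8")
})

test_that("cohort table round-trips through write/read byte-identically", {
  f <- tempfile(fileext = ".tsv")
  write_cohort_table(tab, f)
  again <- load_cohort_table(f)
  expect_identical(attr(again, "wide"), attr(tab, "wide"))
  expect_equal(again$d_per_a, tab$d_per_a)
})

test_that("dose summaries weight every kidney-cycle entry equally", {
  s <- summarize_doses(tab, "all")
  expect_equal(s$n, 163)
  expect_equal(s$sem, s$sd / sqrt(163), tolerance = 1e-12)
  expect_true(s$min <= s$mean && s$mean <= s$max)
  s1 <- summarize_doses(tab, "first")
  expect_equal(s1$n, 55)
  expect_gt(s1$mean, s$mean - 0.1)
  # summaries are invariant under row permutation
  set.seed(2)
  shuf <- tab[sample(nrow(tab)), ]
  attr(shuf, "wide") <- attr(tab, "wide")
  class(shuf) <- class(tab)
  expect_equal(summarize_doses(shuf, "all"), s)
})

test_that("per-cycle deviations are ratios to the first cycle, per side", {
  cd <- cycle_deviations(tab)
  expect_equal(cd$kidney, c("right", "left"))
  # patient 27 left: 0.68 -> 1.2 gives +76.5%
  p27 <- tab[tab$patient == 27 & tab$kidney == "left", "d_per_a"]
  expect_equal(100 * (p27[2] / p27[1] - 1), 76.47, tolerance = 1e-2)
  expect_true(cd$max_pct[2] >= 76.47)
  # identical doses across cycles -> all deviations zero
  w <- attr(tab, "wide")
  w[, paste0("cycle", 1:5)] <- "1.0"
  f <- tempfile(fileext = ".tsv")
  utils::write.table(w, f, sep = "\t", quote = FALSE, row.names = FALSE)
  flat <- cycle_deviations(load_cohort_table(f))
  expect_equal(flat$mean_pct, c(0, 0))
  expect_equal(flat$sd_pct, c(0, 0))
})

test_that("omitting a point from an exact mono-exponential changes nothing", {
  lb <- log(2) / 60
  times <- c(1, 24, 48, 168)
  exact <- lapply(c(100, 250), function(A0) {
    time_activity_series(times, A0 * exp(-lb * times),
                         decay_corrected = TRUE)
  })
  om <- omit_timepoint_study(exact)
  expect_equal(om$mean_ratio, rep(1, 4), tolerance = 1e-6)
  expect_equal(om$n_unbounded, rep(0L, 4))
  # wrong schedule is refused
  short <- list(time_activity_series(c(1, 24, 48), c(3, 2, 1),
                                     decay_corrected = TRUE))
  expect_error(omit_timepoint_study(short), "exactly")
})

test_that("day-2-peaked slow clearance goes unbounded without the day-7 point", {
  # biphasic truth peaking near day 1-2: the 3-point refit (1 h, 1 d, 2 d)
  # sees a net rise and extrapolates growth
  kin <- biphasic_kinetics(100, log(2) / 120, log(2) / 10)
  times <- c(1, 24, 48, 168)
  s <- time_activity_series(times, kinetic_activity(kin, times),
                            decay_corrected = TRUE)
  om <- omit_timepoint_study(list(s))
  expect_equal(om$n_unbounded[om$omit_h == 168], 1L)
  # omitting 1 h changes A0 relative to the full fit (independent refit)
  oracle <- fit_monoexp(time_activity_series(times[-1],
                                             s$activity_MBq[-1],
                                             decay_corrected = TRUE))
  full <- fit_monoexp(s)
  expect_false(isTRUE(all.equal(oracle$A0, full$A0, tolerance = 1e-4)))
})

test_that("method comparison reports paired statistics and regression", {
  v <- c(0.5, 0.8, 1.1, 0.7, 0.9)
  same <- method_comparison(v, v)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  shift <- method_comparison(v, v - 0.2)
  expect_equal(shift$mean_difference, 0.2, tolerance = 1e-12)
  expect_equal(shift$slope, 1, tolerance = 1e-12)
  expect_equal(shift$correlation, 1, tolerance = 1e-12)
  expect_true(is.na(shift$p_value))   # zero-variance differences
  set.seed(9)
  a <- runif(10); b <- a - 0.1 + rnorm(10, 0, 0.01)
  mc <- method_comparison(a, b)
  expect_lt(mc$p_value, 1e-4)
  expect_gt(mc$mean_difference, 0)
})

test_that("deep kidneys bias the posterior-only method low", {
  mc <- simulate_cv_pa_cohort(n = 8, depth_error_cm = 1.5, seed = 5)
  expect_lt(mean(mc$pa_per_GBq), mean(mc$cv_per_GBq))
  # noiseless single-kidney check of the bias factor
  d_cv <- planardose:::simulate_kidney_dose(6, 20, 4, 0.15)
  d_pa <- planardose:::simulate_kidney_dose(6, 20, 4, 0.15,
                                            assumed_a = 3, method = "PA")
  expect_equal(d_pa$dose_per_GBq / d_cv$dose_per_GBq, exp(-0.119),
               tolerance = 1e-6)
})

test_that("standard-size doses scale with the inverse assumed mass and geometry", {
  geo <- data.frame(patient = 1, kidney = "left", sex = "M",
                    kidney_thickness_cm = 6, mass_kg = 0.155,
                    trunk_cm = 20)
  ss <- size_sensitivity(geo)
  expect_equal(ss$ratio, 1, tolerance = 1e-9)   # geometry equals standard
  # smallest kidney in the cohort: mass term alone gives 0.088/0.155
  geo2 <- data.frame(patient = 14, kidney = "left", sex = "M",
                     kidney_thickness_cm = 6, mass_kg = 0.088,
                     trunk_cm = 20)
  expect_equal(size_sensitivity(geo2)$ratio, 0.088 / 0.155,
               tolerance = 1e-9)
  # monotone in true mass, all else fixed
  ratios <- vapply(c(0.08, 0.12, 0.155, 0.20), function(m) {
    g <- geo; g$mass_kg <- m
    size_sensitivity(g)$ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})
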