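test_that("prescription generator is deterministic under a fixed seed", {
  tt <- trend_truth()
  a <- gen_prescription_data(tt, seed = 99L)
  b <- gen_prescription_data(tt, seed = 99L)
  expect_identical(a, b)
  c <- gen_prescription_data(tt, seed = 100L)
  expect_false(identical(a$prescriptions, c$prescriptions))
})

test_that("constant-trend Poisson limit gives a flat 500 per 1,000", {
  tt <- trend_truth(intercept_log_rate = log(0.5), slope_pre = 0,
                    slope_post = 0, sex_effect = 0, dispersion = Inf)
  nf <- gen_prescription_data(tt, noise = FALSE)
  expect_equal(nf$rate_per_1000, rep(500, nrow(nf)))
  # large-count noisy mean stays close in relative terms
  tt_big <- trend_truth(intercept_log_rate = log(0.5), slope_pre = 0,
                        slope_post = 0, sex_effect = 0, dispersion = Inf,
                        births_per_year = 1e7)
  noisy <- gen_prescription_data(tt_big, seed = 5L)
  expect_lt(max(abs(noisy$rate_per_1000 - 500) / 500), 0.01)
})

test_that("post-break log-rate ratios track the generating slope", {
  tt <- trend_truth(slope_pre = -0.02, slope_post = -0.09)
  ratios <- vapply(1:50, function(s) {
    d <- gen_prescription_data(tt, seed = s)
    f <- d[d$sex == "female" & d$year >= 2006, ]
    f <- f[order(f$year), ]
    mean(diff(log(f$rate_per_1000)))
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - tt$slope_post), 3 * se)
})

test_that("prescription generator validates its inputs", {
  tt <- trend_truth()
  expect_error(gen_prescription_data(tt, years = integer(0)), "non-empty")
  expect_error(gen_prescription_data(tt, years = 2010:2018),
               "break_year")
  expect_error(trend_truth(dispersion = 0), "dispersion")
  expect_error(trend_truth(births_per_year = -5), "births")
})

test_that("study generator hits the noise-free linear predictor", {
  # with beta0 = beta_age = 0 and no heterogeneity, the logged effect at
  # dose d is exactly beta_dose * d (canada intercept fixed at 0 too)
  mt <- meta_truth(beta0 = 0, beta_age = 0, beta_dose = 0.05, sigma_u = 0,
                   canada_effect = 0, se_range = c(1e-12, 1e-12))
  st <- gen_meta_studies(mt, seed = 3L)
  expect_equal(st$log_effect, 0.05 * st$dose, tolerance = 1e-9)
  # full linear predictor reproduced on the (age, dose) grid
  mt2 <- meta_truth(beta0 = 1.71, beta_age = -0.23, beta_dose = 0.05,
                    sigma_u = 0, canada_effect = 0,
                    se_range = c(1e-12, 1e-12))
  st2 <- gen_meta_studies(mt2, seed = 3L)
  expect_equal(st2$log_effect,
               1.71 - 0.23 * st2$age_mid + 0.05 * st2$dose,
               tolerance = 1e-9)
})

test_that("study generator flags exactly one Canadian study", {
  st <- gen_meta_studies(meta_truth(), seed = 8L)
  expect_identical(length(unique(st$study_id[st$canada_flag])), 1L)
  expect_identical(a <- sort(unique(st$dose)), 1:5)
  expect_true(all(st$age_range_width < 6))
  expect_identical(gen_meta_studies(meta_truth(), seed = 8L), st)
  expect_error(meta_truth(n_studies = 1), "n_studies")
  expect_error(meta_truth(se_range = c(0, 1)), "se_range")
})

test_that("calibration tables cover ages 3-18 with valid shapes", {
  cal <- gen_calibration()
  expect_setequal(unique(cal$age), 3:18)
  expect_setequal(as.character(unique(cal$sex)), c("female", "male"))
  expect_true(all(cal$incidence >= 0 & cal$incidence <= 1))
  expect_true(all(cal$remission >= 0 & cal$remission <= 1))
  expect_true(all(cal$exacerbation_rate >= 0))
  # onset rises then falls with age (unimodal, peak before 10)
  f <- cal[cal$sex == "female", ]
  f <- f[order(f$age), ]
  peak <- which.max(f$incidence)
  expect_lt(f$age[peak], 10)
  expect_true(all(diff(f$incidence[1:peak]) >= 0))
  expect_true(all(diff(f$incidence[peak:nrow(f)]) <= 0))
  # adolescent remission exceeds childhood remission
  expect_gt(f$remission[f$age == 17], f$remission[f$age == 5])
})

test_that("extreme calibration shapes error instead of clamping", {
  expect_error(gen_calibration(calibration_shape(peak_incidence = 1.5)),
               "\\[0, 1\\]")
  expect_error(calibration_shape(peak_age = 12), "before age 10")
})

test_that("truth parameters round-trip through YAML", {
  tt <- trend_truth()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(tt, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$slope_post, tt$slope_post)
  expect_equal(back$.class, "trend_truth")
})

test_that("substream seeds are distinct, stable integers", {
  s <- vapply(c("prescriptions", "meta", "calibration", "microsim"),
              function(k) substream_seed(123, k), integer(1))
  expect_identical(length(unique(s)), 4L)
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(substream_seed(123, "meta"), substream_seed(123, "meta"))
})
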