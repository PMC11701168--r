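test_that("noise-free generate-then-fit recovers both slopes exactly", {
  tt <- trend_truth()
  nf <- gen_prescription_data(tt, noise = FALSE)
  fit <- fit_nb_trend(nf)
  slope_pre <- fit$coefficients[["t"]]
  slope_post <- slope_pre + fit$coefficients[["t:post"]]
  expect_equal(slope_pre, tt$slope_pre, tolerance = 1e-6)
  expect_equal(slope_post, tt$slope_post, tolerance = 1e-6)
  expect_equal(fit$coefficients[["sexmale"]], tt$sex_effect,
               tolerance = 1e-6)
  expect_identical(fit$dispersion, Inf)
})

test_that("row aggregation does not change the fit", {
  dat <- gen_prescription_data(trend_truth(dispersion = Inf), seed = 21L)
  # split every count across two half-rows; the offset log-likelihood
  # depends on the data only through per-cell totals
  half <- dat
  half$births <- dat$births / 2
  half$prescriptions <- dat$prescriptions / 2
  dup <- rbind(half, half)
  f1 <- fit_nb_trend(dat, dispersion = Inf)
  f2 <- fit_nb_trend(dup, dispersion = Inf)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("sex coefficient interval covers zero when truth has no sex gap", {
  tt <- trend_truth(sex_effect = 0, dispersion = 50)
  covered <- vapply(1:100, function(s) {
    fit <- fit_nb_trend(gen_prescription_data(tt, seed = s))
    b <- fit$coefficients[["sexmale"]]
    se <- sqrt(fit$vcov["sexmale", "sexmale"])
    abs(b) < stats::qnorm(0.975) * se
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("deviance explained behaves like a GLM R-squared", {
  tt <- trend_truth(dispersion = Inf, births_per_year = 1e6)
  fit <- fit_nb_trend(gen_prescription_data(tt, seed = 2L))
  de <- deviance_explained(fit)
  expect_gt(de, 99)
  expect_lte(de, 100)
  # the null model explains exactly none of its own deviance
  null_fit <- fit_nb_trend(gen_prescription_data(tt, seed = 2L),
                           terms = character(0))
  expect_equal(deviance_explained(null_fit), 0, tolerance = 1e-8)
  # invariant to relabeling of the sexes
  dat <- gen_prescription_data(trend_truth(), seed = 4L)
  swapped <- dat
  swapped$sex <- factor(ifelse(dat$sex == "male", "female", "male"),
                        levels = c("female", "male"))
  expect_equal(deviance_explained(fit_nb_trend(swapped)),
               deviance_explained(fit_nb_trend(dat)), tolerance = 1e-8)
})

test_that("degenerate designs are reported, one-sided years downgraded", {
  dat <- gen_prescription_data(trend_truth(), seed = 1L)
  pre_only <- dat[dat$year <= 2005, ]
  expect_warning(fit <- fit_nb_trend(pre_only), "one side")
  expect_false("post" %in% names(fit$coefficients))
  one_sex <- dat[dat$sex == "female", ]
  expect_error(fit_nb_trend(one_sex), "both sexes")
  expect_error(fit_nb_trend(dat[dat$year %in% 2001:2003, ]), "4 distinct")
  expect_error(fit_nb_trend(transform(dat, births = 0)), "births")
})

test_that("scenario curves satisfy their defining identities", {
  curves <- default_curves()
  base <- curve_of(curves, "base")
  flat <- curve_of(curves, "flat")
  mid <- curve_of(curves, "mid")
  key <- function(x) paste(x$year, x$sex)
  i <- match(key(base), key(flat))
  j <- match(key(base), key(mid))
  expect_equal(mid$rate_per_1000[j],
               (base$rate_per_1000 + flat$rate_per_1000[i]) / 2)
  # flat is constant per sex and anchored at the base year
  for (s in c("female", "male")) {
    v <- flat$rate_per_1000[flat$sex == s]
    expect_equal(v, rep(v[1], length(v)))
    expect_equal(v[1], base$rate_per_1000[base$sex == s &
                                            base$year == 2001])
  }
  # declining base implies flat >= mid >= base after the anchor year
  late <- base$year > 2001
  expect_true(all(flat$rate_per_1000[i][late] >=
                    mid$rate_per_1000[j][late]))
  expect_true(all(mid$rate_per_1000[j][late] >=
                    base$rate_per_1000[late]))
  # positive rates, CI only on base
  expect_true(all(curves$rate_per_1000 > 0))
  expect_true(all(is.na(flat$ci_low)) && all(is.na(mid$ci_low)))
  expect_true(all(base$ci_low <= base$rate_per_1000 &
                    base$rate_per_1000 <= base$ci_high))
  expect_error(build_scenarios(fit_nb_trend(
    gen_prescription_data(trend_truth(), seed = 1L)), base_year = 1990),
    "base_year")
})

test_that("refitting data regenerated from a fit recovers it", {
  fit <- fit_nb_trend(gen_prescription_data(trend_truth(), seed = 31L))
  co <- fit$coefficients
  tt2 <- trend_truth(intercept_log_rate = co[["(Intercept)"]],
                     slope_pre = co[["t"]],
                     slope_post = co[["t"]] + co[["t:post"]],
                     sex_effect = co[["sexmale"]],
                     dispersion = Inf, births_per_year = 1e6)
  # note: the jump term co[["post"]] is omitted; regenerate with a
  # continuous break and compare the slopes, which are shared
  refit <- fit_nb_trend(gen_prescription_data(tt2, seed = 32L))
  expect_lt(abs(refit$coefficients[["t"]] - co[["t"]]), 1e-3)
  expect_lt(abs(refit$coefficients[["t:post"]] + refit$coefficients[["t"]] -
                  (co[["t:post"]] + co[["t"]])), 1e-3)
})

test_that("mean rate and percent reduction follow report rounding", {
  expect_equal(mean_rate(data.frame(births = 1000, prescriptions = 100)),
               100)
  expect_equal(mean_rate(data.frame(births = 773160,
                                    prescriptions = 404675)), 523)
  expect_equal(percent_reduction(868, 236), 73)
  expect_error(mean_rate(data.frame(births = numeric(0),
                                    prescriptions = numeric(0))), "empty")
  expect_error(percent_reduction(0, 10), "from")
  expect_equal(round_half_up(522.5), 523)
  expect_equal(round_half_up(85.35, 1), 85.4)
})
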