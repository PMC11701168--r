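test_that("dose assignment matches its generating distribution", {
  withr::local_seed(1)
  expect_identical(assign_dose(0, n = 100), rep(0L, 100))
  big <- assign_dose(500, n = 1e6)
  expect_lt(abs(mean(big) - 0.5) / 0.5, 0.01)
  # heavy truncation: mass accumulates at the cap but stays a dose
  sat <- assign_dose(5000, n = 1e4)
  expect_gt(mean(sat == 5L), 0.4)
  expect_true(all(sat %in% 0:5))
  expect_error(assign_dose(-1), ">= 0")
  nb <- assign_dose(500, n = 1e5, dist = "nbinom", dispersion = 2)
  expect_lt(abs(mean(nb) - 0.5) / 0.5, 0.05)
})

test_that("odds transform of onset probability is exact", {
  expect_equal(onset_probability(0.1, 1), 0.1)
  expect_equal(round(onset_probability(0.1, 1.05), 4), 0.1045)
  expect_equal(onset_probability(1, 3.7), 1)
  expect_equal(onset_probability(0, 2), 0)
  p <- seq(0, 1, 0.1)
  expect_equal(onset_probability(onset_probability(p, 2), 0.5), p)
  expect_error(onset_probability(1.2, 1), "\\[0, 1\\]")
  expect_error(onset_probability(0.5, -1), "> 0")
})

test_that("zero incidence yields zero tallies in every scenario", {
  cal <- gen_calibration()
  cal$incidence <- 0
  cfg <- small_config()
  out <- run_scenario(cfg, const_curve(500), cal, point_dr())
  expect_true(all(out$mean == 0))
})

test_that("identical config and seeds reproduce identical outcomes", {
  cal <- gen_calibration()
  cfg <- small_config()
  a <- run_scenario(cfg, const_curve(500), cal, point_dr())
  b <- run_scenario(cfg, const_curve(500), cal, point_dr())
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "runs"), attr(b, "runs"))
})

test_that("overall rows are exact sums of age groups in every run", {
  cal <- gen_calibration()
  out <- run_scenario(small_config(n_runs = 3), const_curve(600), cal,
                      point_dr())
  runs <- attr(out, "runs")
  for (r in unique(runs$run)) {
    for (oc in unique(runs$outcome)) {
      sub <- runs[runs$run == r & runs$outcome == oc, ]
      expect_identical(sub$value[sub$age_group == "overall"],
                       sum(sub$value[sub$age_group != "overall"]))
    }
  }
  # onset year contributes a person-year: cumulative PY >= incident cases
  py <- runs$value[runs$outcome == "person_years" &
                     runs$age_group == "overall"]
  inc <- runs$value[runs$outcome == "incident_cases" &
                      runs$age_group == "overall"]
  expect_true(all(py >= inc))
})

test_that("a null dose effect makes ordered scenarios coincide", {
  cal <- gen_calibration()
  cfg <- small_config()
  dr0 <- point_dr(beta_dose = 0)
  hi <- run_scenario(cfg, const_curve(900), cal, dr0)
  lo <- run_scenario(cfg, const_curve(300), cal, dr0)
  expect_equal(as.data.frame(hi)[c("age_group", "outcome", "mean", "mc_sd")],
               as.data.frame(lo)[c("age_group", "outcome", "mean", "mc_sd")])
})

test_that("doses are ordered agent-by-agent under common random numbers", {
  cfg <- small_config()
  withr::with_seed(cfg$base_seed, pop_hi <- init_population(cfg, const_curve(900)))
  withr::with_seed(cfg$base_seed, pop_lo <- init_population(cfg, const_curve(300)))
  expect_identical(pop_hi$id, pop_lo$id)
  expect_true(all(pop_hi$dose >= pop_lo$dose))
  expect_gt(sum(pop_hi$dose), sum(pop_lo$dose))
})

test_that("expected tallies scale linearly with population scale", {
  cal <- gen_calibration()
  dr <- point_dr()
  t1 <- run_scenario(small_config(population_scale = 0.05, n_runs = 2),
                     const_curve(500), cal, dr)
  t2 <- run_scenario(small_config(population_scale = 0.1, n_runs = 2),
                     const_curve(500), cal, dr)
  m1 <- t1$mean[t1$age_group == "overall"]
  m2 <- t2$mean[t2$age_group == "overall"]
  expect_equal(m2 / m1, rep(2, 3), tolerance = 0.05)
})

test_that("single-replicate runs warn and report zero MC SD", {
  cal <- gen_calibration()
  expect_warning(
    out <- run_scenario(small_config(n_runs = 1), const_curve(400), cal,
                        point_dr()),
    "n_runs = 1")
  expect_true(all(out$mc_sd == 0))
})

test_that("step_year enforces calibration coverage and curve coverage", {
  cal <- gen_calibration()
  cfg <- small_config()
  gap <- cal[!(cal$age == 12 & cal$sex == "male"), ]
  pop <- withr::with_seed(1, init_population(cfg, const_curve(500)))
  expect_error(step_year(pop, 2002, const_curve(500), gap, point_dr(), cfg),
               "age 12, male")
  expect_error(run_scenario(cfg, const_curve(500, years = 2001:2005), cal,
                            point_dr()),
               "does not cover")
  st <- withr::with_seed(1, step_year(pop, 2001, const_curve(500), cal,
                                      point_dr(), cfg))
  expect_s3_class(st$tallies, "data.frame")
  expect_true(all(st$tallies$count >= 0))
  # agents aging past max_age leave the population
  expect_true(all(2001 - st$population$birth_year < cfg$max_age))
})
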