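# shared desk-scale fixtures; everything is generated in code

small_config <- function(...) {
  args <- utils::modifyList(
    list(population_scale = 0.02, n_runs = 2, base_seed = 11L),
    list(...))
  do.call(sim_config, args)
}

default_curves <- function(seed = 42L) {
  tt <- trend_truth()
  dat <- gen_prescription_data(tt, seed = seed)
  build_scenarios(fit_nb_trend(dat))
}

curve_of <- function(curves, id) curves[curves$scenario == id, ]

# flat exposure curve at a constant rate, for direct microsim tests
const_curve <- function(rate, years = 2001:2018) {
  data.frame(scenario = "const",
             year = rep(years, 2),
             sex = rep(c("female", "male"), each = length(years)),
             rate_per_1000 = rate, ci_low = NA, ci_high = NA)
}

point_dr <- function(beta_dose = 0.05, ...) {
  dose_response(meta_point(beta_dose = beta_dose, ...))
}

# raw study rows for harmonization tests
raw_study_rows <- function() {
  data.frame(
    study_id = c("A", "A", "B", "C", "D", "E", "F"),
    country = c("Canada", "Canada", "Japan", "USA", "Poland", "UK", "Korea"),
    exposure_period = c("first_year", "first_year", "first_year",
                        "first_year", "second_year", "first_year",
                        "first_year"),
    original_research = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    age_low = c(3, 3, 1, 2, 3, 4, 5),
    age_high = c(6, 6, 18, 6, 7, 8, 9),
    dose_raw = c("1-2", "3-4", "2", "5+", "1", "2", "3"),
    effect_scale = c("OR", "OR", "HR", "OR", "OR", "OR", "HR"),
    log_effect = c(0.05, 0.16, 0.10, 0.30, 0.04, 0.08, 0.12),
    se = c(0.02, 0.03, 0.05, 0.10, 0.04, 0.03, NA),
    risk_of_bias = c(1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}
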