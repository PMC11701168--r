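#' Ground truth for a piecewise log-linear prescription-rate trend
#'
#' Describes annual infant antibiotic prescribing as a piecewise log-linear
#' trend in the per-infant rate, continuous at a stewardship-program
#' breakpoint, with a multiplicative male-vs-female offset and negative
#' binomial count noise. The reference year anchors the intercept: the
#' female log rate in `ref_year` is `intercept_log_rate`.
#'
#' Defaults emulate British Columbia 2001-2018: a 2001 female rate around
#' 810 per 1,000 infants, a shallow decline before the 2005 stewardship
#' breakpoint and a steep one after (roughly a 70 percent drop over the
#' period), males prescribed about 28 percent more than females, and
#' 43,000 births per year across both sexes (about 773,000 over 18 years).
#'
#' @param intercept_log_rate Log of prescriptions per infant (female) in
#'   `ref_year`.
#' @param slope_pre Per-year change in the log rate up to `break_year`.
#' @param slope_post Per-year change in the log rate after `break_year`.
#' @param break_year Calendar year of the trend break (default 2005; years
#'   strictly greater are on the post slope).
#' @param sex_effect Additive male-vs-female offset on the log-rate scale.
#' @param dispersion Negative binomial dispersion (size) parameter, > 0;
#'   `Inf` gives Poisson counts.
#' @param births_per_year Births per sex per year: a single number, or a
#'   numeric vector named by calendar year.
#' @param ref_year Calendar year anchoring the intercept (default 2001).
#' @return An object of class `trend_truth`.
#' @export
trend_truth <- function(intercept_log_rate = log(0.81),
                        slope_pre = -0.02,
                        slope_post = -0.09,
                        break_year = 2005,
                        sex_effect = 0.25,
                        dispersion = 200,
                        births_per_year = 21500,
                        ref_year = 2001) {
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_input("dispersion must be > 0 (use Inf for Poisson counts)")
  }
  if (any(births_per_year < 0)) stop_input("births_per_year must be >= 0")
  structure(
    list(intercept_log_rate = intercept_log_rate, slope_pre = slope_pre,
         slope_post = slope_post, break_year = break_year,
         sex_effect = sex_effect, dispersion = dispersion,
         births_per_year = births_per_year, ref_year = ref_year),
    class = "trend_truth"
  )
}

# expected log prescriptions per infant; continuous piecewise in year
trend_linpred <- function(truth, year, male) {
  t <- year - truth$ref_year
  tb <- truth$break_year - truth$ref_year
  truth$intercept_log_rate + truth$sex_effect * male +
    truth$slope_pre * pmin(t, tb) + truth$slope_post * pmax(t - tb, 0)
}

births_for_year <- function(truth, year) {
  b <- truth$births_per_year
  if (length(b) == 1L && is.null(names(b))) return(rep(b, length(year)))
  out <- b[as.character(year)]
  if (anyNA(out)) stop_input("births_per_year does not cover year(s): ",
                             paste(year[is.na(out)], collapse = ", "))
  unname(out)
}

#' Generate an annual prescription-rate table with known truth
#'
#' Samples one row per (year, sex): births, a negative-binomial prescription
#' count with mean `births * exp(linear predictor)`, and the rate per 1,000
#' infants. With `noise = FALSE` the expected counts are returned exactly
#' (useful for noise-free recovery checks).
#'
#' @param truth A [trend_truth()] object.
#' @param years Calendar years to simulate (must contain the breakpoint).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param noise Draw negative binomial counts (default) or return expected
#'   counts exactly.
#' @return A data frame with columns `year`, `sex`, `births`,
#'   `prescriptions`, `rate_per_1000`.
#' @export
gen_prescription_data <- function(truth, years = 2001:2018, seed = 1L,
                                  noise = TRUE) {
  stopifnot(inherits(truth, "trend_truth"))
  if (length(years) == 0L) stop_input("year range must be non-empty")
  if (truth$break_year < min(years) || truth$break_year > max(years)) {
    stop_input("break_year (", truth$break_year,
               ") must lie inside the simulated year span")
  }
  grid <- expand.grid(year = sort(unique(years)),
                      sex = factor(c("female", "male"),
                                   levels = c("female", "male")),
                      KEEP.OUT.ATTRS = FALSE)
  births <- births_for_year(truth, grid$year)
  mu <- births * exp(trend_linpred(truth, grid$year, grid$sex == "male"))
  counts <- if (!noise) {
    mu
  } else {
    withr::with_seed(seed, {
      if (is.infinite(truth$dispersion)) {
        stats::rpois(nrow(grid), mu)
      } else {
        stats::rnbinom(nrow(grid), size = truth$dispersion, mu = mu)
      }
    })
  }
  data.frame(year = grid$year, sex = grid$sex, births = births,
             prescriptions = counts,
             rate_per_1000 = counts / births * 1000)
}

#' Ground truth for the dose-response meta-regression
#'
#' Parameters of the logit-scale linear predictor
#' `beta0 + u_study + beta_age * age + beta_dose * dose` used to generate
#' study effect tables. The single Canada-flagged study's random intercept
#' is fixed at `canada_effect`; other studies draw theirs from
#' `Normal(0, sigma_u^2)`.
#'
#' Defaults follow the pooled evidence on infant antibiotic exposure and
#' childhood asthma: a 5 percent increase in asthma odds per prescription
#' course, attenuation of about 21 percent per year of age at diagnosis,
#' and substantial between-study heterogeneity.
#'
#' @param beta0 Logit-scale intercept.
#' @param beta_age Per-year-of-age slope (logit scale).
#' @param beta_dose Per-prescription slope (logit scale).
#' @param sigma_u Study random-effect SD (>= 0).
#' @param canada_effect Realized random intercept of the Canadian study.
#' @param n_studies Number of studies (>= 2).
#' @param se_range Length-2 range of per-row standard errors (low > 0).
#' @return An object of class `meta_truth`.
#' @export
meta_truth <- function(beta0 = 1.71, beta_age = -0.23, beta_dose = 0.05,
                       sigma_u = sqrt(0.93), canada_effect = 0.12,
                       n_studies = 6, se_range = c(0.05, 0.20)) {
  if (sigma_u < 0) stop_input("sigma_u must be >= 0")
  if (n_studies < 2) stop_input("n_studies must be >= 2")
  if (length(se_range) != 2L || se_range[1] <= 0 || diff(se_range) < 0) {
    stop_input("se_range must be (low, high) with low > 0")
  }
  structure(
    list(beta0 = beta0, beta_age = beta_age, beta_dose = beta_dose,
         sigma_u = sigma_u, canada_effect = canada_effect,
         n_studies = n_studies, se_range = se_range),
    class = "meta_truth"
  )
}

#' Generate a harmonized study effect table with known truth
#'
#' Emulates the handful of studies feeding the dose-response meta-analysis:
#' each study reports logit-scale effects (vs the zero-prescription
#' reference) at dose categories 1 through 5 ("5+"), for a narrow age-at-
#' diagnosis range (width < 6 years). Effects are drawn as the full linear
#' predictor plus the study's random intercept plus `Normal(0, SE)` noise
#' with SE known per row. Exactly one study is Canada-flagged.
#'
#' @param truth A [meta_truth()] object.
#' @param seed Integer seed.
#' @return A `study_effect_table` data frame (see [harmonize_studies()]).
#' @export
gen_meta_studies <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "meta_truth"))
  if (truth$n_studies < 2) stop_input("n_studies must be >= 2")
  J <- truth$n_studies
  withr::with_seed(seed, {
    age_low <- sample(2:7, J, replace = TRUE)
    width <- sample(1:5, J, replace = TRUE)
    age_high <- age_low + width
    u <- stats::rnorm(J, 0, truth$sigma_u)
    canada_idx <- 1L
    u[canada_idx] <- truth$canada_effect
    countries <- c("Canada",
                   sample(c("Japan", "Poland", "South Korea", "USA",
                            "UK", "Sweden"), J - 1L, replace = TRUE))
    doses <- 1:5
    idx <- rep(seq_len(J), each = length(doses))
    dose <- rep(doses, J)
    age_mid <- (age_low + age_high) / 2
    se <- stats::runif(length(idx), truth$se_range[1], truth$se_range[2])
    mu <- truth$beta0 + u[idx] + truth$beta_age * age_mid[idx] +
      truth$beta_dose * dose
    log_effect <- mu + stats::rnorm(length(idx), 0, se)
    out <- data.frame(
      study_id = sprintf("S%02d", idx),
      country = countries[idx],
      canada_flag = idx == canada_idx,
      age_low = age_low[idx], age_high = age_high[idx],
      age_mid = age_mid[idx],
      age_range_width = width[idx],
      dose_raw = as.character(dose), dose = dose,
      effect_scale = "OR",
      log_effect = log_effect, se = se,
      risk_of_bias = 1L,
      stringsAsFactors = FALSE
    )
    class(out) <- c("study_effect_table", "data.frame")
    out
  })
}

#' Shape parameters for baseline asthma calibration tables
#'
#' Describes an age-shaped baseline: annual onset probability unimodal in
#' age (rising in early childhood, peaking before age 10, then declining),
#' remission low in childhood and rising through adolescence (so prevalence
#' falls in adolescence), and an exacerbation rate per person-year with
#' asthma that decays with age.
#'
#' Default magnitudes are typical of pediatric asthma in a high-income
#' setting: onset peaking near 3.5 percent per year around age 4-5, about
#' 1.2 exacerbations per person-year with asthma at age 3 falling to
#' roughly 0.04 by age 18, and adolescent remission near 8 percent per
#' year.
#'
#' @param peak_age Age (< 10) at which onset probability peaks.
#' @param peak_incidence Onset probability at the peak (female).
#' @param incidence_width Gaussian width (years) of the onset curve.
#' @param male_incidence_ratio Male/female onset ratio (boys higher in
#'   childhood).
#' @param remission_base Annual remission probability in childhood.
#' @param remission_adolescent Annual remission probability approached in
#'   adolescence.
#' @param remission_midpoint Age of the remission logistic midpoint.
#' @param exac_rate_age3 Exacerbations per person-year with asthma at age 3.
#' @param exac_decay Exponential decay per year of age of the
#'   exacerbation rate.
#' @return An object of class `calibration_shape`.
#' @export
calibration_shape <- function(peak_age = 4.5, peak_incidence = 0.035,
                              incidence_width = 3.2,
                              male_incidence_ratio = 1.25,
                              remission_base = 0.02,
                              remission_adolescent = 0.08,
                              remission_midpoint = 12,
                              exac_rate_age3 = 1.2, exac_decay = 0.22) {
  if (peak_age >= 10) {
    stop_input("onset curve must peak before age 10 (peak_age < 10)")
  }
  structure(
    list(peak_age = peak_age, peak_incidence = peak_incidence,
         incidence_width = incidence_width,
         male_incidence_ratio = male_incidence_ratio,
         remission_base = remission_base,
         remission_adolescent = remission_adolescent,
         remission_midpoint = remission_midpoint,
         exac_rate_age3 = exac_rate_age3, exac_decay = exac_decay),
    class = "calibration_shape"
  )
}

#' Generate baseline asthma calibration tables
#'
#' Builds deterministic incidence, remission, and exacerbation-rate tables
#' for ages 3-18 and both sexes from a [calibration_shape()]. Probabilities
#' outside `[0, 1]` raise an input error rather than being silently
#' clamped.
#'
#' @param shape A [calibration_shape()] object.
#' @param ages Ages covered (default 3:18).
#' @return A `calibration_tables` data frame with columns `age`, `sex`,
#'   `incidence`, `remission`, `exacerbation_rate`.
#' @export
gen_calibration <- function(shape = calibration_shape(), ages = 3:18) {
  stopifnot(inherits(shape, "calibration_shape"))
  grid <- expand.grid(age = ages,
                      sex = factor(c("female", "male"),
                                   levels = c("female", "male")),
                      KEEP.OUT.ATTRS = FALSE)
  inc <- shape$peak_incidence *
    exp(-(grid$age - shape$peak_age)^2 / (2 * shape$incidence_width^2)) *
    ifelse(grid$sex == "male", shape$male_incidence_ratio, 1)
  rem <- shape$remission_base +
    (shape$remission_adolescent - shape$remission_base) /
      (1 + exp(-(grid$age - shape$remission_midpoint)))
  exac <- shape$exac_rate_age3 * exp(-shape$exac_decay * (grid$age - 3))
  bad <- c(inc, rem)[c(inc, rem) < 0 | c(inc, rem) > 1]
  if (length(bad)) {
    stop_input("shape parameters imply probabilities outside [0, 1] ",
               "(e.g. ", signif(bad[1], 4), "); adjust the shape instead")
  }
  if (any(exac < 0)) stop_input("exacerbation rates must be >= 0")
  out <- data.frame(age = grid$age, sex = grid$sex, incidence = inc,
                    remission = rem, exacerbation_rate = exac)
  class(out) <- c("calibration_tables", "data.frame")
  out
}

#' Write ground-truth parameters to a YAML file
#'
#' Persists a [trend_truth()] or [meta_truth()] object so parameter-recovery
#' tests can be re-run against the generating values.
#'
#' @param truth A truth object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  x <- unclass(truth)
  x$.class <- class(truth)[1]
  yaml::write_yaml(x, path)
  invisible(path)
}
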