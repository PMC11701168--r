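#' Configuration for the asthma microsimulation
#'
#' An open pediatric population is followed year by year: a birth cohort
#' enters each calendar year, infants receive their first-year antibiotic
#' dose from the scenario exposure curve, asthma onset (modeled from age 3,
#' with the dose odds ratio applied through `dose_effect_max_age`),
#' remission, and exacerbations evolve annually, and agents age out past
#' `max_age`. The population standing at `start_year` (ages
#' `init_ages`) is initialized by simulating each cohort forward from
#' birth, with doses drawn from the base-year exposure value.
#'
#' Ages are attained during the calendar year (birth year is age 0).
#' Replicate `r` uses seed `base_seed + r - 1`, and all draws are made in
#' a fixed order over a scenario-independent population, so scenarios
#' share common random numbers when run with the same config.
#'
#' @param start_year,end_year Study window (defaults 2001-2018).
#' @param births_per_year Births per sex per year: a number, or a numeric
#'   vector named by calendar year covering the window.
#' @param population_scale Fraction of the population to simulate, in
#'   (0, 1]; expected tallies scale proportionally.
#' @param n_runs Monte Carlo replicates (default 100).
#' @param base_seed Seed of the first replicate.
#' @param min_asthma_age Youngest age with modeled asthma (>= 3).
#' @param max_age Oldest simulated age (default 18).
#' @param dose_effect_max_age Oldest age (inclusive) at which the dose
#'   odds ratio applies.
#' @param dose_dist Per-infant count distribution behind the population
#'   rate: `"poisson"` (default) or `"nbinom"`.
#' @param dose_dispersion Dispersion (size) for `dose_dist = "nbinom"`.
#' @param max_dose Dose truncation point ("5+" coded 5).
#' @param init_ages Ages of the standing population at `start_year`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(start_year = 2001, end_year = 2018,
                       births_per_year = 21500, population_scale = 1,
                       n_runs = 100, base_seed = 1L, min_asthma_age = 3,
                       max_age = 18, dose_effect_max_age = 7,
                       dose_dist = c("poisson", "nbinom"),
                       dose_dispersion = NULL, max_dose = 5L,
                       init_ages = 1:18) {
  dose_dist <- match.arg(dose_dist)
  if (start_year > end_year) stop_input("start_year must be <= end_year")
  if (population_scale <= 0 || population_scale > 1) {
    stop_input("population_scale must be in (0, 1]")
  }
  if (n_runs < 1) stop_input("n_runs must be >= 1")
  if (min_asthma_age < 3) stop_input("min_asthma_age must be >= 3")
  if (dose_dist == "nbinom" &&
      (is.null(dose_dispersion) || dose_dispersion <= 0)) {
    stop_input("dose_dispersion must be > 0 for dose_dist = 'nbinom'")
  }
  structure(
    list(start_year = start_year, end_year = end_year,
         births_per_year = births_per_year,
         population_scale = population_scale, n_runs = n_runs,
         base_seed = base_seed, min_asthma_age = min_asthma_age,
         max_age = max_age, dose_effect_max_age = dose_effect_max_age,
         dose_dist = dose_dist, dose_dispersion = dose_dispersion,
         max_dose = as.integer(max_dose), init_ages = init_ages),
    class = "sim_config"
  )
}

config_births <- function(config, year) {
  b <- config$births_per_year
  if (length(b) == 1L && is.null(names(b))) return(rep(b, length(year)))
  # standing cohorts born before the covered window use the earliest value
  yr <- pmax(year, min(as.numeric(names(b))))
  out <- b[as.character(yr)]
  if (anyNA(out)) stop_input("births_per_year does not cover year(s): ",
                             paste(year[is.na(out)], collapse = ", "))
  unname(out)
}

#' Draw first-year antibiotic doses from a population rate
#'
#' Draws per-infant prescription counts with mean `rate_per_1000 / 1000`
#' from a truncated Poisson (default) or negative binomial, capped at
#' `max_dose` ("5+"). Inverse-CDF sampling from a single uniform per
#' infant makes the draw monotone in the rate, so pointwise-ordered
#' exposure curves yield agent-by-agent ordered doses under common random
#' numbers.
#'
#' @param rate_per_1000 Annual prescription rate per 1,000 infants (>= 0);
#'   recycled against `n`.
#' @param n Number of draws.
#' @param dist `"poisson"` or `"nbinom"`.
#' @param dispersion Size parameter for `"nbinom"`.
#' @param max_dose Truncation point (default 5).
#' @return Integer doses in `0..max_dose`.
#' @export
assign_dose <- function(rate_per_1000, n = length(rate_per_1000),
                        dist = c("poisson", "nbinom"), dispersion = NULL,
                        max_dose = 5L) {
  dist <- match.arg(dist)
  if (any(rate_per_1000 < 0)) stop_input("rate_per_1000 must be >= 0")
  lambda <- rep_len(rate_per_1000 / 1000, n)
  u <- stats::runif(n)
  k <- if (dist == "poisson") {
    stats::qpois(u, lambda)
  } else {
    if (is.null(dispersion) || dispersion <= 0) {
      stop_input("dispersion must be > 0 for dist = 'nbinom'")
    }
    stats::qnbinom(u, size = dispersion, mu = lambda)
  }
  as.integer(pmin(k, max_dose))
}

#' Apply an odds ratio to an annual onset probability
#'
#' Multiplies the odds of the baseline annual probability by the odds
#' ratio: `adjusted = or * p / (1 - p + or * p)`.
#'
#' @param base_p Baseline annual probability in `[0, 1]`.
#' @param or_value Odds ratio (> 0); recycled.
#' @return Adjusted probability, same length as the longer input.
#' @export
onset_probability <- function(base_p, or_value) {
  if (any(base_p < 0 | base_p > 1)) stop_input("base_p must be in [0, 1]")
  if (any(or_value <= 0)) stop_input("or_value must be > 0")
  (or_value * base_p) / (1 - base_p + or_value * base_p)
}

# --- lookups -----------------------------------------------------------

# validates calibration coverage and precomputes matrices indexed by
# [age - min_asthma_age + 1, sex]; OR matrix by [age index, dose + 1]
sim_lookups <- function(calib, dr, config) {
  ages <- config$min_asthma_age:config$max_age
  sexes <- c("female", "male")
  assert_cols(calib, c("age", "sex", "incidence", "remission",
                       "exacerbation_rate"), "calibration tables")
  key <- interaction(calib$age, calib$sex)
  need <- expand.grid(age = ages, sex = sexes)
  miss <- !interaction(need$age, need$sex) %in% key
  if (any(miss)) {
    stop_input("missing calibration cell(s): ",
               paste(sprintf("(age %d, %s)", need$age[miss],
                             as.character(need$sex[miss])),
                     collapse = ", "))
  }
  grab <- function(col) {
    m <- matrix(NA_real_, length(ages), 2,
                dimnames = list(ages, sexes))
    i <- match(interaction(calib$age, calib$sex),
               interaction(need$age, need$sex))
    ok <- !is.na(i)
    m[cbind(match(calib$age[ok], ages),
            match(as.character(calib$sex[ok]), sexes))] <- calib[[col]][ok]
    m
  }
  orm <- matrix(1, length(ages), config$max_dose + 1L)
  if (!is.null(dr)) {
    grid <- expand.grid(age = ages, dose = 0:config$max_dose)
    orm[] <- or_at(dr, grid$age, grid$dose)$mean
  }
  list(inc = grab("incidence"), rem = grab("remission"),
       exac = grab("exacerbation_rate"), or = orm,
       min_age = config$min_asthma_age)
}

curve_rate <- function(curve, year, sex) {
  i <- match(paste(year, sex), paste(curve$year, as.character(curve$sex)))
  if (anyNA(i)) {
    stop_input("scenario curve does not cover (", year, ", ", sex, ")")
  }
  curve$rate_per_1000[i]
}

new_agents <- function(ids, sex_int, birth_year, dose) {
  data.frame(id = ids, sex = sex_int, birth_year = birth_year,
             dose = dose, has_asthma = FALSE, ever_asthma = FALSE)
}

draw_cohort <- function(year, curve, config) {
  n <- round(config_births(config, year) * config$population_scale)
  cohort <- lapply(1:2, function(s) {
    dose <- assign_dose(curve_rate(curve, year,
                                   c("female", "male")[s]),
                        n = n, dist = config$dose_dist,
                        dispersion = config$dose_dispersion,
                        max_dose = config$max_dose)
    new_agents(year * 1e6 + s * 1e5 + seq_len(n), s, year, dose)
  })
  do.call(rbind, cohort)
}

#' Initialize the standing population at the start year
#'
#' Creates cohorts aged `init_ages` in `start_year` (equal scaled cohort
#' sizes per sex), with first-year doses drawn from the scenario's
#' base-year exposure value. Asthma states are then developed by running
#' the annual dynamics forward from each cohort's third birthday (a
#' burn-in handled by [run_scenario()]).
#'
#' @param config A [sim_config()].
#' @param curve One scenario's exposure curve (rows of `year`, `sex`,
#'   `rate_per_1000`).
#' @return A population data frame (`id`, `sex`, `birth_year`, `dose`,
#'   `has_asthma`, `ever_asthma`).
#' @export
init_population <- function(config, curve) {
  cohorts <- lapply(sort(config$init_ages, decreasing = TRUE),
                    function(a) {
    birth_year <- config$start_year - a
    n <- round(config_births(config, birth_year) * config$population_scale)
    do.call(rbind, lapply(1:2, function(s) {
      dose <- assign_dose(curve_rate(curve, config$start_year,
                                     c("female", "male")[s]),
                          n = n, dist = config$dose_dist,
                          dispersion = config$dose_dispersion,
                          max_dose = config$max_dose)
      new_agents(birth_year * 1e6 + s * 1e5 + seq_len(n), s, birth_year,
                 dose)
    }))
  })
  do.call(rbind, cohorts)
}

zero_tallies <- function() {
  matrix(0, nrow = length(AGE_GROUPS), ncol = length(OUTCOMES),
         dimnames = list(AGE_GROUPS, OUTCOMES))
}

# core annual update; draws are made for every live agent in population
# order so scenarios with identical populations share random numbers
step_core <- function(population, year, curve, lk, config, tally = TRUE,
                      add_births = TRUE) {
  if (add_births && year >= config$start_year &&
      year <= config$end_year) {
    population <- rbind(population, draw_cohort(year, curve, config))
  }
  age <- year - population$birth_year
  alive <- which(age >= 0 & age <= config$max_age)
  tl <- zero_tallies()
  if (length(alive)) {
    a <- age[alive]
    sx <- population$sex[alive]
    has <- population$has_asthma[alive]
    ever <- population$ever_asthma[alive]
    dose <- population$dose[alive]
    n <- length(alive)
    u_onset <- stats::runif(n)
    u_rem <- stats::runif(n)
    u_exac <- stats::runif(n)
    can <- a >= lk$min_age
    ai <- pmax(a, lk$min_age) - lk$min_age + 1L
    idx <- cbind(ai, sx)
    p_onset <- onset_probability(lk$inc[idx],
                                 lk$or[cbind(ai, dose + 1L)])
    onset <- can & !has & u_onset < p_onset
    remit <- has & u_rem < lk$rem[idx]
    new_has <- (has & !remit) | onset
    incident <- onset & !ever
    exac <- ifelse(new_has, stats::qpois(u_exac, lk$exac[idx]), 0)
    grp <- age_group_of(a)
    tl[, "person_years"] <- tab_by(new_has, grp)
    tl[, "incident_cases"] <- tab_by(incident, grp)
    tl[, "exacerbations"] <- tab_by(exac, grp)
    population$has_asthma[alive] <- new_has
    population$ever_asthma[alive] <- ever | onset
  }
  keep <- age < config$max_age
  list(population = population[keep, , drop = FALSE], tallies = tl)
}

tab_by <- function(x, grp) {
  out <- vapply(split(as.numeric(x), grp), sum, numeric(1))
  out[AGE_GROUPS]
}

#' Advance the simulated population by one calendar year
#'
#' Adds the year's newborn cohort (within the study window) with doses
#' from the scenario curve, applies asthma onset (from age 3, odds-ratio
#' modulated through the dose-effect age cutoff), then remission, counts a
#' person-year for every agent with asthma after those updates, draws
#' exacerbations (Poisson per person-year with asthma), and ages the
#' population (agents past `max_age` are removed). Draws come from the
#' current RNG state; seed it for reproducibility.
#'
#' @param population Population data frame (see [init_population()]).
#' @param year Calendar year being simulated.
#' @param curve One scenario's exposure curve.
#' @param calib Calibration tables (see [gen_calibration()]).
#' @param dr A [dose_response()] object.
#' @param config A [sim_config()].
#' @param tally Record event tallies (disabled during burn-in).
#' @return A list with the updated `population` and a `tallies` data frame
#'   (age group by outcome).
#' @export
step_year <- function(population, year, curve, calib, dr,
                      config = sim_config(), tally = TRUE) {
  lk <- sim_lookups(calib, dr, config)
  st <- step_core(population, year, curve, lk, config, tally = tally)
  st$tallies <- as.data.frame(as.table(st$tallies),
                              responseName = "count")
  names(st$tallies)[1:2] <- c("age_group", "outcome")
  st
}

#' Run one exposure scenario through the microsimulation
#'
#' Executes `config$n_runs` independent replicates (replicate `r` seeded
#' with `base_seed + r - 1`): the standing population is initialized and
#' burned in from each cohort's third birthday, then the study window is
#' simulated with annual birth cohorts. Events are attributed to the age
#' attained in the event year, tallied by age group (3-4, 5-9, 10-14,
#' 15-18) with an overall row that is the exact sum of the groups in
#' every run.
#'
#' @param config A [sim_config()].
#' @param scenario One scenario's rows from [build_scenarios()] (columns
#'   `year`, `sex`, `rate_per_1000`, optionally `scenario`).
#' @param calib Calibration tables.
#' @param dr A [dose_response()] object.
#' @return An `outcome_table`: per (age group, outcome) means and Monte
#'   Carlo SDs across runs, with per-run tallies attached as
#'   `attr(x, "runs")`.
#' @export
run_scenario <- function(config, scenario, calib, dr) {
  stopifnot(inherits(config, "sim_config"))
  scen_id <- if ("scenario" %in% names(scenario)) {
    ids <- unique(as.character(scenario$scenario))
    if (length(ids) != 1L) {
      stop_input("'scenario' must contain a single scenario ",
                 "(subset the curves first)")
    }
    ids
  } else "scenario"
  for (y in config$start_year:config$end_year) {
    curve_rate(scenario, y, "female")
    curve_rate(scenario, y, "male")
  }
  lk <- sim_lookups(calib, dr, config)
  burn_start <- config$start_year - max(config$init_ages) +
    config$min_asthma_age
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    runs[[r]] <- withr::with_seed(config$base_seed + r - 1L, {
      pop <- init_population(config, scenario)
      if (burn_start <= config$start_year - 1) {
        for (y in burn_start:(config$start_year - 1)) {
          pop <- step_core(pop, y, scenario, lk, config, tally = FALSE,
                           add_births = FALSE)$population
        }
      }
      tl <- zero_tallies()
      for (y in config$start_year:config$end_year) {
        st <- step_core(pop, y, scenario, lk, config)
        pop <- st$population
        tl <- tl + st$tallies
      }
      tl
    })
  }
  outcome_table_from_runs(scen_id, runs, config$n_runs)
}

outcome_table_from_runs <- function(scenario, runs, n_runs) {
  if (n_runs == 1L) {
    warning("n_runs = 1: Monte Carlo SDs are reported as 0",
            call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_along(runs), function(r) {
    tl <- runs[[r]]
    tl <- rbind(tl, overall = colSums(tl))
    data.frame(run = r,
               age_group = rep(rownames(tl), ncol(tl)),
               outcome = rep(colnames(tl), each = nrow(tl)),
               value = as.vector(tl))
  }))
  agg <- stats::aggregate(value ~ age_group + outcome, long,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1)
                                          stats::sd(v) else 0))
  summary <- data.frame(scenario = scenario,
                        age_group = agg$age_group, outcome = agg$outcome,
                        mean = agg$value[, "mean"],
                        mc_sd = agg$value[, "sd"], n_runs = n_runs)
  lev <- c(AGE_GROUPS, "overall")
  summary <- summary[order(match(summary$outcome, OUTCOMES),
                           match(summary$age_group, lev)), ]
  rownames(summary) <- NULL
  long$scenario <- scenario
  structure(summary, runs = long,
            class = c("outcome_table", "data.frame"))
}
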