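#' Harmonize raw study records for the dose-response meta-regression
#'
#' Applies the inclusion and harmonization rules for pooling published
#' dose-response evidence on infant antibiotic exposure and childhood
#' asthma:
#'
#' * keep only original dose-response research (`original_research`),
#'   exposure in the first year of life (`exposure_period ==
#'   "first_year"`), an age range for asthma diagnosis narrower than 6
#'   years, and low risk of bias (`risk_of_bias < 2`);
#' * recode dose ranges by their lower bound ("1-2" becomes 1, "3-4"
#'   becomes 3, "5+" becomes 5) and cap single values at 5;
#' * set the age at diagnosis to the midpoint of the reported range;
#' * relabel hazard ratios as odds ratios (interchangeable at low event
#'   prevalence).
#'
#' Rows with a missing standard error (or a dose-0 reference row) are
#' rejected with a logged reason, available as `attr(x, "rejected")`.
#'
#' @param raw Data frame of study records with columns `study_id`,
#'   `country`, `exposure_period`, `original_research`, `age_low`,
#'   `age_high`, `dose_raw`, `effect_scale`, `log_effect`, `se`,
#'   `risk_of_bias`.
#' @return A `study_effect_table` data frame; errors if every row is
#'   filtered out.
#' @export
harmonize_studies <- function(raw) {
  assert_cols(raw, c("study_id", "country", "exposure_period",
                     "original_research", "age_low", "age_high",
                     "dose_raw", "effect_scale", "log_effect", "se",
                     "risk_of_bias"), "raw study table")
  raw <- as.data.frame(raw)
  reject <- character(nrow(raw))
  dose <- vapply(as.character(raw$dose_raw), parse_dose, numeric(1))
  width <- raw$age_high - raw$age_low
  reject[is.na(raw$se) | !is.finite(raw$se) | raw$se <= 0] <-
    "missing or invalid standard error"
  reject[!is.na(dose) & dose == 0 & reject == ""] <-
    "dose 0 is the reference category"
  reject[is.na(dose) & reject == ""] <- "unparseable dose category"
  reject[!isTRUE_vec(raw$original_research) & reject == ""] <-
    "not original dose-response research"
  reject[as.character(raw$exposure_period) != "first_year" & reject == ""] <-
    "exposure not in the first year of life"
  reject[width >= 6 & reject == ""] <-
    "age range for diagnosis not narrower than 6 years"
  reject[raw$risk_of_bias >= 2 & reject == ""] <- "risk of bias not low"
  keep <- reject == ""
  rejected <- data.frame(study_id = raw$study_id[!keep],
                         reason = reject[!keep])
  if (nrow(rejected)) {
    message("harmonize_studies: rejected ", nrow(rejected), " row(s): ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  if (!any(keep)) stop_input("all study rows were filtered out")
  out <- data.frame(
    study_id = raw$study_id[keep],
    country = as.character(raw$country[keep]),
    canada_flag = as.character(raw$country[keep]) == "Canada",
    age_low = raw$age_low[keep], age_high = raw$age_high[keep],
    age_mid = (raw$age_low[keep] + raw$age_high[keep]) / 2,
    age_range_width = width[keep],
    dose_raw = as.character(raw$dose_raw[keep]),
    dose = as.integer(dose[keep]),
    effect_scale = "OR",
    scale_original = as.character(raw$effect_scale[keep]),
    log_effect = raw$log_effect[keep],
    se = raw$se[keep],
    risk_of_bias = raw$risk_of_bias[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  class(out) <- c("study_effect_table", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# "1-2" -> 1, "5+" -> 5, "3" -> 3; values above 5 cap at 5; NA if unparseable
parse_dose <- function(x) {
  x <- trimws(x)
  v <- if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", x)) {
    as.numeric(sub("-.*$", "", x))
  } else if (grepl("^[0-9]+\\s*\\+$", x)) {
    as.numeric(sub("\\+$", "", x))
  } else if (grepl("^[0-9]+(\\.[0-9]+)?$", x)) {
    as.numeric(x)
  } else {
    NA_real_
  }
  if (!is.na(v)) v <- min(v, 5)
  v
}

#' Prior specification for the meta-regression
#'
#' Weakly informative defaults: `Normal(0, beta_sd^2)` on the fixed effects
#' and half-`Normal(0, sigma_u_sd^2)` on the between-study SD.
#'
#' @param beta_sd Prior SD for fixed effects (> 0).
#' @param sigma_u_sd Prior scale for the half-normal on `sigma_u` (> 0).
#' @return A `meta_priors` list.
#' @export
meta_priors <- function(beta_sd = 10, sigma_u_sd = 5) {
  if (!is.numeric(beta_sd) || beta_sd <= 0 ||
      !is.numeric(sigma_u_sd) || sigma_u_sd <= 0) {
    stop_input("prior scales must be positive numbers")
  }
  structure(list(beta_sd = beta_sd, sigma_u_sd = sigma_u_sd),
            class = "meta_priors")
}

#' Sampler configuration for the meta-regression
#'
#' @param n_adapt Adaptation iterations.
#' @param n_burnin Burn-in iterations.
#' @param n_iter Sampling iterations per chain.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param rhat_max Maximum tolerated rank-normalized split-Rhat before
#'   failing.
#' @param max_tries Sampling is re-run with doubled iterations up to this
#'   many times if any split-Rhat exceeds `rhat_max`.
#' @return A `meta_mcmc` list.
#' @export
meta_mcmc <- function(n_adapt = 1000, n_burnin = 2000, n_iter = 10000,
                      n_chains = 2, rhat_max = 1.01, max_tries = 3) {
  if (n_chains < 2) stop_input("need >= 2 chains for split-Rhat")
  structure(list(n_adapt = n_adapt, n_burnin = n_burnin, n_iter = n_iter,
                 n_chains = n_chains, rhat_max = rhat_max,
                 max_tries = max_tries),
            class = "meta_mcmc")
}

meta_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(a[study[i]] + beta_age * agec[i] + beta_dose * dosec[i],
                 prec_y[i])
  }
  for (j in 1:J) { a[j] ~ dnorm(beta0c, tau_u) }
  beta0c ~ dnorm(0, prec_beta)
  beta_age ~ dnorm(0, prec_beta)
  beta_dose ~ dnorm(0, prec_beta)
  sigma_u ~ dnorm(0, prec_sigma) T(0,)
  tau_u <- pow(sigma_u, -2)
}"

#' Fit the Bayesian random-effects dose-response meta-regression
#'
#' Fits the logit-scale model
#' `y_ij ~ Normal(beta0 + u_j + beta_age * age_ij + beta_dose * dose_ij,
#' se_ij^2)` with study random intercepts `u_j ~ Normal(0, sigma_u^2)` and
#' known within-study standard errors. The Canada coefficient is reported
#' as the posterior of the single Canada-flagged study's realized random
#' intercept. Sampling uses JAGS with hierarchical centering and centered
#' covariates internally; draws are transformed back to the uncentered
#' parameterization. Rank-normalized split-Rhat (robust for the
#' heavy-tailed variance component) and effective sample size are attached
#' per parameter; sampling is extended (doubling iterations, up to
#' `mcmc$max_tries`) and then fails loudly if any split-Rhat stays above
#' `mcmc$rhat_max`.
#'
#' @param table A `study_effect_table` (from [harmonize_studies()] or
#'   [gen_meta_studies()]) with at least 2 studies and exactly one
#'   Canada-flagged study.
#' @param priors A [meta_priors()] object.
#' @param mcmc A [meta_mcmc()] object.
#' @param seed Integer seed for the sampler.
#' @return An object of class `meta_posterior` with `draws` (data frame of
#'   `beta0`, `beta_canada`, `beta_age`, `beta_dose`, `sigma_u_sq` and
#'   per-study intercepts), `summary` (mean, 95 percent credible interval,
#'   split-Rhat, ESS per parameter) and the configuration used.
#' @export
fit_meta <- function(table, priors = meta_priors(), mcmc = meta_mcmc(),
                     seed = 1L) {
  assert_cols(table, c("study_id", "canada_flag", "age_mid", "dose",
                       "log_effect", "se"), "study effect table")
  if (!inherits(priors, "meta_priors")) stop_input("invalid prior spec")
  if (!inherits(mcmc, "meta_mcmc")) stop_input("invalid sampler config")
  if (any(table$se <= 0)) stop_input("all standard errors must be > 0")
  studies <- unique(as.character(table$study_id))
  J <- length(studies)
  if (J < 2L) {
    stop_input("at least 2 studies are required: the random-effect ",
               "variance is unidentifiable from a single study")
  }
  canada_studies <- unique(as.character(table$study_id[table$canada_flag]))
  if (length(canada_studies) != 1L) {
    stop_input("exactly one Canada-flagged study is required (found ",
               length(canada_studies), ")")
  }
  idx <- match(as.character(table$study_id), studies)
  mean_age <- mean(table$age_mid)
  mean_dose <- mean(table$dose)
  dat <- list(y = table$log_effect, prec_y = 1 / table$se^2,
              agec = table$age_mid - mean_age,
              dosec = table$dose - mean_dose,
              study = idx, N = nrow(table), J = J,
              prec_beta = 1 / priors$beta_sd^2,
              prec_sigma = 1 / priors$sigma_u_sd^2)
  canada_j <- match(canada_studies, studies)

  n_iter <- mcmc$n_iter
  n_burnin <- mcmc$n_burnin
  for (try in seq_len(mcmc$max_tries)) {
    draws <- run_meta_jags(dat, mcmc$n_adapt, n_burnin, n_iter,
                           mcmc$n_chains, seed)
    post <- transform_meta_draws(draws, mean_age, mean_dose, canada_j,
                                 studies)
    diag <- meta_diagnostics(post$by_chain)
    if (all(diag$rhat <= mcmc$rhat_max, na.rm = TRUE)) break
    if (try == mcmc$max_tries) {
      bad <- diag$parameter[diag$rhat > mcmc$rhat_max]
      stop_input("sampler did not converge (split-Rhat > ",
                 mcmc$rhat_max, ") for: ", paste(bad, collapse = ", "))
    }
    n_iter <- n_iter * 2L
    n_burnin <- n_burnin * 2L
  }
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  pars <- c("beta0", "beta_canada", "beta_age", "beta_dose", "sigma_u_sq")
  summ <- data.frame(
    parameter = pars,
    mean = vapply(post$draws[pars], mean, numeric(1)),
    ci_low = vapply(post$draws[pars], function(v) qs(v)[1], numeric(1)),
    ci_high = vapply(post$draws[pars], function(v) qs(v)[2], numeric(1)),
    rhat = diag$rhat[match(pars, diag$parameter)],
    ess = diag$ess[match(pars, diag$parameter)],
    row.names = NULL
  )
  structure(
    list(draws = post$draws, summary = summ, studies = studies,
         canada_study = canada_studies, priors = priors,
         mcmc = utils::modifyList(unclass(mcmc),
                                  list(n_iter = n_iter,
                                       n_burnin = n_burnin)),
         seed = seed),
    class = "meta_posterior"
  )
}

run_meta_jags <- function(dat, n_adapt, n_burnin, n_iter, n_chains, seed) {
  rjags::load.module("glm", quiet = TRUE)
  inits <- lapply(seq_len(n_chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(seed, 10L + i))
  })
  jm <- rjags::jags.model(textConnection(meta_model_string), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_burnin, progress.bar = "none")
  rjags::coda.samples(jm, c("beta0c", "beta_age", "beta_dose", "sigma_u",
                            "a"),
                      n.iter = n_iter, progress.bar = "none")
}

# back-transform to the uncentered parameterization, per chain
transform_meta_draws <- function(samples, mean_age, mean_dose, canada_j,
                                 studies) {
  by_chain <- lapply(samples, function(ch) {
    m <- as.matrix(ch)
    beta0 <- m[, "beta0c"] - m[, "beta_age"] * mean_age -
      m[, "beta_dose"] * mean_dose
    u <- m[, sprintf("a[%d]", seq_along(studies)), drop = FALSE] -
      m[, "beta0c"]
    colnames(u) <- paste0("u_", studies)
    cbind(beta0 = beta0, beta_canada = u[, canada_j],
          beta_age = m[, "beta_age"], beta_dose = m[, "beta_dose"],
          sigma_u_sq = m[, "sigma_u"]^2, u)
  })
  list(by_chain = by_chain,
       draws = as.data.frame(do.call(rbind, by_chain)))
}

# rank-normalized split-Rhat (bulk) and ESS, computed on transformed
# draws; rank normalization keeps the diagnostic calibrated for
# heavy-tailed quantities such as the variance component
meta_diagnostics <- function(by_chain) {
  pars <- colnames(by_chain[[1]])
  rhat <- ess <- stats::setNames(numeric(length(pars)), pars)
  for (p in pars) {
    vals <- lapply(by_chain, function(m) m[, p])
    if (stats::var(unlist(vals)) < 1e-12) {
      rhat[p] <- 1
      ess[p] <- NA_real_
      next
    }
    pooled <- unlist(vals)
    r <- rank(pooled, ties.method = "average")
    z <- stats::qnorm((r - 0.375) / (length(pooled) + 0.25))
    zc <- split(z, rep(seq_along(vals), lengths(vals)))
    halves <- unlist(lapply(zc, function(v) {
      h <- length(v) %/% 2
      list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    ml <- coda::mcmc.list(lapply(halves, coda::mcmc))
    rhat[p] <- coda::gelman.diag(ml, autoburnin = FALSE,
                                 multivariate = FALSE)$psrf[1, 1]
    ess[p] <- sum(coda::effectiveSize(
      coda::mcmc.list(lapply(vals, coda::mcmc))))
  }
  data.frame(parameter = pars, rhat = unname(rhat), ess = unname(ess))
}

#' @export
print.meta_posterior <- function(x, ...) {
  cat("Dose-response meta-regression posterior (", nrow(x$draws),
      " draws, ", length(x$studies), " studies)\n", sep = "")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) round(v, 3))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Build a point-mass posterior from fixed coefficient values
#'
#' Useful for plugging published coefficient estimates into
#' [prevalence_logit()] and [or_at()] arithmetic.
#'
#' @param beta0,beta_canada,beta_age,beta_dose,sigma_u_sq Coefficient
#'   values.
#' @return A single-draw `meta_posterior`.
#' @export
meta_point <- function(beta0 = 0, beta_canada = 0, beta_age = 0,
                       beta_dose = 0, sigma_u_sq = 0) {
  draws <- data.frame(beta0 = beta0, beta_canada = beta_canada,
                      beta_age = beta_age, beta_dose = beta_dose,
                      sigma_u_sq = sigma_u_sq)
  summ <- data.frame(parameter = names(draws),
                     mean = as.numeric(draws[1, ]),
                     ci_low = as.numeric(draws[1, ]),
                     ci_high = as.numeric(draws[1, ]),
                     rhat = NA_real_, ess = NA_real_)
  structure(list(draws = draws, summary = summ, studies = character(),
                 canada_study = NA_character_, priors = NULL, mcmc = NULL,
                 seed = NA_integer_),
            class = "meta_posterior")
}

#' Dose-response odds-ratio function for the microsimulation
#'
#' Wraps a posterior with the conservative age cutoff: the dose effect on
#' asthma odds applies only up to `max_effect_age` (7 years by default,
#' where the estimated effect has essentially attenuated away); beyond it
#' the odds ratio is exactly 1. Dose categories are capped at `dose_cap`
#' ("5+" coded 5).
#'
#' @param posterior A `meta_posterior`.
#' @param max_effect_age Oldest age (inclusive) at which the dose effect
#'   applies.
#' @param dose_cap Maximum dose category.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(posterior, max_effect_age = 7, dose_cap = 5L) {
  stopifnot(inherits(posterior, "meta_posterior"))
  structure(list(posterior = posterior, max_effect_age = max_effect_age,
                 dose_cap = as.integer(dose_cap)),
            class = "dose_response")
}

check_age_dose <- function(age, dose, dose_cap, min_age = 3) {
  if (any(age < min_age)) {
    stop_input("age must be >= ", min_age,
               ": asthma is not modeled under ", min_age, " years of age")
  }
  if (any(dose < 0)) stop_input("dose must be in 0..", dose_cap)
  if (any(dose > dose_cap)) {
    warning("dose above ", dose_cap, " clamped to ", dose_cap,
            call. = FALSE)
    dose <- pmin(dose, dose_cap)
  }
  dose
}

#' Odds ratio for asthma at a given age and antibiotic dose
#'
#' Evaluates `exp(beta_dose * dose)` (relative to dose 0) per posterior
#' draw, returning the posterior mean and a 95 percent interval. Returns
#' exactly 1 when `dose` is 0 or `age` exceeds the effect cutoff.
#'
#' @param dr A [dose_response()] object.
#' @param age Age(s) in years (>= 3).
#' @param dose Dose category (0..5; values above 5 are clamped with a
#'   warning).
#' @param draws Return the raw per-draw odds ratios instead of a summary.
#' @return A data frame with `age`, `dose`, `mean`, `lo`, `hi` — or, with
#'   `draws = TRUE`, a matrix of per-draw odds ratios (rows = draws).
#' @export
or_at <- function(dr, age, dose, draws = FALSE) {
  stopifnot(inherits(dr, "dose_response"))
  n <- max(length(age), length(dose))
  age <- rep_len(age, n)
  dose <- rep_len(dose, n)
  dose <- check_age_dose(age, dose, dr$dose_cap)
  bd <- dr$posterior$draws$beta_dose
  active <- dose > 0 & age <= dr$max_effect_age
  or <- matrix(1, nrow = length(bd), ncol = n)
  if (any(active)) {
    or[, active] <- exp(outer(bd, dose[active]))
  }
  if (draws) return(or)
  data.frame(age = age, dose = dose,
             mean = colMeans(or),
             lo = apply(or, 2, stats::quantile, 0.025, names = FALSE),
             hi = apply(or, 2, stats::quantile, 0.975, names = FALSE))
}

#' Logit of asthma prevalence under the meta-regression
#'
#' Evaluates the linear predictor `beta0 + beta_canada * canada +
#' beta_age * age + beta_dose * dose` per posterior draw. Note the
#' intercept is only interpretable relative to the included studies'
#' baselines (absorbed into `beta0` and the study intercepts); age enters
#' uncentered, in years.
#'
#' @param posterior A `meta_posterior`.
#' @param age Age(s) in years (>= 3).
#' @param dose Dose category (0..5).
#' @param canada Include the Canada random-intercept term.
#' @param draws Return per-draw values instead of a summary.
#' @return A data frame with `age`, `dose`, `mean`, `lo`, `hi` — or a
#'   matrix of per-draw logits with `draws = TRUE`.
#' @export
prevalence_logit <- function(posterior, age, dose, canada = FALSE,
                             draws = FALSE) {
  stopifnot(inherits(posterior, "meta_posterior"))
  n <- max(length(age), length(dose))
  age <- rep_len(age, n)
  dose <- rep_len(dose, n)
  dose <- check_age_dose(age, dose, 5L)
  d <- posterior$draws
  lp <- outer(d$beta0 + if (canada) d$beta_canada else 0, rep(1, n)) +
    outer(d$beta_age, age) + outer(d$beta_dose, dose)
  if (draws) return(lp)
  data.frame(age = age, dose = dose,
             mean = colMeans(lp),
             lo = apply(lp, 2, stats::quantile, 0.025, names = FALSE),
             hi = apply(lp, 2, stats::quantile, 0.975, names = FALSE))
}
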