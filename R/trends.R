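validate_rate_table <- function(data) {
  assert_cols(data, c("year", "sex", "births", "prescriptions"),
              "annual rate table")
  if (nrow(data) == 0L) stop_input("annual rate table is empty")
  if (any(data$births <= 0)) stop_input("births must be > 0 in every row")
  if (any(data$prescriptions < 0)) stop_input("prescriptions must be >= 0")
  invisible(data)
}

#' Fit the negative binomial prescription-trend model
#'
#' Models annual infant antibiotic prescription counts with a log link and
#' a `log(births)` offset, so coefficients act on the log rate per infant.
#' Covariates are calendar year centered at `ref_year`, sex, an indicator
#' for years after the stewardship breakpoint (`year > break_year`, i.e.
#' 2006 onward by default), and the year-by-indicator interaction, giving
#' separate log-linear slopes before and after the break. Dispersion is
#' estimated by maximum likelihood; an effectively infinite dispersion
#' (no overdispersion, e.g. noise-free input) falls back to the Poisson
#' limit with `dispersion = Inf`.
#'
#' @param data Annual rate table: columns `year`, `sex`, `births`,
#'   `prescriptions` (one row per year and sex).
#' @param break_year Breakpoint year; years strictly greater are "post".
#' @param ref_year Centering year for the time covariate, so the intercept
#'   is the log rate in `ref_year` (default 2001).
#' @param sex_time_interaction Also include a sex-by-year interaction
#'   (default `FALSE`: a common slope for both sexes).
#' @param terms Model terms to include; the default is the full piecewise
#'   trend. `character(0)` fits the intercept-plus-offset null model.
#' @param dispersion `NULL` (default) estimates the negative binomial
#'   dispersion by maximum likelihood; a finite value fixes it; `Inf`
#'   fits the Poisson limit directly.
#' @return An object of class `trend_fit` with elements `coefficients`,
#'   `dispersion`, `vcov`, `model`, `deviance`, `null_deviance`,
#'   `ref_year`, `break_year`, `data`.
#' @seealso [deviance_explained()], [build_scenarios()]
#' @export
fit_nb_trend <- function(data, break_year = 2005, ref_year = 2001,
                         sex_time_interaction = FALSE,
                         terms = c("t", "sex", "post", "t:post"),
                         dispersion = NULL) {
  validate_rate_table(data)
  if (!all(c("female", "male") %in% as.character(data$sex))) {
    stop_input("both sexes must be present in the data")
  }
  yrs <- sort(unique(data$year))
  if (length(yrs) < 4L) stop_input("need at least 4 distinct years")
  d <- data.frame(
    prescriptions = data$prescriptions,
    births = data$births,
    t = data$year - ref_year,
    sex = factor(as.character(data$sex), levels = c("female", "male")),
    post = as.numeric(data$year > break_year)
  )
  one_sided <- length(unique(d$post)) == 1L
  if (one_sided && any(c("post", "t:post") %in% terms)) {
    warning("all years lie on one side of the breakpoint (",
            break_year, "); dropping breakpoint terms", call. = FALSE)
    terms <- setdiff(terms, c("post", "t:post"))
  }
  if (sex_time_interaction) terms <- union(terms, "t:sex")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(
    paste("prescriptions ~", rhs, "+ offset(log(births))"))
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("design matrix is singular; collinear column(s): ",
               paste(aliased, collapse = ", "))
  }
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  if (!is.null(dispersion)) {
    if (dispersion <= 0) stop_input("dispersion must be > 0")
    fam <- if (is.infinite(dispersion)) stats::poisson() else
      MASS::negative.binomial(dispersion)
    fit <- suppressWarnings(stats::glm(form, family = fam, data = d,
                                       control = ctrl))
  } else {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(form, data = d, control = ctrl)),
      error = function(e) NULL
    )
    dispersion <- if (!is.null(fit)) fit$theta else Inf
  }
  if (is.null(fit) || (is.finite(dispersion) && dispersion > 1e8)) {
    # no detectable overdispersion: Poisson limit (suppress the
    # non-integer-count warning noise-free expected counts trigger)
    fit <- suppressWarnings(
      stats::glm(form, family = stats::poisson(), data = d,
                 control = ctrl))
    dispersion <- Inf
  }
  null_dev <- null_deviance_nb(d, dispersion)
  structure(
    list(coefficients = stats::coef(fit), dispersion = dispersion,
         vcov = stats::vcov(fit), model = fit,
         deviance = stats::deviance(fit), null_deviance = null_dev,
         terms = terms, ref_year = ref_year, break_year = break_year,
         data = data),
    class = "trend_fit"
  )
}

# null model: intercept + offset only, at the fitted dispersion
null_deviance_nb <- function(d, dispersion) {
  fam <- if (is.infinite(dispersion)) stats::poisson() else
    MASS::negative.binomial(dispersion)
  nf <- suppressWarnings(
    stats::glm(prescriptions ~ 1 + offset(log(births)), family = fam,
               data = d,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  stats::deviance(nf)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Negative binomial prescription-trend fit\n")
  cat("  dispersion:", format(x$dispersion), "\n")
  cat("  deviance explained:",
      format(round(deviance_explained(x), 1)), "%\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Percentage deviance explained by a trend fit
#'
#' `100 * (1 - residual deviance / null deviance)`, where the null model is
#' intercept plus offset only at the fitted dispersion. Values near 100
#' justify using regression-smoothed rates in place of raw frequencies.
#'
#' @param fit A [fit_nb_trend()] object.
#' @return A percentage in `[0, 100]` (up to numerical noise).
#' @export
deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  if (fit$null_deviance <= .Machine$double.eps^0.5 &&
      fit$deviance <= .Machine$double.eps^0.5) {
    stop_input("null deviance is zero; deviance explained is undefined")
  }
  100 * (1 - fit$deviance / fit$null_deviance)
}

#' Build the three exposure scenario curves
#'
#' From a fitted trend, constructs per-sex annual prescription-rate curves
#' for the factual and counterfactual worlds: `base` is the model-smoothed
#' rate with a 95 percent Wald interval on the linear-predictor scale,
#' `flat` holds the smoothed `base_year` value constant over all years, and
#' `mid` is the pointwise arithmetic mean of `base` and `flat`. Intervals
#' are reported for the base curve only.
#'
#' @param fit A [fit_nb_trend()] object.
#' @param years Years to cover (default: the fitted data's year range).
#' @param base_year Anchoring year for the flat scenario (must be covered).
#' @param level Confidence level for the base-curve interval.
#' @return A `scenario_curves` data frame with columns `scenario`
#'   (`base`/`flat`/`mid`), `year`, `sex`, `rate_per_1000`, `ci_low`,
#'   `ci_high`.
#' @export
build_scenarios <- function(fit, years = NULL, base_year = 2001,
                            level = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  years <- years %||% seq(min(fit$data$year), max(fit$data$year))
  if (!base_year %in% years) stop_input("base_year must be inside years")
  grid <- expand.grid(year = years,
                      sex = factor(c("female", "male"),
                                   levels = c("female", "male")),
                      KEEP.OUT.ATTRS = FALSE)
  nd <- data.frame(t = grid$year - fit$ref_year, sex = grid$sex,
                   post = as.numeric(grid$year > fit$break_year),
                   births = 1)
  rhs <- if (length(fit$terms)) paste(fit$terms, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), nd)
  eta <- drop(X %*% fit$coefficients)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  base <- data.frame(scenario = "base", year = grid$year, sex = grid$sex,
                     rate_per_1000 = 1000 * exp(eta),
                     ci_low = 1000 * exp(eta - z * se),
                     ci_high = 1000 * exp(eta + z * se))
  anchor <- base[base$year == base_year, c("sex", "rate_per_1000")]
  flat <- base
  flat$scenario <- "flat"
  flat$rate_per_1000 <- anchor$rate_per_1000[match(flat$sex, anchor$sex)]
  flat$ci_low <- NA_real_
  flat$ci_high <- NA_real_
  mid <- base
  mid$scenario <- "mid"
  mid$rate_per_1000 <- (base$rate_per_1000 + flat$rate_per_1000) / 2
  mid$ci_low <- NA_real_
  mid$ci_high <- NA_real_
  out <- rbind(base, flat, mid)
  rownames(out) <- NULL
  class(out) <- c("scenario_curves", "data.frame")
  out
}

#' Period mean prescription rate per 1,000 infants
#'
#' Total prescriptions over total births, times 1,000, with the reporting
#' convention of rounding half up to an integer rate.
#'
#' @param data Annual rate table (or any data frame with `prescriptions`
#'   and `births`).
#' @param round Round half-up to an integer per 1,000 (default `TRUE`).
#' @return The mean rate per 1,000 infants.
#' @export
mean_rate <- function(data, round = TRUE) {
  assert_cols(data, c("births", "prescriptions"), "rate table")
  if (nrow(data) == 0L) stop_input("rate table is empty")
  tot_b <- sum(data$births)
  if (tot_b <= 0) stop_input("total births must be > 0")
  r <- sum(data$prescriptions) / tot_b * 1000
  if (round) round_half_up(r) else r
}

#' Percentage reduction between two rates
#'
#' `100 * (1 - to / from)`, rounded half-up to an integer percentage by
#' default (e.g. a fall from 868 to 236 per 1,000 is a 73 percent
#' reduction).
#'
#' @param from Starting rate (> 0).
#' @param to Ending rate.
#' @param round Round half-up to an integer percentage (default `TRUE`).
#' @return Percentage reduction.
#' @export
percent_reduction <- function(from, to, round = TRUE) {
  if (any(from <= 0)) stop_input("'from' must be > 0")
  r <- 100 * (1 - to / from)
  if (round) round_half_up(r) else r
}
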