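outcome_levels <- function() c(AGE_GROUPS, "overall")

#' Coerce a summary data frame to an outcome table
#'
#' Validates and classes a per-(age group, outcome) summary — for example
#' reported scenario results loaded from a CSV — so it can be fed to
#' [compare()] and [render_table2()]. Per-run data are not attached;
#' comparisons then use variance addition rather than paired differences
#' for Monte Carlo SDs.
#'
#' @param df Data frame with columns `scenario`, `age_group`, `outcome`,
#'   `mean`, `mc_sd`, `n_runs`.
#' @return An `outcome_table`.
#' @export
as_outcome_table <- function(df) {
  assert_cols(df, c("scenario", "age_group", "outcome", "mean", "mc_sd",
                    "n_runs"), "outcome table")
  if (nrow(df) == 0L) stop_input("outcome table is empty")
  if (length(unique(df$scenario)) != 1L) {
    stop_input("an outcome table holds a single scenario; subset first")
  }
  if (any(df$mc_sd < 0)) stop_input("mc_sd must be >= 0")
  bad <- !df$age_group %in% outcome_levels() | !df$outcome %in% OUTCOMES
  if (any(bad)) {
    stop_input("unknown age_group/outcome label(s): ",
               paste(unique(paste(df$age_group[bad], df$outcome[bad])),
                     collapse = ", "))
  }
  df <- df[order(match(df$outcome, OUTCOMES),
                 match(df$age_group, outcome_levels())), ]
  rownames(df) <- NULL
  structure(as.data.frame(df), runs = attr(df, "runs"),
            class = c("outcome_table", "data.frame"))
}

cell_key <- function(x) paste(x$age_group, x$outcome, sep = "|")

#' Compare a counterfactual scenario with the base scenario
#'
#' Computes, per (age group, outcome) cell, the difference in means
#' (counterfactual minus base), its Monte Carlo SD, the relative change
#' `100 * difference / base mean`, and the relative change's Monte Carlo
#' SD. With `paired_runs = TRUE` (default) and per-run tallies attached to
#' both tables, SDs come from per-run paired differences and per-run
#' relative changes — the appropriate estimator when scenarios share
#' common random numbers; otherwise SDs combine by variance addition.
#'
#' @param base The base-scenario `outcome_table`.
#' @param cf The counterfactual `outcome_table` (same age groups,
#'   outcomes, and number of runs).
#' @param paired_runs Use paired per-run differences when available.
#' @return A `comparison_table` data frame with columns `scenario`,
#'   `age_group`, `outcome`, `base_mean`, `cf_mean`, `diff`, `diff_sd`,
#'   `rel_change`, `rel_sd`.
#' @export
compare <- function(base, cf, paired_runs = TRUE) {
  stopifnot(inherits(base, "outcome_table"), inherits(cf, "outcome_table"))
  kb <- cell_key(base)
  kc <- cell_key(cf)
  missing <- c(setdiff(kb, kc), setdiff(kc, kb))
  if (length(missing)) {
    stop_input("tables do not share the same cells; mismatched: ",
               paste(unique(missing), collapse = ", "))
  }
  if (!identical(sort(unique(base$n_runs)), sort(unique(cf$n_runs)))) {
    stop_input("tables were built from different numbers of runs")
  }
  i <- match(kb, kc)
  out <- data.frame(scenario = cf$scenario[i][1],
                    age_group = base$age_group, outcome = base$outcome,
                    base_mean = base$mean, cf_mean = cf$mean[i],
                    diff = cf$mean[i] - base$mean)
  rb <- attr(base, "runs")
  rc <- attr(cf, "runs")
  paired <- paired_runs && !is.null(rb) && !is.null(rc)
  if (paired) {
    krb <- paste(rb$run, rb$age_group, rb$outcome)
    krc <- paste(rc$run, rc$age_group, rc$outcome)
    j <- match(krb, krc)
    if (anyNA(j)) stop_input("per-run tallies do not align across tables")
    d <- data.frame(run = rb$run, age_group = rb$age_group,
                    outcome = rb$outcome,
                    diff = rc$value[j] - rb$value,
                    rel = 100 * (rc$value[j] - rb$value) /
                      ifelse(rb$value == 0, NA, rb$value))
    key <- paste(d$age_group, d$outcome)
    sd0 <- function(v) if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE)
      else 0
    out$diff_sd <- vapply(split(d$diff, key), sd0,
                          numeric(1))[paste(out$age_group, out$outcome)]
    out$rel_sd <- vapply(split(d$rel, key), sd0,
                         numeric(1))[paste(out$age_group, out$outcome)]
  } else {
    out$diff_sd <- sqrt(base$mc_sd^2 + cf$mc_sd[i]^2)
    out$rel_sd <- ifelse(out$base_mean == 0, NA,
                         100 * out$diff_sd / out$base_mean)
  }
  out$rel_change <- ifelse(out$base_mean == 0,
                           ifelse(out$diff == 0, 0, NA),
                           100 * out$diff / out$base_mean)
  out <- out[, c("scenario", "age_group", "outcome", "base_mean",
                 "cf_mean", "diff", "diff_sd", "rel_change", "rel_sd")]
  if (paired) attr(out, "run_diffs") <- d
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Share of the excess burden attributable to selected age groups
#'
#' `100 * sum(selected groups' differences) / overall difference`,
#' reported to one decimal place. For instance, ages under 10 correspond
#' to `groups = c("3-4", "5-9")`.
#'
#' @param ct A [compare()] result.
#' @param groups Subset of the table's age groups.
#' @param outcome One of `"person_years"`, `"incident_cases"`,
#'   `"exacerbations"`.
#' @return The percentage share (1 decimal place).
#' @export
age_group_share <- function(ct, groups, outcome) {
  stopifnot(inherits(ct, "comparison_table"))
  outcome <- match.arg(outcome, OUTCOMES)
  bad <- setdiff(groups, AGE_GROUPS)
  if (length(bad)) {
    stop_input("unknown age group(s): ", paste(bad, collapse = ", "))
  }
  rows <- ct[ct$outcome == outcome, ]
  overall <- rows$diff[rows$age_group == "overall"]
  if (length(overall) != 1L) stop_input("comparison lacks an overall row")
  if (overall == 0) {
    stop_input("overall difference is zero; share is undefined")
  }
  sel <- sum(rows$diff[rows$age_group %in% groups])
  round_half_up(100 * sel / overall, 1)
}

#' Translate excess person-years with asthma into direct medical costs
#'
#' Multiplies excess person-years by an annual per-person cost of managed
#' asthma (default 550, in 2024 Canadian dollars).
#'
#' @param excess_person_years Excess person-years with asthma (>= 0).
#' @param unit_cost Annual direct medical cost per person-year (>= 0).
#' @return A `cost_summary` list with `unit_cost`, `excess_person_years`,
#'   `total_savings`, and `savings_millions` (rounded to the nearest
#'   million for presentation).
#' @export
cost_savings <- function(excess_person_years, unit_cost = 550) {
  if (excess_person_years < 0 || unit_cost < 0) {
    stop_input("inputs must be >= 0")
  }
  total <- excess_person_years * unit_cost
  structure(list(unit_cost = unit_cost,
                 excess_person_years = excess_person_years,
                 total_savings = total,
                 savings_millions = round_half_up(total / 1e6)),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(format(x$excess_person_years, big.mark = ","),
      " excess person-years x $", x$unit_cost, " = $",
      format(x$total_savings, big.mark = ","),
      " (~$", x$savings_millions, " million)\n", sep = "")
  invisible(x)
}

#' Render the three-scenario excess-burden table
#'
#' Lays out base, flat, and mid scenario results in the standard reporting
#' shape: per outcome and age group (plus overall), the estimated values
#' with Monte Carlo SDs, differences versus base, and relative changes
#' versus base. Values are kept at full precision so writing the result
#' with [utils::write.csv()] and re-reading reproduces them exactly; use
#' [format_table2()] for a display version with thousands separators and
#' bracketed SDs.
#'
#' @param base,cf_flat,cf_mid `outcome_table`s with identical structure.
#' @param paired_runs Passed to [compare()].
#' @return A `table2` data frame.
#' @export
render_table2 <- function(base, cf_flat, cf_mid, paired_runs = TRUE) {
  for (x in list(base, cf_flat, cf_mid)) {
    if (!inherits(x, "outcome_table") || nrow(x) == 0L) {
      stop_input("all three inputs must be non-empty outcome tables")
    }
  }
  c2 <- compare(base, cf_flat, paired_runs)
  c3 <- compare(base, cf_mid, paired_runs)
  key <- function(x) paste(x$age_group, x$outcome)
  i2 <- match(key(base), key(c2))
  i3 <- match(key(base), key(c3))
  kf <- match(key(base), key(cf_flat))
  km <- match(key(base), key(cf_mid))
  out <- data.frame(
    outcome = base$outcome, age_group = base$age_group,
    s1_mean = base$mean, s1_sd = base$mc_sd,
    s2_mean = cf_flat$mean[kf], s2_sd = cf_flat$mc_sd[kf],
    s3_mean = cf_mid$mean[km], s3_sd = cf_mid$mc_sd[km],
    diff2 = c2$diff[i2], diff2_sd = c2$diff_sd[i2],
    diff3 = c3$diff[i3], diff3_sd = c3$diff_sd[i3],
    rel2 = c2$rel_change[i2], rel2_sd = c2$rel_sd[i2],
    rel3 = c3$rel_change[i3], rel3_sd = c3$rel_sd[i3]
  )
  out <- out[order(match(out$outcome, OUTCOMES),
                   match(out$age_group, outcome_levels())), ]
  rownames(out) <- NULL
  # consistency of overall rows with age-group sums, recorded per outcome
  chk <- do.call(rbind, lapply(split(out, out$outcome), function(b) {
    data.frame(outcome = b$outcome[1],
               overall = b$s1_mean[b$age_group == "overall"],
               group_sum = sum(b$s1_mean[b$age_group != "overall"]))
  }))
  rownames(chk) <- NULL
  structure(out, consistency = chk, class = c("table2", "data.frame"))
}

#' Format an excess-burden table for display
#'
#' @param x A [render_table2()] result.
#' @return A character matrix with counts rounded and thousands-separated
#'   and Monte Carlo SDs in brackets, one row per (outcome, age group).
#' @export
format_table2 <- function(x) {
  stopifnot(inherits(x, "table2"))
  num <- function(m, s) {
    paste0(formatC(round_half_up(m), format = "d", big.mark = ","),
           " (", formatC(round_half_up(s), format = "d", big.mark = ","),
           ")")
  }
  pct <- function(m, s) sprintf("%.1f (%.1f)", m, s)
  cbind(outcome = x$outcome, age_group = x$age_group,
        scenario1 = num(x$s1_mean, x$s1_sd),
        scenario2 = num(x$s2_mean, x$s2_sd),
        scenario3 = num(x$s3_mean, x$s3_sd),
        diff_s2 = num(x$diff2, x$diff2_sd),
        diff_s3 = num(x$diff3, x$diff3_sd),
        rel_s2 = pct(x$rel2, x$rel2_sd),
        rel_s3 = pct(x$rel3, x$rel3_sd))
}

#' Load the bundled reference scenario outcome summaries
#'
#' Reported three-scenario outcome summaries (means and Monte Carlo SDs
#' over 100 runs) for the British Columbia pediatric asthma burden
#' analysis, 2001-2018, shipped as a plain-text CSV. Useful for desk-scale
#' arithmetic: differences, age-group shares, and cost translation.
#'
#' @return A named list of three `outcome_table`s: `base`, `flat`, `mid`.
#' @export
bc_outcome_summaries <- function() {
  path <- system.file("extdata", "bc_outcome_summaries.csv",
                      package = "abxasthma", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(stats::setNames(nm = c("base", "flat", "mid")),
         function(s) as_outcome_table(df[df$scenario == s, ]))
}
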