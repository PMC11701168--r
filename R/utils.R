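#' Round half away from zero
#'
#' Reporting convention for rates and percentages: halves round up in
#' magnitude (so 522.5 -> 523), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a per-stage random seed from one global seed
#'
#' A single pipeline seed fans out to independent substreams so that each
#' stage (prescription data, study tables, calibration, microsimulation)
#' can be regenerated on its own. The rule is fixed and documented:
#' `(seed mod 1000003) * 1009 + stream index`, which stays below 2^31.
#'
#' @param seed Integer global seed.
#' @param stream One of `"prescriptions"`, `"meta"`, `"calibration"`,
#'   `"microsim"`, or a nonnegative integer index.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  streams <- c(prescriptions = 1L, meta = 2L, calibration = 3L, microsim = 4L)
  if (is.character(stream)) {
    stream <- streams[[match.arg(stream, names(streams))]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), stream >= 0)
  as.integer((abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(stream))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
}

# pediatric reporting age groups; overall handled separately
AGE_GROUPS <- c("3-4", "5-9", "10-14", "15-18")

age_group_of <- function(age) {
  cut(age, breaks = c(3, 5, 10, 15, 19), right = FALSE, labels = AGE_GROUPS)
}

OUTCOMES <- c("person_years", "incident_cases", "exacerbations")
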