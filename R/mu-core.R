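#' Geometric mean
#'
#' The geometric mean `exp(mean(ln(x)))` of a vector of positive values. This
#' is the conventional location summary for clotting times: the mean normal
#' prothrombin time (MNPT) is defined as the geometric mean of the PTs of
#' citrated plasmas from about 20 healthy donors, and replicate PTs of a test
#' plasma are summarised the same way so that all downstream propagation can
#' work on the natural-log scale.
#'
#' @param x Numeric vector of positive values (e.g. PTs in seconds).
#' @return A single positive number.
#' @examples
#' geometric_mean(c(2, 8)) # 4
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) {
    abort_invalid("`x` must be a non-empty numeric vector.")
  }
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    abort_invalid("All values in `x` must be positive and non-missing.")
  }
  exp(mean(log(x)))
}

#' Summarise raw PT replicates for log-space propagation
#'
#' Reduces a vector of replicate prothrombin times to the three summary
#' statistics the uncertainty propagation consumes: the geometric mean PT, the
#' standard deviation of `ln(PT)` (sample SD, `n - 1` denominator), and the
#' replicate count. At least two replicates are required: a log-scale SD is
#' never estimated from a single value.
#'
#' @param replicates_seconds Numeric vector of at least two positive PTs
#'   (seconds).
#' @return A one-row tibble with columns `pt_mean_s`, `sd_log_pt`, `n`.
#' @examples
#' plasma_summary(c(12.1, 12.3, 12.0))
#' @export
plasma_summary <- function(replicates_seconds) {
  if (length(replicates_seconds) < 2L) {
    abort_invalid(
      "At least two replicates are needed to estimate `sd_log_pt`; supply summary statistics directly for n = 1."
    )
  }
  gm <- geometric_mean(replicates_seconds)
  tibble(
    pt_mean_s = gm,
    sd_log_pt = sd(log(replicates_seconds)),
    n = length(replicates_seconds)
  )
}

#' INR from a PT and a thromboplastin calibration
#'
#' Converts a prothrombin time to an International Normalized Ratio through the
#' ISI model `INR = (PT / MNPT)^ISI`, where R = PT/MNPT is the PT ratio, MNPT
#' is the reagent's mean normal PT and ISI its International Sensitivity
#' Index. All arguments are vectorised.
#'
#' @param pt_seconds Positive PT (geometric mean of replicates), seconds.
#' @param mnpt_seconds Positive MNPT, seconds.
#' @param isi Positive ISI of the thromboplastin/measurement system.
#' @return Numeric vector of INR values.
#' @examples
#' inr_from_pt(25.25, mnpt_seconds = 12.17, isi = 1.11)
#' @export
inr_from_pt <- function(pt_seconds, mnpt_seconds, isi) {
  if (!is.numeric(pt_seconds) || !is.numeric(mnpt_seconds) || !is.numeric(isi) ||
      anyNA(c(pt_seconds, mnpt_seconds, isi)) ||
      any(pt_seconds <= 0) || any(mnpt_seconds <= 0) || any(isi <= 0)) {
    abort_invalid("`pt_seconds`, `mnpt_seconds` and `isi` must all be positive.")
  }
  exp(isi * (log(pt_seconds) - log(mnpt_seconds)))
}

#' Standard deviation of ln(INR) by log-space error propagation
#'
#' The delta-method standard uncertainty of `ln(INR)` combining three
#' independent components of the reference measurement system:
#'
#' \deqn{SD_{\ln INR} = \sqrt{\frac{(ISI \cdot SD_{\ln PT})^2}{n} +
#'   \frac{(ISI \cdot SD_{\ln MNPT})^2}{m} + (\ln R \cdot SD_{ISI})^2}}
#'
#' where `R = PT/MNPT`. The first term is PT repeatability (same operator,
#' `n` replicate measurements), the second MNPT intermediate precision (same
#' operator over `m` calibration studies), and the third ISI reproducibility
#' (between calibration laboratories). Covariance terms are deliberately
#' omitted: the ISI is an externally assigned quantity, the MNPT comes from
#' prior calibration studies, and the lyophilized-plasma measurements are
#' treated as independent of both. Natural logarithms throughout.
#'
#' @param pt_mean_s,mnpt_s Geometric-mean PT and MNPT, seconds.
#' @param isi ISI of the thromboplastin.
#' @param sd_log_pt,sd_log_mnpt SDs of `ln(PT)` and `ln(MNPT)` (natural-log
#'   scale, dimensionless).
#' @param n,m Number of PT replicates and of MNPT determinations (each >= 1).
#' @param sd_isi Between-laboratory SD of the ISI.
#' @return Numeric vector of `SD_logINR` values. All arguments are vectorised.
#' @seealso [inr_uncertainty()] for the data-frame interface that also returns
#'   the three variance contributions, confidence intervals and relative
#'   uncertainty.
#' @examples
#' sd_log_inr(25.25, 12.17, isi = 1.11, sd_log_pt = 0.009, n = 10,
#'            sd_log_mnpt = 0.014, m = 6, sd_isi = 0.063)
#' @export
sd_log_inr <- function(pt_mean_s, mnpt_s, isi, sd_log_pt, n, sd_log_mnpt, m,
                       sd_isi) {
  v <- log_inr_variance_terms(pt_mean_s, mnpt_s, isi, sd_log_pt, n,
                              sd_log_mnpt, m, sd_isi)
  sqrt(v$pt + v$mnpt + v$isi)
}

# the three variance addends of the propagation, kept separate so callers can
# report per-component contributions
log_inr_variance_terms <- function(pt_mean_s, mnpt_s, isi, sd_log_pt, n,
                                   sd_log_mnpt, m, sd_isi) {
  if (any(n < 1) || any(m < 1)) {
    abort_invalid("`n` and `m` must both be at least 1.")
  }
  if (any(pt_mean_s <= 0) || any(mnpt_s <= 0) || any(isi <= 0)) {
    abort_invalid("`pt_mean_s`, `mnpt_s` and `isi` must all be positive.")
  }
  if (any(sd_log_pt < 0) || any(sd_log_mnpt < 0) || any(sd_isi < 0)) {
    abort_invalid("Standard deviations must be non-negative.")
  }
  log_r <- log(pt_mean_s) - log(mnpt_s)
  list(
    pt   = (isi * sd_log_pt)^2 / n,
    mnpt = (isi * sd_log_mnpt)^2 / m,
    isi  = (log_r * sd_isi)^2
  )
}

#' Coverage-factor confidence interval for an INR
#'
#' Expands the log-scale standard uncertainty into an interval on the INR
#' scale: `exp(mean_log_inr -/+ k * sd_log_inr)`. With the default coverage
#' factor `k = 2` this is an approximate 95% interval under log-normality.
#' The interval is geometrically symmetric: the geometric mean of its bounds
#' equals the mean INR.
#'
#' @param mean_log_inr Mean of `ln(INR)` (natural log).
#' @param sd_log_inr Non-negative SD of `ln(INR)`.
#' @param k Positive coverage factor (default 2).
#' @return A tibble with columns `ci_lower`, `ci_upper`.
#' @examples
#' inr_confidence_interval(log(2.25), 0.047)
#' @export
inr_confidence_interval <- function(mean_log_inr, sd_log_inr, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    abort_invalid("`k` must be a single positive number.")
  }
  if (any(sd_log_inr < 0)) {
    abort_invalid("`sd_log_inr` must be non-negative.")
  }
  tibble(
    ci_lower = exp(mean_log_inr - k * sd_log_inr),
    ci_upper = exp(mean_log_inr + k * sd_log_inr)
  )
}

#' Relative standard uncertainty of an INR, in percent
#'
#' Converts a log-scale SD to a percent relative uncertainty. For small
#' `sd_log_inr` under a log-normal distribution the approximation
#' `%ru ~ 100 * sd_log_inr` holds and is the reporting convention; the exact
#' log-normal conversion `100 * (exp(sd_log_inr) - 1)` is available for
#' comparison and is always at least as large.
#'
#' @param sd_log_inr Non-negative SD of `ln(INR)`; vectorised.
#' @param mode `"approximate"` (default, `100 * sd`) or `"exact"`
#'   (`100 * (exp(sd) - 1)`).
#' @return Numeric vector of percent relative uncertainties.
#' @examples
#' relative_uncertainty(0.047)
#' relative_uncertainty(0.047, mode = "exact")
#' @export
relative_uncertainty <- function(sd_log_inr, mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  if (any(sd_log_inr < 0)) {
    abort_invalid("`sd_log_inr` must be non-negative.")
  }
  switch(mode,
    approximate = 100 * sd_log_inr,
    exact = 100 * (expm1(sd_log_inr))
  )
}

#' Per-plasma INR measurement uncertainty
#'
#' The main analysis verb. Takes a measurement table with one row per
#' (thromboplastin, plasma) pair and returns the same rows augmented with the
#' full uncertainty analysis: mean INR, `SD_logINR` by log-space error
#' propagation (see [sd_log_inr()]), the three per-component variance
#' contributions, a coverage-factor confidence interval, and the percent
#' relative uncertainty.
#'
#' @param data A data frame with numeric columns `pt_mean_s`, `sd_log_pt`,
#'   `n`, `mnpt_s`, `sd_log_mnpt`, `m`, `isi`, `sd_isi`. Identifier columns
#'   such as `irp_id` and `plasma_id` are carried through; see
#'   [read_measurement_csv()] for the file format.
#' @param k Positive coverage factor for the confidence interval (default 2,
#'   approximately 95% under log-normality).
#' @param ru_mode How to convert `SD_logINR` to percent relative uncertainty;
#'   see [relative_uncertainty()].
#' @return A tibble with the input columns plus `mean_log_inr`, `mean_inr`,
#'   `term_pt`, `term_mnpt`, `term_isi` (variance contributions summing to
#'   `sd_log_inr^2`), `sd_log_inr`, `ci_lower`, `ci_upper`, `ru_percent`, `k`.
#'   Internal computation is never rounded; see [render_report()] for the
#'   conventional display rounding.
#' @examples
#' irp_example_measurements() |> inr_uncertainty()
#' @export
inr_uncertainty <- function(data, k = 2, ru_mode = c("approximate", "exact")) {
  ru_mode <- match.arg(ru_mode)
  validate_measurements(data)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    abort_invalid("`k` must be a single positive number.")
  }
  out <- as_tibble(data)
  terms <- log_inr_variance_terms(
    out$pt_mean_s, out$mnpt_s, out$isi,
    out$sd_log_pt, out$n, out$sd_log_mnpt, out$m, out$sd_isi
  )
  out$mean_log_inr <- out$isi * (log(out$pt_mean_s) - log(out$mnpt_s))
  out$mean_inr <- exp(out$mean_log_inr)
  out$term_pt <- terms$pt
  out$term_mnpt <- terms$mnpt
  out$term_isi <- terms$isi
  out$sd_log_inr <- sqrt(terms$pt + terms$mnpt + terms$isi)
  ci <- inr_confidence_interval(out$mean_log_inr, out$sd_log_inr, k = k)
  out$ci_lower <- ci$ci_lower
  out$ci_upper <- ci$ci_upper
  out$ru_percent <- relative_uncertainty(out$sd_log_inr, mode = ru_mode)
  out$k <- k
  out
}

#' Summarise relative uncertainty per thromboplastin preparation
#'
#' Median, minimum and maximum percent relative uncertainty across the plasmas
#' measured with each reference preparation. The median is computed on the
#' unrounded `ru_percent` values (for an even number of plasmas it is the mean
#' of the two central values) and only then rounded for reporting.
#'
#' @param results Output of [inr_uncertainty()] (needs `ru_percent`; grouped by
#'   `irp_id` when present).
#' @param digits Decimal places for the reported summaries (default 1, the
#'   conventional display precision); `NULL` to leave unrounded.
#' @return A tibble with one row per preparation: `n_plasmas`, `median_ru`,
#'   `min_ru`, `max_ru`.
#' @examples
#' irp_example_measurements() |> inr_uncertainty() |> summarize_irp()
#' @export
summarize_irp <- function(results, digits = 1) {
  if (!is.data.frame(results) || !"ru_percent" %in% names(results)) {
    abort_invalid("`results` must contain a `ru_percent` column; run `inr_uncertainty()` first.")
  }
  if (nrow(results) == 0L) {
    abort_invalid("`results` must contain at least one row.")
  }
  grp <- intersect("irp_id", names(results))
  out <- results |>
    group_by(across(all_of(grp))) |>
    summarise(
      n_plasmas = n(),
      median_ru = median(.data$ru_percent),
      min_ru = min(.data$ru_percent),
      max_ru = max(.data$ru_percent),
      .groups = "drop"
    )
  if (!is.null(digits)) {
    out <- mutate(out, across(c("median_ru", "min_ru", "max_ru"),
                              ~ round(.x, .env$digits)))
  }
  out
}

# column contract shared by inr_uncertainty(), the Monte Carlo oracle and the
# CSV reader
measurement_columns <- function() {
  c("pt_mean_s", "sd_log_pt", "n", "mnpt_s", "sd_log_mnpt", "m",
    "isi", "sd_isi")
}

validate_measurements <- function(data) {
  if (!is.data.frame(data)) {
    abort_invalid("`data` must be a data frame of PT/INR measurements.")
  }
  missing_cols <- setdiff(measurement_columns(), names(data))
  if (length(missing_cols) > 0L) {
    abort_invalid(paste0("Missing required column(s): ",
                         paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(data) == 0L) {
    abort_invalid("`data` must contain at least one row.")
  }
  for (col in measurement_columns()) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]])) {
      abort_invalid(paste0("Column `", col, "` must be numeric with no missing values."))
    }
  }
  if (any(data$pt_mean_s <= 0) || any(data$mnpt_s <= 0) || any(data$isi <= 0)) {
    abort_invalid("`pt_mean_s`, `mnpt_s` and `isi` must be positive in every row.")
  }
  if (any(data$sd_log_pt < 0) || any(data$sd_log_mnpt < 0) || any(data$sd_isi < 0)) {
    abort_invalid("SD columns must be non-negative in every row.")
  }
  if (any(data$n < 1) || any(data$m < 1) ||
      any(data$n != round(data$n)) || any(data$m != round(data$m))) {
    abort_invalid("`n` and `m` must be whole numbers >= 1 in every row.")
  }
  if (all(c("irp_id", "plasma_id") %in% names(data))) {
    key <- paste(data$irp_id, data$plasma_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1L]
      abort_invalid(paste0("Duplicate (irp_id, plasma_id) pair in row ", dup, "."))
    }
  }
  invisible(data)
}
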