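#' Fit a precision profile as a power function of INR
#'
#' Fits the CLSI EP17-style precision profile `%ru = a * INR^b` by ordinary
#' least squares on the log-log transformed pairs
#' `ln(ru) = ln(a) + b * ln(INR)`. This is the standard deterministic,
#' closed-form fit for a power function. The fitted profile can be evaluated
#' at any INR inside its validity domain (default 1.0 to 4.0, the range over
#' which prediction is endorsed) with [predict_ru()].
#'
#' @param data A data frame with positive columns `inr` and `ru_percent`
#'   (at least two rows), typically the output of [inr_uncertainty()] for one
#'   preparation with `mean_inr` renamed to `inr`, or any (INR, %ru) pairs.
#' @param domain Length-2 numeric validity interval for prediction,
#'   lower < upper.
#' @return An object of class `precision_profile` with elements
#'   `coefficient_a`, `exponent_b`, `inr_domain` and `fit_points`. Supports
#'   [tidy()], [glance()], [autoplot()], [predict_ru()] and JSON round-trip
#'   via [write_profile_json()] / [read_profile_json()].
#' @examples
#' pts <- tibble::tibble(inr = c(0.94, 1.84, 2.81, 4.10),
#'                       ru_percent = c(1.4, 2.2, 3.2, 4.2))
#' fit_power_profile(pts)
#' @export
fit_power_profile <- function(data, domain = c(1, 4)) {
  if (!is.data.frame(data) || !all(c("inr", "ru_percent") %in% names(data))) {
    abort_invalid("`data` must be a data frame with columns `inr` and `ru_percent`.")
  }
  if (nrow(data) < 2L) {
    abort_invalid("At least two (inr, ru_percent) points are needed to fit a power function.")
  }
  if (anyNA(data$inr) || anyNA(data$ru_percent) ||
      any(data$inr <= 0) || any(data$ru_percent <= 0)) {
    abort_invalid("All `inr` and `ru_percent` values must be positive.")
  }
  if (!is.numeric(domain) || length(domain) != 2L || anyNA(domain) ||
      any(domain <= 0) || domain[1] >= domain[2]) {
    abort_invalid("`domain` must be a positive interval with lower < upper.")
  }
  fit <- lm(log(ru_percent) ~ log(inr), data = data)
  cf <- coef(fit)
  structure(
    list(
      coefficient_a = unname(exp(cf[1])),
      exponent_b = unname(cf[2]),
      inr_domain = as.numeric(domain),
      fit_points = tibble(inr = as.numeric(data$inr),
                          ru_percent = as.numeric(data$ru_percent))
    ),
    class = "precision_profile"
  )
}

#' Predict relative uncertainty from a precision profile
#'
#' Evaluates `a * INR^b`. By default the INR must lie inside the profile's
#' validity domain; prediction outside it is an extrapolation the profile was
#' not built to support and raises a domain error unless explicitly requested.
#'
#' @param profile A [fit_power_profile()] object.
#' @param inr Positive INR value(s) at which to predict.
#' @param extrapolate Set `TRUE` to allow prediction outside `inr_domain`.
#' @return Numeric vector of predicted `%ru` values.
#' @examples
#' pts <- tibble::tibble(inr = c(1, 2, 4), ru_percent = c(2, 4, 8))
#' predict_ru(fit_power_profile(pts), 3)
#' @export
predict_ru <- function(profile, inr, extrapolate = FALSE) {
  if (!inherits(profile, "precision_profile")) {
    abort_invalid("`profile` must be a `precision_profile` object.")
  }
  if (!is.numeric(inr) || anyNA(inr) || any(inr <= 0)) {
    abort_invalid("`inr` must be positive.")
  }
  dom <- profile$inr_domain
  if (!extrapolate && (any(inr < dom[1]) || any(inr > dom[2]))) {
    abort_domain(paste0(
      "INR outside the profile validity domain [", dom[1], ", ", dom[2],
      "]; set `extrapolate = TRUE` to override."
    ))
  }
  profile$coefficient_a * inr^profile$exponent_b
}

#' @export
print.precision_profile <- function(x, ...) {
  cat("Precision profile: %ru = a * INR^b\n")
  cat(sprintf("  a = %.4f, b = %.4f\n", x$coefficient_a, x$exponent_b))
  cat(sprintf("  validity domain: INR %.2f to %.2f, fitted on %d points\n",
              x$inr_domain[1], x$inr_domain[2], nrow(x$fit_points)))
  invisible(x)
}

# refit on the stored points; cheap, and keeps the object JSON-serialisable
profile_lm <- function(x) {
  lm(log(ru_percent) ~ log(inr), data = x$fit_points)
}

#' @rdname fit_power_profile
#' @param x A `precision_profile` object.
#' @param ... Unused.
#' @export
tidy.precision_profile <- function(x, ...) {
  sm <- summary(profile_lm(x))$coefficients
  tibble(
    term = c("coefficient_a", "exponent_b"),
    estimate = c(x$coefficient_a, x$exponent_b),
    # ln(a) SE delta-mapped back to the a scale
    std.error = c(sm[1, 2] * x$coefficient_a, sm[2, 2])
  )
}

#' @rdname fit_power_profile
#' @export
glance.precision_profile <- function(x, ...) {
  sm <- summary(profile_lm(x))
  tibble(
    coefficient_a = x$coefficient_a,
    exponent_b = x$exponent_b,
    r.squared = sm$r.squared,
    sigma_log = sm$sigma,
    n_points = nrow(x$fit_points),
    domain_lower = x$inr_domain[1],
    domain_upper = x$inr_domain[2]
  )
}

#' Plot a precision profile
#'
#' Fitted power curve over its validity domain with the observed
#' (INR, `%ru`) points; optionally a dashed horizontal line marking an
#' uncertainty-budget share for visual comparison.
#'
#' @param object A `precision_profile` object.
#' @param budget_share Optional budget line, percent (e.g. 3.3 or 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.precision_profile <- function(object, budget_share = NULL, ...) {
  dom <- object$inr_domain
  curve <- tibble(
    inr = seq(dom[1], dom[2], length.out = 200),
    ru_percent = object$coefficient_a * seq(dom[1], dom[2], length.out = 200)^object$exponent_b
  )
  p <- ggplot2::ggplot(object$fit_points,
                       ggplot2::aes(x = .data$inr, y = .data$ru_percent)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Mean INR", y = "Relative standard uncertainty (%)",
      title = "Precision profile",
      subtitle = sprintf("%%ru = %.3f × INR^%.3f", object$coefficient_a,
                         object$exponent_b)
    )
  if (!is.null(budget_share)) {
    p <- p + ggplot2::geom_hline(yintercept = budget_share,
                                 linetype = "dashed", colour = "darkorange")
  }
  p
}

#' Export or import a precision profile as JSON
#'
#' A small plain-text representation (coefficients, domain, fit points) so a
#' fitted profile can be shared between runs and tools.
#'
#' @param profile A `precision_profile` object.
#' @param path File path for the JSON document.
#' @return `write_profile_json()` returns `path` invisibly;
#'   `read_profile_json()` returns the reconstructed `precision_profile`.
#' @export
write_profile_json <- function(profile, path) {
  if (!inherits(profile, "precision_profile")) {
    abort_invalid("`profile` must be a `precision_profile` object.")
  }
  jsonlite::write_json(
    list(
      coefficient_a = profile$coefficient_a,
      exponent_b = profile$exponent_b,
      inr_domain = profile$inr_domain,
      fit_points = profile$fit_points
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  if (!file.exists(path)) {
    abort_invalid(paste0("File not found: ", path))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("coefficient_a", "exponent_b", "inr_domain", "fit_points")
  if (!all(needed %in% names(obj))) {
    abort_parse("Not a precision-profile JSON document.")
  }
  structure(
    list(
      coefficient_a = as.numeric(obj$coefficient_a),
      exponent_b = as.numeric(obj$exponent_b),
      inr_domain = as.numeric(obj$inr_domain),
      fit_points = as_tibble(obj$fit_points)
    ),
    class = "precision_profile"
  )
}
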