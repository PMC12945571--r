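#' Allocate the INR measurement-uncertainty budget across the traceability
#' chain
#'
#' The outcome-based performance specification for the INR caps the total
#' standard uncertainty at the end-user level at 10% (CV). Two allocation
#' conventions for sharing that total down the calibration hierarchy are
#' supported, both linear in the CV (the field's rule-of-thumb arithmetic,
#' not a quadrature combination):
#'
#' * `"thirds"` — one third each for the calibration laboratories, the IVD
#'   manufacturers, and the end-user laboratories (10/3 ≈ 3.3% each).
#' * `"half_reference"` — half for the primary and secondary reference
#'   thromboplastins together, half for IVD industry plus end users combined
#'   (5% and 5%), the pragmatic split proposed once both reference
#'   preparations are in place.
#'
#' @param total_ru_percent Positive total relative-uncertainty budget
#'   (default 10).
#' @param scheme `"thirds"` or `"half_reference"`.
#' @return A tibble with columns `tier`, `share_percent`, `scheme`; the shares
#'   sum to `total_ru_percent`.
#' @seealso [budget_quadrature()] for the root-sum-of-squares combination of a
#'   set of shares, reported for context only.
#' @examples
#' allocate_budget(10, "thirds")
#' allocate_budget(10, "half_reference")
#' @export
allocate_budget <- function(total_ru_percent = 10,
                            scheme = c("thirds", "half_reference")) {
  if (!is.numeric(total_ru_percent) || length(total_ru_percent) != 1L ||
      is.na(total_ru_percent) || total_ru_percent <= 0) {
    abort_invalid("`total_ru_percent` must be a single positive number.")
  }
  if (!is.character(scheme) || !scheme[1] %in% c("thirds", "half_reference")) {
    abort_invalid("`scheme` must be \"thirds\" or \"half_reference\".")
  }
  scheme <- scheme[1]
  out <- switch(scheme,
    thirds = tibble(
      tier = c("calibration_laboratories", "ivd_manufacturers", "end_users"),
      share_percent = rep(total_ru_percent / 3, 3)
    ),
    half_reference = tibble(
      tier = c("reference_thromboplastins", "ivd_manufacturers_and_end_users"),
      share_percent = rep(total_ru_percent / 2, 2)
    )
  )
  out$scheme <- scheme
  out
}

#' Check a relative uncertainty against a budget share
#'
#' A measured `%ru` meets its tier's budget when it is strictly below the
#' allocated share (the specification is an exclusive bound, "< 3.3%").
#'
#' @param ru_percent Non-negative measured relative uncertainty, percent;
#'   vectorised.
#' @param budget_share Positive allocated share, percent.
#' @return A tibble with columns `ru_percent`, `budget_share`, `pass`
#'   (strict `ru < share`) and `margin` (`share - ru`, negative on failure).
#' @examples
#' check_budget(3.2, 3.3)
#' check_budget(c(2.2, 3.2, 4.2), 3.3)
#' @export
check_budget <- function(ru_percent, budget_share) {
  if (!is.numeric(ru_percent) || anyNA(ru_percent) || any(ru_percent < 0)) {
    abort_invalid("`ru_percent` must be non-negative.")
  }
  if (!is.numeric(budget_share) || anyNA(budget_share) || any(budget_share <= 0)) {
    abort_invalid("`budget_share` must be positive.")
  }
  tibble(
    ru_percent = ru_percent,
    budget_share = budget_share,
    pass = ru_percent < budget_share,
    margin = budget_share - ru_percent
  )
}

#' Quadrature combination of budget shares
#'
#' The root-sum-of-squares `sqrt(sum(share^2))` of a set of independent CV
#' shares. Provided for context when comparing the linear rule-of-thumb
#' allocation with how independent uncertainty components actually combine;
#' the allocation itself ([allocate_budget()]) is linear.
#'
#' @param shares Numeric vector of non-negative shares, percent.
#' @return The combined share, percent.
#' @examples
#' budget_quadrature(c(3.3, 3.3, 3.3)) # < 10: linear sharing is conservative
#' @export
budget_quadrature <- function(shares) {
  if (!is.numeric(shares) || length(shares) == 0L || anyNA(shares) ||
      any(shares < 0)) {
    abort_invalid("`shares` must be non-negative numbers.")
  }
  sqrt(sum(shares^2))
}
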