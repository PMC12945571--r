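#' Configuration of a synthetic multicenter calibration study
#'
#' Describes the generating truth and design of a simulated calibration-lab
#' network study: a network of calibration laboratories, each with a number
#' of operators; every operator measures `replicates` PTs per lyophilized
#' plasma, determines an MNPT as the geometric mean of a panel of healthy
#' donors, and works with an ISI realization drawn around the assigned value.
#' The defaults mirror the reference-measurement-system design: 4 calibration
#' laboratories, 2 operators each, n = 10 replicates per plasma, MNPT from 20
#' healthy donors.
#'
#' @param true_isi Assigned (true) ISI of the thromboplastin.
#' @param sd_isi Between-operator SD of the ISI realizations.
#' @param true_mnpt_s True MNPT, seconds.
#' @param true_plasma_pts Named numeric vector of true PTs (seconds) per
#'   lyophilized plasma, e.g. `c(B = 19.80, C = 29.38)`.
#' @param sd_log_pt Replicate-level SD of `ln(PT)` (repeatability); a single
#'   value or one per plasma.
#' @param donor_log_sd SD of `ln(PT)` across healthy donors (default 0.05, a
#'   typical normal-donor spread).
#' @param n_labs,operators_per_lab,replicates,donors Design sizes (defaults
#'   4, 2, 10, 20).
#' @param seed Integer seed; [generate_study()] is deterministic given the
#'   config.
#' @return An object of class `study_config`.
#' @examples
#' study_config(true_isi = 1.08, sd_isi = 0.030, true_mnpt_s = 11.28,
#'              true_plasma_pts = c(C = 29.38), sd_log_pt = 0.016, seed = 1)
#' @export
study_config <- function(true_isi, sd_isi, true_mnpt_s, true_plasma_pts,
                         sd_log_pt = 0.016, donor_log_sd = 0.05,
                         n_labs = 4, operators_per_lab = 2,
                         replicates = 10, donors = 20, seed = 1L) {
  if (!is.numeric(true_isi) || true_isi <= 0 ||
      !is.numeric(true_mnpt_s) || true_mnpt_s <= 0) {
    abort_invalid("`true_isi` and `true_mnpt_s` must be positive.")
  }
  if (sd_isi < 0 || donor_log_sd < 0 || any(sd_log_pt < 0)) {
    abort_invalid("SD parameters must be non-negative.")
  }
  if (length(true_plasma_pts) == 0L || is.null(names(true_plasma_pts)) ||
      any(!nzchar(names(true_plasma_pts))) || any(true_plasma_pts <= 0)) {
    abort_invalid("`true_plasma_pts` must be a named vector of positive PTs.")
  }
  if (!length(sd_log_pt) %in% c(1L, length(true_plasma_pts))) {
    abort_invalid("`sd_log_pt` must have length 1 or one value per plasma.")
  }
  sizes <- c(n_labs = n_labs, operators_per_lab = operators_per_lab,
             replicates = replicates, donors = donors)
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    abort_invalid("Design sizes must be whole numbers >= 1.")
  }
  structure(
    list(
      true_isi = true_isi, sd_isi = sd_isi, true_mnpt_s = true_mnpt_s,
      true_plasma_pts = true_plasma_pts,
      sd_log_pt = setNames(rep(sd_log_pt, length.out = length(true_plasma_pts)),
                           names(true_plasma_pts)),
      donor_log_sd = donor_log_sd,
      n_labs = as.integer(n_labs),
      operators_per_lab = as.integer(operators_per_lab),
      replicates = as.integer(replicates), donors = as.integer(donors),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Generate synthetic multicenter calibration-study raw data
#'
#' Draws raw data for every operator in the configured network, in a fixed
#' deterministic order under the config's seed: the operator's ISI realization
#' `N(true_isi, sd_isi)` truncated above zero, a healthy-donor PT panel
#' `exp(N(ln true_mnpt, donor_log_sd))`, and per-plasma replicate PTs
#' `exp(N(ln true_pt, sd_log_pt))`. With all SDs at zero every value equals
#' its generating truth exactly.
#'
#' @param config A [study_config()].
#' @return An object of class `calibration_study`: a list of tibbles
#'   `replicates` (lab, operator, plasma_id, replicate, pt_s), `donors`
#'   (lab, operator, donor, pt_s), `operators` (lab, operator, isi), plus the
#'   generating `config`.
#' @examples
#' cfg <- study_config(1.08, 0.030, 11.28, c(C = 29.38), seed = 42)
#' study <- generate_study(cfg)
#' head(study$replicates)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) {
    abort_invalid("`config` must be created with `study_config()`.")
  }
  set.seed(config$seed)
  plasmas <- names(config$true_plasma_pts)
  ops <- tidyr::expand_grid(
    lab = paste0("lab", seq_len(config$n_labs)),
    operator = paste0("op", seq_len(config$operators_per_lab))
  )
  pieces <- purrr::pmap(ops, function(lab, operator) {
    isi <- rnorm_pos(1L, config$true_isi, config$sd_isi)
    donor_pts <- exp(rnorm(config$donors, log(config$true_mnpt_s),
                           config$donor_log_sd))
    reps <- purrr::map_dfr(plasmas, function(pl) {
      tibble(
        lab = lab, operator = operator, plasma_id = pl,
        replicate = seq_len(config$replicates),
        pt_s = exp(rnorm(config$replicates,
                         log(config$true_plasma_pts[[pl]]),
                         config$sd_log_pt[[pl]]))
      )
    })
    list(
      operators = tibble(lab = lab, operator = operator, isi = isi),
      donors = tibble(lab = lab, operator = operator,
                      donor = seq_len(config$donors), pt_s = donor_pts),
      replicates = reps
    )
  })
  structure(
    list(
      replicates = purrr::map_dfr(pieces, "replicates"),
      donors = purrr::map_dfr(pieces, "donors"),
      operators = purrr::map_dfr(pieces, "operators"),
      config = config
    ),
    class = "calibration_study"
  )
}

#' @export
print.calibration_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic calibration study: %d labs x %d operators, %d plasmas, n = %d replicates, %d donors (seed %d)\n",
    cfg$n_labs, cfg$operators_per_lab, length(cfg$true_plasma_pts),
    cfg$replicates, cfg$donors, cfg$seed
  ))
  invisible(x)
}

#' Recover per-operator summary statistics from study raw data
#'
#' Computes, for each operator, the summaries that the uncertainty analysis
#' consumes: geometric-mean PT, `sd_log_pt` and `n` per plasma; the MNPT as
#' the geometric mean of the operator's donor panel; and the between-operator
#' `sd_isi` as the sample SD of the operator ISI realizations. All SDs use the
#' `n - 1` denominator.
#'
#' @param study A [generate_study()] result.
#' @return A list with elements `plasmas` (per lab/operator/plasma tibble:
#'   `pt_mean_s`, `sd_log_pt`, `n`), `operators` (per lab/operator tibble:
#'   `mnpt_s`, `isi`) and `sd_isi` (scalar).
#' @examples
#' cfg <- study_config(1.08, 0.030, 11.28, c(C = 29.38), seed = 42)
#' estimate_parameters(generate_study(cfg))$sd_isi
#' @export
estimate_parameters <- function(study) {
  if (!inherits(study, "calibration_study")) {
    abort_invalid("`study` must be created with `generate_study()`.")
  }
  if (nrow(study$operators) < 2L) {
    abort_invalid("`sd_isi` is undefined with fewer than two operators.")
  }
  operators <- study$donors |>
    group_by(.data$lab, .data$operator) |>
    summarise(mnpt_s = geometric_mean(.data$pt_s), .groups = "drop") |>
    left_join(study$operators, by = c("lab", "operator"))
  plasmas <- study$replicates |>
    group_by(.data$lab, .data$operator, .data$plasma_id) |>
    summarise(
      pt_mean_s = geometric_mean(.data$pt_s),
      sd_log_pt = sd(log(.data$pt_s)),
      n = n(),
      .groups = "drop"
    )
  list(plasmas = plasmas, operators = operators,
       sd_isi = sd(study$operators$isi))
}

#' Top-down between-operator CV of the INR
#'
#' The empirical (top-down) counterpart of the analytic (bottom-up)
#' propagation: each operator's INR for a plasma is computed from that
#' operator's own geometric-mean PT, MNPT and ISI realization as
#' `(PT̄/MNPT)^ISI`, and the between-operator coefficient of variation is
#' `100 × SD/mean` of those INRs on the INR scale — the convention in which
#' multicenter between-operator CVs are reported, and directly comparable
#' with the `%ru` of [inr_uncertainty()].
#'
#' @param study A [generate_study()] result with at least two operators.
#' @param plasma_id Optional plasma label(s) to restrict to.
#' @return A tibble with columns `plasma_id`, `cv_percent`, `n_operators`.
#' @examples
#' cfg <- study_config(1.08, 0.030, 11.28, c(B = 19.80, C = 29.38), seed = 42)
#' between_operator_cv(generate_study(cfg))
#' @export
between_operator_cv <- function(study, plasma_id = NULL) {
  est <- estimate_parameters(study)
  df <- est$plasmas |>
    left_join(est$operators, by = c("lab", "operator")) |>
    mutate(inr = (.data$pt_mean_s / .data$mnpt_s)^.data$isi)
  if (!is.null(plasma_id)) {
    unknown <- setdiff(plasma_id, unique(df$plasma_id))
    if (length(unknown) > 0L) {
      abort_invalid(paste0("Unknown plasma_id: ",
                           paste(unknown, collapse = ", "), "."))
    }
    df <- filter(df, .data$plasma_id %in% .env$plasma_id)
  }
  df |>
    group_by(.data$plasma_id) |>
    summarise(
      cv_percent = 100 * sd(.data$inr) / mean(.data$inr),
      n_operators = n(),
      .groups = "drop"
    )
}
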