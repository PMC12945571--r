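#' Read a PT/INR measurement table from CSV
#'
#' Reads and validates the comma-delimited measurement format (period decimal
#' separator, mandatory header). Required columns: `irp_id`, `plasma_id`,
#' `pt_mean_s`, `sd_log_pt`, `n`, `mnpt_s`, `sd_log_mnpt`, `m`, `isi`,
#' `sd_isi`. Alternatively a `replicates` column of semicolon-joined raw PTs
#' (e.g. `"12.1;12.3;12.0"`) may replace `pt_mean_s`/`sd_log_pt`/`n`; the
#' summary statistics are then derived with [plasma_summary()]. Validation
#' errors name the offending row and column.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A validated tibble ready for [inr_uncertainty()].
#' @export
read_measurement_csv <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_invalid(paste0("File not found: ", path))
  }
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )),
    error = function(e) abort_parse(paste0("Cannot parse CSV: ", conditionMessage(e)))
  )
  if (nrow(raw) == 0L) {
    abort_parse("Empty measurement file: no data rows.")
  }
  has_reps <- "replicates" %in% names(raw)
  numeric_cols <- if (has_reps) {
    c("mnpt_s", "sd_log_mnpt", "m", "isi", "sd_isi")
  } else {
    measurement_columns()
  }
  needed <- c("irp_id", "plasma_id", numeric_cols)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort_parse(paste0("Missing required column(s): ",
                       paste(missing_cols, collapse = ", "), "."))
  }
  parse_numeric_col <- function(col) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      abort_parse(paste0("Non-numeric value in row ", bad[1],
                         ", column `", col, "`."))
    }
    vals
  }
  out <- tibble(irp_id = raw$irp_id, plasma_id = raw$plasma_id)
  for (col in numeric_cols) out[[col]] <- parse_numeric_col(col)

  if (has_reps) {
    reps <- purrr::imap(raw$replicates, function(txt, i) {
      vals <- suppressWarnings(as.numeric(strsplit(txt, ";", fixed = TRUE)[[1]]))
      if (length(vals) == 0L || anyNA(vals) || any(vals <= 0)) {
        abort_parse(paste0("Invalid replicate list in row ", i,
                           ", column `replicates`."))
      }
      vals
    })
    summ <- purrr::map_dfr(reps, plasma_summary)
    # if summary columns are also present they must agree with the raw lists
    if ("pt_mean_s" %in% names(raw)) {
      given <- parse_numeric_col("pt_mean_s")
      off <- which(abs(given - summ$pt_mean_s) > 1e-9 * summ$pt_mean_s)
      if (length(off) > 0L) {
        abort_parse(paste0("Row ", off[1],
                           ": `pt_mean_s` does not equal the geometric mean of `replicates`."))
      }
    }
    if ("n" %in% names(raw)) {
      given_n <- parse_numeric_col("n")
      off <- which(given_n != summ$n)
      if (length(off) > 0L) {
        abort_parse(paste0("Row ", off[1],
                           ": `n` does not match the number of `replicates`."))
      }
    }
    out$pt_mean_s <- summ$pt_mean_s
    out$sd_log_pt <- summ$sd_log_pt
    out$n <- summ$n
  }
  out <- out[, c("irp_id", "plasma_id", measurement_columns())]
  key <- paste(out$irp_id, out$plasma_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_parse(paste0("Duplicate (irp_id, plasma_id) pair in row ",
                       which(duplicated(key))[1], "."))
  }
  validate_measurements(out)
  out
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurement_csv()]: full-precision, comma-delimited,
#' period decimal separator. Write-then-read is the identity on all fields.
#'
#' @param data A validated measurement table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(data, path) {
  validate_measurements(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Render an uncertainty report with conventional display rounding
#'
#' Formats [inr_uncertainty()] results the way calibration reports print
#' them: mean INR to 2 decimals, `SD_logINR` to 3, the confidence interval as
#' `"lower-upper"` with 2 decimals, and `%ru` to 1 decimal. Rounding happens
#' only here — the analysis columns themselves are never rounded.
#'
#' @param results Output of [inr_uncertainty()].
#' @param path Optional file path; the CSV form is written there.
#' @param format `"csv"` (a tibble of formatted strings, default) or
#'   `"text"` (aligned fixed-width lines).
#' @return The formatted tibble, or a character vector of lines for
#'   `format = "text"`.
#' @examples
#' irp_example_measurements() |> inr_uncertainty() |> render_report()
#' @export
render_report <- function(results, path = NULL, format = c("csv", "text")) {
  format <- match.arg(format)
  needed <- c("mean_inr", "sd_log_inr", "ci_lower", "ci_upper", "ru_percent")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    abort_invalid("`results` must be the output of `inr_uncertainty()`.")
  }
  ids <- intersect(c("irp_id", "plasma_id"), names(results))
  fmt <- dplyr::bind_cols(
    results[, ids, drop = FALSE],
    tibble(
      mean_inr = sprintf("%.2f", results$mean_inr),
      sd_log_inr = sprintf("%.3f", results$sd_log_inr),
      ci_95 = sprintf("%.2f-%.2f", results$ci_lower, results$ci_upper),
      ru_percent = sprintf("%.1f", results$ru_percent)
    )
  )
  if (!is.null(path)) readr::write_csv(fmt, path, progress = FALSE)
  if (format == "text") {
    cols <- purrr::imap(fmt, ~ format(c(.y, .x), justify = "right"))
    return(apply(as.data.frame(cols), 1L, paste, collapse = "  "))
  }
  fmt
}

#' Worked-example measurement table: two WHO thromboplastin IRPs
#'
#' The bundled per-plasma calibration summaries for two WHO international
#' reference preparations for thromboplastin — the human recombinant rTF/16
#' and its successor IRP 24/114 — measured with four lyophilized plasmas
#' spanning INR ~1 (normal, plasma A) through the oral-anticoagulation
#' therapeutic window (plasmas B and C) to INR ~5.5 (plasma D). Each row
#' carries the geometric-mean PT of n = 10 replicates with its log-scale SD,
#' the MNPT (geometric mean of 20 healthy-donor PTs) with its
#' intermediate-precision SD over m determinations, and the assigned ISI with
#' its between-laboratory SD.
#'
#' @return A tibble of 8 measurement rows, one per (IRP, plasma).
#' @examples
#' irp_example_measurements()
#' @export
irp_example_measurements <- function() {
  read_measurement_csv(
    system.file("extdata", "irp_lyophilized_plasmas.csv", package = "inrmu",
                mustWork = TRUE)
  )
}
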