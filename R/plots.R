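#' Forest-style plot of INR uncertainty results
#'
#' Mean INR with its coverage-factor interval for every plasma, faceted by
#' reference preparation when several are present. A quick visual of how the
#' expanded uncertainty widens with increasing INR.
#'
#' @param results Output of [inr_uncertainty()].
#' @return A ggplot object.
#' @examples
#' irp_example_measurements() |> inr_uncertainty() |> plot_inr_uncertainty()
#' @export
plot_inr_uncertainty <- function(results) {
  needed <- c("mean_inr", "ci_lower", "ci_upper")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    abort_invalid("`results` must be the output of `inr_uncertainty()`.")
  }
  if (!"plasma_id" %in% names(results)) {
    results$plasma_id <- as.character(seq_len(nrow(results)))
  }
  p <- ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$mean_inr, y = .data$plasma_id)
  ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "INR (point estimate and expanded interval)",
                  y = "Plasma")
  if ("irp_id" %in% names(results)) {
    p <- p + ggplot2::facet_wrap(~irp_id, ncol = 1)
  }
  p
}
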