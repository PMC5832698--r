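#' Plot micro / macro / predicted rate estimates side by side
#'
#' Point-and-interval comparison of rate estimates (median and 95%
#' percentile interval per estimate), the standard way to display the
#' micro- vs macroevolutionary rate contrast and the pruning-based
#' prediction.
#'
#' @param ... `rate_estimate` objects (or one list of them).
#' @param log_scale plot rates on a log axis (default `TRUE`; molecular
#'   rates typically span orders of magnitude).
#' @return a ggplot object.
#' @export
plot_rate_comparison <- function(..., log_scale = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_rate_comparison requires the ggplot2 package", call. = FALSE)
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1]], "rate_estimate"))
    ests <- ests[[1]]
  df <- do.call(rbind, lapply(ests, summary))
  df$label <- factor(df$label, levels = unique(df$label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = label, y = median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
    ggplot2::labs(x = NULL, y = "rate (substitutions / site / Myr)") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot simulated vs empirical trait-rate distributions
#'
#' Overlaid histograms of the drift-simulated and empirical sigma^2 samples
#' from [drift_prediction_test()], with the empirical 95% interval marked.
#'
#' @param test result of [drift_prediction_test()].
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_prediction_test <- function(test, bins = 30) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_prediction_test requires the ggplot2 package", call. = FALSE)
  df <- data.frame(
    sample = c(rep("empirical", length(test$emp_rates)),
               rep("simulated", length(test$sim_rates))),
    sigma2 = c(test$emp_rates, test$sim_rates)
  )
  ci <- quantile(test$emp_rates, c(0.025, 0.975))
  ggplot2::ggplot(df, ggplot2::aes(x = sigma2, fill = sample)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = bins) +
    ggplot2::geom_vline(xintercept = ci, linetype = "dashed") +
    ggplot2::labs(x = expression(sigma^2 ~ "(trait"^2 * "/Myr)"), y = "count",
                  subtitle = sprintf("prediction probability p = %.3f", test$p)) +
    ggplot2::theme_minimal()
}
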