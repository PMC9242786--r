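#' Agreement plots for paired measurements
#'
#' `plot_agreement_scatter()` draws predicted vs actual with the OLS fit and
#' the identity line; `plot_bland_altman()` draws the difference against the
#' pair mean with the bias and the 95% limits of agreement. Both require
#' \pkg{ggplot2}.
#'
#' @param reference reference measurements (mm).
#' @param candidate paired candidate measurements (mm).
#' @return A ggplot object.
#' @export
plot_agreement_scatter <- function(reference, candidate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  la <- linear_agreement(reference, candidate)
  df <- data.frame(reference = reference, candidate = candidate)
  ggplot2::ggplot(df, ggplot2::aes(x = reference, y = candidate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = la$slope, intercept = la$offset,
                         colour = "steelblue") +
    ggplot2::labs(x = "Force-plate COP path (mm)",
                  y = "Predicted COP path (mm)",
                  subtitle = sprintf("slope %.2f, offset %.1f mm",
                                     la$slope, la$offset)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_agreement_scatter
#' @export
plot_bland_altman <- function(reference, candidate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ba <- bland_altman(candidate, reference)
  df <- data.frame(mean = (reference + candidate) / 2,
                   diff = candidate - reference)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (mm)",
                  y = "Difference, predicted - actual (mm)",
                  subtitle = sprintf("bias %.1f mm, LoA [%.1f, %.1f] mm",
                                     ba$bias, ba$loa[1], ba$loa[2])) +
    ggplot2::theme_minimal()
}
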