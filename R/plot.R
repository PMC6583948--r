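#' Occurrence-abundance plot of a neutral fit
#'
#' One dot per taxon (mean relative abundance on a log x-axis, occurrence
#' frequency on y), the fitted neutral expectation as a solid line and the
#' 95\% prediction band as dashed lines with a shaded ribbon. Taxa outside
#' the band are colored by direction.
#'
#' @param fit a [NeutralFit-class].
#' @param pointSize dot size.
#' @return a ggplot object.
#' @export
plotFit <- function(fit, pointSize = 1.2) {
  df <- as.data.frame(fit)
  grid_p <- exp(seq(log(max(min(df$p_bar) / 2, 1e-6)),
                    log(min(max(df$p_bar) * 1.5, 1 - 1e-9)),
                    length.out = 300))
  curve <- data.frame(
    p_bar = grid_p,
    phi = occurrenceProbability(grid_p, fit@stats@N, fit@mHat,
                                fit@stats@d))
  band <- confidenceBands(curve$phi, fit@stats@S, level = fit@level)
  curve$lower <- band$lower
  curve$upper <- band$upper
  ggplot2::ggplot(df, ggplot2::aes(x = p_bar)) +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(ymin = lower,
                                      ymax = upper),
                         fill = "grey85", alpha = 0.7) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = lower),
                       linetype = "dashed", color = "grey40") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = upper),
                       linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = f, color = label),
                        size = pointSize, alpha = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = phi),
                       linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(
      values = c(above = "#c0392b", within = "grey30",
                 below = "#2980b9")) +
    ggplot2::labs(x = "mean relative abundance",
                  y = "occurrence frequency", color = NULL,
                  subtitle = sprintf("m = %.3g,  R² = %.2f",
                                     fit@mHat, fit@rSquared)) +
    ggplot2::theme_classic()
}

utils::globalVariables(c("p_bar", "f", "label", "lower", "upper", "phi"))
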