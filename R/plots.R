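#' Passing-Bablok scatter plot
#'
#' Scatter of the paired measurements with the identity line (dashed) and
#' the fitted Passing-Bablok line.
#'
#' @param x,y the paired measurements.
#' @param pb a [passing_bablok()] result for the same data (computed if
#'   omitted).
#' @param xlab,ylab,main plot annotations.
#' @return the `pb_result`, invisibly.
#' @export
plot_passing_bablok <- function(x, y, pb = NULL, xlab = "method A",
                                ylab = "method B", main = "Passing-Bablok") {
  if (is.null(pb)) pb <- passing_bablok(x, y)
  graphics::plot(x, y, pch = 19, col = "#00000088", xlab = xlab,
                 ylab = ylab, main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(pb$intercept, pb$slope, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "Y = %.4f X + %.4f", pb$slope, pb$intercept))
  invisible(pb)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias line and limits of agreement.
#'
#' @param ba a [bland_altman()] result.
#' @param xlab,ylab,main plot annotations.
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, xlab = "mean of methods",
                              ylab = "difference (A - B)",
                              main = "Bland-Altman") {
  graphics::plot(ba$means, ba$diffs, pch = 19, col = "#00000088",
                 xlab = xlab, ylab = ylab, main = main,
                 ylim = range(c(ba$diffs, ba$loa_lower, ba$loa_upper)))
  graphics::abline(h = ba$bias, col = "firebrick", lwd = 2)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), lty = 2,
                   col = "steelblue")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "%.3f ± %.2f × %.3f", ba$bias, ba$multiplier, ba$sd_diff))
  invisible(ba)
}
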