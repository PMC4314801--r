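#' Plot LD decay curves for one or more populations
#'
#' @param ... one or more [ld_decay()] tables.
#' @param smooth lowess-smooth each curve for display (statistics are
#'   never smoothed; this is a plotting concern only).
#' @return Invisibly, `NULL`. Draws on the active device.
#' @export
plot_ld_decay <- function(..., smooth = FALSE) {
  tables <- list(...)
  cols <- seq_along(tables) + 1L
  xmax <- max(vapply(tables, function(t) max(t$bin_end), 0)) / 1e6
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "inter-SNP distance (Mb)", ylab = expression(r^2),
                 main = "LD decay")
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    x <- (t$bin_start + t$bin_end) / 2 / 1e6
    y <- t$mean_r2
    if (smooth && length(x) > 3) {
      lo <- stats::lowess(x, y)
      graphics::lines(lo, col = cols[i], lwd = 2)
    } else {
      graphics::lines(x, y, col = cols[i], lwd = 2)
    }
    graphics::points(x, y, col = cols[i], pch = 16, cex = 0.6)
  }
  graphics::legend("topright", legend = vapply(tables, function(t)
    t$population[1L], ""), col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot windowed scan statistics along a chromosome
#'
#' @param table a window table carrying `start`, `end` and a statistic
#'   column.
#' @param stat_col which column to draw.
#' @param highlight optional bp position marked with a vertical dashed
#'   line (e.g. a known sweep site).
#' @return Invisibly, `NULL`.
#' @export
plot_window_stat <- function(table, stat_col = "max_stat", highlight = NULL) {
  x <- (table$start + table$end) / 2 / 1e3
  y <- table[[stat_col]]
  graphics::plot(x, y, type = "s", xlab = "position (kb)", ylab = stat_col,
                 main = paste("windowed", stat_col))
  if (!is.null(highlight))
    graphics::abline(v = highlight / 1e3, lty = 2, col = "red")
  invisible(NULL)
}
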