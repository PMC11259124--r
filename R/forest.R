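# Forest table and plot across several burden comparisons.

#' Assemble a plot-ready forest table from burden fits
#'
#' @param results List of `"ptv_burden"` fits (see [burden_test()]).
#' @return Data frame of class `"forest_table"`, one row per comparison in
#'   input order: `label`, `or`, `ci_low`, `ci_high`, the four cells, and
#'   carrier frequencies. The attribute `axis` carries the log-scale hint.
#' @export
forest_table <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "ptv_burden"))
    t <- r$table
    data.frame(label = r$label, or = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high,
               a = t$a, b = t$b, c = t$c, d = t$d,
               freq_case_pct = r$carrier_freq_case,
               freq_control_pct = r$carrier_freq_control,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "axis") <- "log"
  class(out) <- c("forest_table", "data.frame")
  out
}

#' Forest plot of odds ratios on a log axis
#'
#' @param x A [forest_table()] (or list of burden fits).
#' @param ref Reference line position (default OR = 1).
#' @param xlab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.forest_table <- function(x, ref = 1, xlab = "Odds ratio (log scale)",
                              main = "Carrier burden", ...) {
  ft <- if (inherits(x, "forest_table")) x else forest_table(x)
  n <- nrow(ft)
  ys <- rev(seq_len(n))
  xlim <- range(c(ft$ci_low, ft$ci_high, ref), na.rm = TRUE)
  op <- graphics::par(mar = c(4, 12, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(ft$or, ys, log = "x", xlim = xlim, ylim = c(0.5, n + 0.5),
                 pch = 15, cex = 1.3, yaxt = "n", ylab = "", xlab = xlab,
                 main = main, ...)
  graphics::segments(ft$ci_low, ys, ft$ci_high, ys, lwd = 2)
  graphics::abline(v = ref, lty = 2, col = "grey40")
  graphics::axis(2, at = ys, labels = ft$label, las = 1, cex.axis = 0.8)
  invisible(ft)
}

#' @export
plot.ptv_burden <- function(x, ...) {
  plot.forest_table(forest_table(list(x)), ...)
}
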