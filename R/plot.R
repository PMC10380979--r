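# Base-graphics views of the two partitions.

.region_palette <- function(n) {
  grDevices::hcl.colors(max(n, 3L), palette = "Set 2")[seq_len(n)]
}

#' Plot an interval partition
#'
#' Draws each classifier's cost line over the clinical interval and, below,
#' the colored bar of sub-intervals where each classifier is cost-optimal.
#'
#' @param x an [partition_interval()] result.
#' @param profiles the [profile_set()] the partition was computed from;
#'   when given, all cost lines are drawn.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.interval_partition <- function(x, profiles = NULL, ...) {
  rho <- attr(x, "rho")
  owners <- unique(x$predictor)
  cols <- stats::setNames(.region_palette(length(owners)), owners)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(-0.12, 1),
                 xlab = expression(rc[1]), ylab = "normalized cost rc", ...)
  if (!is.null(profiles)) {
    profiles <- as_profile_set(profiles)
    k <- .misc_coeffs(profiles, rho)
    for (i in seq_len(nrow(profiles))) {
      own <- profiles$name[i] %in% owners
      graphics::abline(a = k$intercept[i], b = k$slope[i],
                       col = if (own) cols[[profiles$name[i]]] else "grey70",
                       lwd = if (own) 2 else 1)
    }
  }
  graphics::rect(x$lo, -0.1, x$hi, -0.03, col = cols[x$predictor], border = NA)
  graphics::legend("topright", legend = owners, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Plot a triangle partition
#'
#' Draws the clinical triangle with each region colored by its cost-optimal
#' classifier.
#'
#' @param x a [partition_triangle()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.region_partition <- function(x, ...) {
  preds <- x$summary$predictor
  cols <- stats::setNames(.region_palette(length(preds)), preds)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                 xlab = expression(rc[0]), ylab = expression(rc[1]), ...)
  for (pred in preds) {
    for (poly in x$regions[[pred]]) {
      graphics::polygon(poly[, 1], poly[, 2], col = cols[[pred]],
                        border = cols[[pred]])
    }
  }
  graphics::polygon(c(0, 1, 0), c(0, 0, 1), border = "black", lwd = 1.5)
  graphics::legend("topright", legend = sprintf(
    "%s (%.1f%%)", preds, 100 * x$summary$fraction),
    fill = cols, bty = "n")
  invisible(x)
}
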