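## Base-graphics diagnostics. Each returns its input invisibly so calls can
## be piped into scripts that also write CSV/JSON.

#' Plot a cumulative rolled-area trace with its logistic fit
#'
#' @param trace a [RollingTrace-class].
#' @param fit optional [LogisticFit-class] overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plotRollingFit <- function(trace, fit = NULL, ...) {
  graphics::plot(trace@times, trace@cumulativeArea, pch = 16, cex = 0.6,
                 col = "steelblue", xlab = "time (s)",
                 ylab = expression("cumulative rolled area (" * mu * m^2 * ")"),
                 ...)
  if (!is.null(fit)) {
    graphics::lines(trace@times, fit@fitted, col = "red", lwd = 2)
    graphics::abline(v = fit@onsetTime, lty = 3)
    graphics::mtext(sprintf("tau = %.2f s", fit@tau), side = 3, adj = 1)
  }
  invisible(trace)
}

#' Plot a rolled-length parameter sweep
#'
#' Rolled length against the sweep factor on a log y-axis, with the
#' resolution limit and the critical factor marked.
#'
#' @param sweep a [SweepResult-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotSweep <- function(sweep, ...) {
  L <- pmax(sweep@rolledLengths, sweep@resolutionLimit / 50)
  graphics::plot(sweep@factors, L * 1e6, type = "b", log = "y", pch = 16,
                 xlab = sprintf("%s factor", sweep@parameter),
                 ylab = expression("rolled length L* (" * mu * "m)"), ...)
  graphics::abline(h = sweep@resolutionLimit * 1e6, lty = 2, col = "grey40")
  if (!is.na(sweep@criticalFactor))
    graphics::abline(v = sweep@criticalFactor, lty = 3, col = "red")
  invisible(sweep)
}

#' Heat map of a curvature field or height map
#'
#' @param object a [CurvatureField-class], [MidplaneSurface-class] or
#'   [HeightMap-class].
#' @param ... passed to [graphics::image()].
#' @export
plotField <- function(object, ...) {
  m <- if (is(object, "CurvatureField")) object@meanCurvature
       else if (is(object, "MidplaneSurface")) object@grid
       else heights(object)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "x (cells)", ylab = "y (cells)", useRaster = TRUE,
                  ...)
  invisible(object)
}

#' Plot a multi-channel line profile
#'
#' @param profile a [LineProfile-class].
#' @param ... passed to [graphics::matplot()].
#' @export
plotLineProfile <- function(profile, ...) {
  graphics::matplot(profile@positions, profile@intensities, type = "l",
                    lty = 1, lwd = 2, xlab = expression("position (" * mu * "m)"),
                    ylab = "normalized intensity", ...)
  graphics::legend("topright", colnames(profile@intensities), lty = 1,
                   lwd = 2, col = seq_len(ncol(profile@intensities)))
  for (p in profile@peaks) if (is.finite(p)) graphics::abline(v = p, lty = 3)
  invisible(profile)
}
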