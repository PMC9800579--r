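## Rolling/unrolling kinetics from time-lapse image stacks.
##
## Rolling consumes patch area, so rolled membrane shows up as intensity
## LOSS in the membrane-dye channel between consecutive frames. The loss
## map (previous - current, clipped at 0) is binarized at a cutoff and the
## positive pixels counted; the running sum of the incremental areas is
## fitted with a 3-parameter logistic to extract the rolling time constant.

## pull the single dye-channel 3D array out of a stack
dyeChannel <- function(stack, channel = 1L) {
  f <- stack@frames
  if (length(dim(f)) == 4L) f[, , channel, , drop = TRUE] else f
}

## background statistics from a border margin of a (difference) image
borderStats <- function(m, margin = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  margin <- min(margin, floor(nr / 4), floor(nc / 4))
  border <- c(m[seq_len(margin), ], m[seq(nr - margin + 1L, nr), ],
              m[, seq_len(margin)], m[, seq(nc - margin + 1L, nc)])
  c(mean = mean(border), sd = stats::sd(border))
}

## drift check between first and last frame by whole-pixel cross-correlation
## (FFT phase correlation); warns when the shift exceeds 2 px
checkDrift <- function(first, last, maxShift = 2) {
  X <- fft(first - mean(first)); Y <- fft(last - mean(last))
  cc <- Re(fft(X * Conj(Y), inverse = TRUE))
  idx <- arrayInd(which.max(cc), dim(cc)) - 1L
  shift <- ifelse(idx > dim(cc) / 2, idx - dim(cc), idx)
  if (any(abs(shift) > maxShift))
    warning(sprintf("apparent frame drift of (%d, %d) px; traces assume a static patch",
                    shift[1], shift[2]))
  invisible(shift)
}

#' Incremental and cumulative rolled area from a time-lapse stack
#'
#' For each consecutive frame pair the binarized dye-intensity loss map
#' (previous minus current, clipped at 0) marks the pixels newly consumed by
#' rolling; the incremental rolled area is their count times the pixel area,
#' and the cumulative area its running sum. Each frame is binarized at the
#' cutoff first and the binary frames subtracted, which makes the loss map
#' robust to shot noise even when the front advances less than a pixel per
#' frame: patch-presence masks are large contiguous blobs, so a 3x3 median
#' filter removes isolated threshold flickers from them without eroding the
#' thin consumed arcs of the mask difference. With `cutoff = "auto"` the
#' threshold is Otsu's threshold of the first frame (midway between the
#' background and dye modes).
#'
#' @param stack a [FrameStack-class]; the first channel is taken as the
#'   membrane dye.
#' @param cutoff "auto" or an absolute intensity threshold separating dye
#'   from background.
#' @param medianFilter apply a 3x3 median filter to each binarized frame
#'   before differencing (recommended whenever the stack is noisy).
#' @param minSpeckle smallest connected component (px) of the loss map
#'   counted as rolled membrane; 0 (default) keeps everything, since
#'   sub-pixel front advances legitimately produce fragmented arcs.
#' @param roi optional rectangle `c(row1, row2, col1, col2)` restricting the
#'   analysis to one patch; default is the whole frame.
#' @param driftCheck cross-correlate first and last frame and warn when the
#'   apparent shift exceeds 2 px.
#' @param monotone treat rolling as irreversible: the patch mask can only
#'   shrink, so a pixel, once consumed, is never re-counted when noise
#'   flickers it back above the cutoff. Disable for processes that regrow
#'   area.
#' @return A [RollingTrace-class]. Times are frame times of the *later*
#'   frame of each pair, starting at one frame interval.
#' @export
incrementalRolledArea <- function(stack, cutoff = "auto",
                                  medianFilter = TRUE, minSpeckle = 0L,
                                  roi = NULL, driftCheck = FALSE,
                                  monotone = TRUE) {
  stopifnot(is(stack, "FrameStack"))
  f <- dyeChannel(stack)
  if (!is.null(roi)) f <- f[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  n <- dim(f)[3]
  if (driftCheck) checkDrift(f[, , 1], f[, , n])
  thr <- if (identical(cutoff, "auto")) otsuThreshold(as.vector(f[, , 1]))
         else cutoff
  prev <- f[, , 1] > thr
  if (medianFilter) prev <- binaryMedian3x3(prev)
  inc <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    cur <- f[, , i + 1L] > thr
    if (medianFilter) cur <- binaryMedian3x3(cur)
    if (monotone) cur <- cur & prev
    mask <- prev & !cur                       # binarized loss map
    if (minSpeckle > 0L && any(mask)) {
      lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
      sizes <- tabulate(as.integer(EBImage::imageData(lab)))
      mask <- matrix(as.integer(EBImage::imageData(lab)) %in%
                       which(sizes >= minSpeckle), nrow(mask), ncol(mask))
    }
    inc[i] <- sum(mask) * stack@pixelSize^2
    prev <- cur
  }
  new("RollingTrace",
      times = seq_len(n - 1L) * stack@frameInterval,
      incrementalArea = inc, cumulativeArea = cumsum(inc))
}

#' Fit a logistic to a cumulative rolled-area trace
#'
#' Least-squares fit of \eqn{A / (1 + \exp(-(t - t_0)/\tau))} to the
#' cumulative area, which yields the rolling time constant \eqn{\tau}.
#' Starting values come from the trace itself: A from the maximum, t0 from
#' the half-maximum crossing, tau from the 20--80\% rise time divided by
#' 2.2 (the logistic's 20--80 rise is \eqn{2\ln 4 \approx 2.77} tau; the
#' slight underestimate is a robust starting point). The fit uses
#' Levenberg--Marquardt least squares. The onset time is the first trace
#' time at which the cumulative area exceeds `onsetFraction` of the fitted
#' A (linearly interpolated between frames).
#'
#' @param trace a [RollingTrace-class], or a list with elements `times` and
#'   `cumulative` (the latter need not be monotone, e.g. a trace with
#'   measurement noise added).
#' @param onsetFraction fraction of the fitted amplitude defining rolling
#'   onset (default 0.05).
#' @return A [LogisticFit-class].
#' @section Errors: a flat trace, or a non-convergent fit, raises a
#'   condition of class `patchRoll_fitFailure` carrying diagnostics
#'   (`$diagnostics`), never a silent default.
#' @export
fitLogistic <- function(trace, onsetFraction = 0.05) {
  if (is(trace, "RollingTrace")) {
    t <- trace@times; y <- trace@cumulativeArea
  } else if (is.list(trace) && all(c("times", "cumulative") %in% names(trace))) {
    t <- trace$times; y <- trace$cumulative
  } else stop("trace must be a RollingTrace or a list(times, cumulative)")
  if (max(y) <= min(y) || max(y) <= 0)
    fitFailure("cumulative area spans no rise; nothing to fit",
               diagnostics = list(range = range(y)))
  A0 <- max(y)
  t20 <- t[which(y >= 0.2 * A0)[1]]
  t50 <- t[which(y >= 0.5 * A0)[1]]
  t80 <- t[which(y >= 0.8 * A0)[1]]
  tau0 <- max((t80 - t20) / 2.2, diff(range(t)) / 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + exp(-(t - t0) / tau)),
                      start = list(A = A0, t0 = t50, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      fitFailure(paste("logistic fit did not converge:",
                       conditionMessage(e)),
                 diagnostics = list(start = c(A = A0, t0 = t50, tau = tau0))))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf["tau"] <= 0 || cf["A"] <= 0)
    fitFailure("logistic fit converged to non-physical parameters",
               diagnostics = list(coef = cf))
  fitted <- cf["A"] / (1 + exp(-(t - cf["t0"]) / cf["tau"]))
  ## onset: first crossing of onsetFraction * A, interpolated
  thr <- onsetFraction * cf[["A"]]
  onset <- if (y[1] >= thr) t[1] else if (max(y) < thr) NA_real_ else {
    i <- which(y >= thr)[1]
    t[i - 1] + (t[i] - t[i - 1]) * (thr - y[i - 1]) / (y[i] - y[i - 1])
  }
  new("LogisticFit", tau = cf[["tau"]], t0 = cf[["t0"]],
      amplitude = cf[["A"]],
      onsetTime = min(onset, cf[["t0"]], na.rm = TRUE),
      fitResidual = sqrt(mean((y - fitted)^2)), fitted = as.numeric(fitted))
}

#' Relative area increase of an unrolling patch
#'
#' For a stack starting at the maximally rolled state, the patch area per
#' frame is the count of pixels above the cutoff times the pixel area, and
#' the relative area is area(t)/area(0). The trace is truncated at
#' `duration` (default 80 s). With `cutoff = "auto"` the threshold is the
#' midpoint between the background mode and the patch mode of the first
#' frame (Otsu's threshold).
#'
#' @param stack a [FrameStack-class] beginning at the maximally rolled state.
#' @param duration trace length, s.
#' @param cutoff "auto" or an absolute intensity threshold.
#' @return An [UnrollTrace-class].
#' @export
relativeAreaIncrease <- function(stack, duration = 80, cutoff = "auto") {
  stopifnot(is(stack, "FrameStack"))
  f <- dyeChannel(stack)
  n <- dim(f)[3]
  if (duration <= 0) stop("duration must be > 0")
  nKeep <- min(n, floor(duration / stack@frameInterval) + 1L)
  thr <- if (identical(cutoff, "auto")) otsuThreshold(as.vector(f[, , 1])) else cutoff
  area <- vapply(seq_len(nKeep), function(i) sum(f[, , i] > thr), numeric(1)) *
    stack@pixelSize^2
  if (area[1] <= 0)
    stop("zero patch area in the first frame; cannot normalize")
  new("UnrollTrace", times = (seq_len(nKeep) - 1L) * stack@frameInterval,
      relativeArea = area / area[1])
}

#' Intensity line profile across a patch edge
#'
#' Samples each channel along the segment from `a` to `b` (fractional pixel
#' coordinates, bilinear interpolation), averaging over `width` parallel
#' lines offset perpendicular to the segment. Each channel is min-max
#' normalized over the profile (a constant channel maps to 0). The peak
#' position per channel is the largest local maximum after 3-point
#' smoothing; a channel whose maximum does not exceed twice its profile
#' median is reported as having no isolated peak (NA), which is how a
#' uniformly distributed protein (no edge rim) is distinguished from an
#' edge-localized one.
#'
#' @param stack a [FrameStack-class] (single- or multi-channel).
#' @param frameIndex which frame to sample.
#' @param a,b segment endpoints as `c(row, col)` pixel coordinates.
#' @param width number of parallel lines averaged (odd; default 1).
#' @param nSamples samples along the segment; defaults to its pixel length.
#' @return A [LineProfile-class]; positions are micrometres from `a`.
#' @export
extractLineProfile <- function(stack, frameIndex, a, b, width = 1L,
                               nSamples = NULL) {
  stopifnot(is(stack, "FrameStack"))
  f <- stack@frames
  nd <- length(dim(f))
  dims <- dim(f)[1:2]
  if (any(a < 1) || any(b < 1) || any(a > dims) || any(b > dims))
    stop("segment endpoints must lie inside the frame")
  len <- sqrt(sum((b - a)^2))
  if (len < 1) stop("degenerate segment: endpoints coincide")
  if (is.null(nSamples)) nSamples <- max(2L, ceiling(len) + 1L)
  tfrac <- seq(0, 1, length.out = nSamples)
  dir <- (b - a) / len
  perp <- c(-dir[2], dir[1])
  offs <- seq_len(width) - (width + 1) / 2
  nCh <- if (nd == 4L) dim(f)[3] else 1L
  prof <- matrix(0, nSamples, nCh)
  for (ch in seq_len(nCh)) {
    m <- if (nd == 4L) f[, , ch, frameIndex] else f[, , frameIndex]
    acc <- numeric(nSamples)
    for (o in offs) {
      ri <- a[1] + tfrac * (b[1] - a[1]) + o * perp[1]
      ci <- a[2] + tfrac * (b[2] - a[2]) + o * perp[2]
      acc <- acc + bilinearSample(m, ri, ci)
    }
    prof[, ch] <- acc / length(offs)
  }
  colnames(prof) <- stack@channels
  raw <- prof
  for (ch in seq_len(nCh)) {
    rng <- range(prof[, ch])
    prof[, ch] <- if (diff(rng) < .Machine$double.eps) 0
                  else (prof[, ch] - rng[1]) / diff(rng)
  }
  positions <- tfrac * len * stack@pixelSize
  peaks <- vapply(seq_len(nCh), function(ch)
    profilePeak(positions, prof[, ch], raw[, ch]), numeric(1))
  names(peaks) <- stack@channels
  new("LineProfile", positions = positions, intensities = prof,
      peaks = peaks)
}

## largest local maximum after 3-point smoothing; NA when the channel's raw
## maximum fails the 2x-median isolation criterion
profilePeak <- function(pos, norm, raw) {
  if (all(norm == 0)) return(NA_real_)
  med <- stats::median(raw)
  if (med > 0 && max(raw) < 2 * med) return(NA_real_)
  s <- stats::filter(norm, rep(1 / 3, 3), sides = 2)
  s[1] <- norm[1]; s[length(s)] <- norm[length(norm)]
  n <- length(s)
  isMax <- c(FALSE, s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
             FALSE)
  if (!any(isMax)) return(pos[which.max(s)])
  cand <- which(isMax)
  pos[cand[which.max(s[cand])]]
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a two-sided p value, as used for comparing rolling time constants,
#' onset times and relative area increases between conditions. This is a
#' thin wrapper over [stats::t.test()] returning the three numbers directly.
#'
#' @param a,b numeric samples (each n >= 2, nonzero variance in at least
#'   one).
#' @return Named vector `c(statistic, p.value, df)`.
#' @examples
#' welchT(rnorm(8), rnorm(8, mean = 2))
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(c(statistic = 0, p.value = 1, df = NA_real_))
    stop("both samples have zero variance; t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(statistic = unname(ht$statistic), p.value = ht$p.value,
    df = unname(ht$parameter))
}
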