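## AFM height-map analysis: line flattening, 2D-FFT lattice period of
## close-packed trimer crystals, and bimodal height-domain segmentation.

#' Flatten an AFM height map
#'
#' Subtracts a per-scanline (row-wise) polynomial background of the given
#' order — the standard AFM line-flattening step that removes tilt (order 1)
#' and scanner bow (order 2) before spectral or threshold analysis. The
#' output has zero mean.
#'
#' @param map a [HeightMap-class].
#' @param order polynomial order, 0 (offset), 1 (tilt) or 2 (bow).
#' @return A flattened [HeightMap-class].
#' @export
planeFlatten <- function(map, order = 1L) {
  stopifnot(is(map, "HeightMap"))
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  H <- map@heights
  x <- seq_len(ncol(H))
  X <- stats::poly(x, degree = max(order, 1), raw = FALSE)
  X <- cbind(1, if (order >= 1) X[, seq_len(order), drop = FALSE])
  ## projection onto the per-row background space, applied to all rows at once
  P <- X %*% solve(crossprod(X), t(X))
  res <- H - H %*% t(P)
  res <- res - mean(res)
  heightMap(res, map@pixelSize)
}

## 2D Hann window (separable)
hann2d <- function(nr, nc) {
  wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  outer(wr, wc)
}

#' Lattice period from the 2D power spectrum
#'
#' Plane-flattens and Hann-windows the height map, locates the first-order
#' Bragg-like peak ring of the 2D power spectrum on the radially averaged
#' spectrum, and averages the period \eqn{2\pi/|q|} over all discrete
#' first-order peaks that exceed the radial background by at least 5 times
#' its local median absolute deviation. The search is restricted to periods
#' of 3--30 nm (the annexin-trimer scale). Because spectral power of an
#' uncorrelated surface is exponentially distributed (heavy upper tail), a
#' candidate peak must additionally exceed `peakFactor` times the radial
#' background; the largest order statistic of an exponential annulus stays
#' near `log(n)` times its mean, so the default factor of 20 rejects noise
#' maps decisively while true Bragg peaks exceed it by orders of magnitude.
#' At least 4 discrete peaks set the crystallinity flag; with fewer than
#' `minPeaks` peaks the period is returned as NA (an explicit sentinel)
#' with `crystallinity = FALSE`.
#'
#' For a hexagonal packing the reported period is the row (d-) spacing; the
#' lattice constant \eqn{a = 2 d / \sqrt{3}} is reported alongside.
#'
#' @param map a [HeightMap-class], at least 64 x 64 px.
#' @param periodRange search range of periods, nm.
#' @param minPeaks minimum number of discrete peaks for a period estimate.
#' @param peakFactor minimum ratio of peak power to the radial background.
#' @return A [LatticeResult-class].
#' @export
latticePeriod <- function(map, periodRange = c(3, 30), minPeaks = 2L,
                          peakFactor = 20) {
  stopifnot(is(map, "HeightMap"))
  H <- heights(planeFlatten(map, 1L))
  nr <- nrow(H); nc <- ncol(H)
  if (nr < 64L || nc < 64L) stop("height map must be at least 64 x 64 px")
  P <- Mod(stats::fft(H * hann2d(nr, nc)))^2
  ## angular spatial frequencies per FFT pixel, rad/nm
  qx <- 2 * pi * c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] /
    (nr * map@pixelSize)
  qy <- 2 * pi * c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] /
    (nc * map@pixelSize)
  Q <- sqrt(outer(qx^2, qy^2, `+`))
  dq <- 2 * pi / (max(nr, nc) * map@pixelSize)   # radial bin width
  bin <- pmax(1L, as.integer(round(Q / dq)) + 1L)
  ## radial background: median power per annulus (robust to the peaks)
  bg <- tapply(P, bin, stats::median)
  madr <- tapply(P, bin, stats::mad)
  inBand <- Q >= 2 * pi / periodRange[2] & Q <= 2 * pi / periodRange[1]
  lut <- match(bin, as.integer(names(bg)))
  bgv <- as.numeric(bg)[lut]; madv <- as.numeric(madr)[lut]
  excess <- P - bgv
  ok <- inBand & excess > 5 * pmax(madv, .Machine$double.eps) &
    P > peakFactor * bgv
  if (!any(ok))
    return(new("LatticeResult", period = NA_real_,
               latticeConstant = NA_real_,
               peakWavevectors = matrix(numeric(0), 0, 2),
               crystallinity = FALSE, binWidth = dq))
  ## first-order ring: the annulus holding the strongest accepted pixel.
  ## Within the validated ring the per-pixel criterion is relaxed (5 MADs
  ## plus a relative floor of a tenth of the ring maximum): a peak whose
  ## centre falls between grid pixels splits its power over neighbours and
  ## would fail the strict ratio test its on-grid partners pass.
  qRing <- Q[which.max(ifelse(ok, P, -Inf))]
  inRing <- abs(Q - qRing) <= 2.5 * dq
  pRingMax <- max(P[inRing])
  ring <- inRing & excess > 5 * pmax(madv, .Machine$double.eps) &
    P >= pRingMax / 10
  ## discrete peaks on the ring: greedy non-maximum suppression with a
  ## minimum angular separation of 20 degrees
  idx <- which(ring)
  idx <- idx[order(P[idx], decreasing = TRUE)]
  ang <- atan2(outer(rep(1, nr), qy)[idx], outer(qx, rep(1, nc))[idx])
  keep <- integer(0); keptAng <- numeric(0)
  for (k in seq_along(idx)) {
    sep <- abs(((ang[k] - keptAng + pi) %% (2 * pi)) - pi)
    if (!length(keptAng) || all(sep > 20 * pi / 180)) {
      keep <- c(keep, idx[k]); keptAng <- c(keptAng, ang[k])
    }
  }
  if (length(keep) < minPeaks)
    return(new("LatticeResult", period = NA_real_,
               latticeConstant = NA_real_,
               peakWavevectors = matrix(numeric(0), 0, 2),
               crystallinity = FALSE, binWidth = dq))
  ## refine each peak |q| by a power-weighted centroid over its 3x3 block
  qRef <- matrix(0, length(keep), 2)
  for (k in seq_along(keep)) {
    rc <- arrayInd(keep[k], c(nr, nc))
    ri <- ((rc[1] - 2):rc[1] %% nr) + 1L
    ci <- ((rc[2] - 2):rc[2] %% nc) + 1L
    blk <- P[ri, ci]
    qRef[k, 1] <- sum(blk * outer(qx[ri], rep(1, 3))) / sum(blk)
    qRef[k, 2] <- sum(blk * outer(rep(1, 3), qy[ci])) / sum(blk)
  }
  periods <- 2 * pi / sqrt(rowSums(qRef^2))
  d <- mean(periods)
  new("LatticeResult", period = d, latticeConstant = 2 * d / sqrt(3),
      peakWavevectors = qRef, crystallinity = length(keep) >= 4L,
      binWidth = dq)
}

## two-component 1D Gaussian fit of heights; deterministic sorted decimation
## keeps the EM affordable on large scans
fitHeightModes <- function(h, maxN = 20000L) {
  hs <- sort(h)
  if (length(hs) > maxN)
    hs <- hs[round(seq(1, length(hs), length.out = maxN))]
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(hs, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) return(NULL)
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1L) sd <- rep(sd, 2)
  o <- order(mu)
  list(mean = mu[o], sd = sd[o], pro = fit$parameters$pro[o])
}

## bimodality gate: kernel density must show two modes (each >= 1% of mass
## by peak prominence) with a valley below 80% of the lower mode
checkBimodal <- function(h, hist) {
  d <- stats::density(h, n = 512)
  y <- d$y; n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
             FALSE)
  peaks <- which(isMax & y > 0.01 * max(y))
  if (length(peaks) >= 2L) {
    peaks <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
    valley <- min(y[min(peaks):max(peaks)])
    if (valley < 0.8 * min(y[peaks])) return(invisible(TRUE))
  }
  segmentationFailure("height histogram is not bimodal", hist)
}

#' Segment an AFM scan into low and high height domains
#'
#' Checks that the height histogram is bimodal, chooses a threshold between
#' the two modes, and reports the percentage of analyzed area in each mode.
#' Bimodality is established on the kernel density of the heights: there
#' must be two modes, each holding at least 1\% of the mass, whose
#' connecting valley dips below 80\% of the lower of the two mode heights
#' (a plain shoulder does not qualify). Otherwise a condition of class
#' `patchRoll_segmentationFailure` is raised with the histogram attached.
#' The threshold is the midpoint between the means of a two-component
#' Gaussian fit of the height histogram; Otsu's threshold is the fallback
#' when the mixture fit fails.
#'
#' @param map a [HeightMap-class] (already flattened; see [planeFlatten()]).
#' @param mask optional logical matrix, TRUE for pixels to analyze
#'   (e.g. to exclude membrane defects).
#' @return A list with `labels` (matrix, "low"/"high"/NA outside the mask)
#'   and `fractions` (a [DomainFractions-class]).
#' @export
segmentHeightDomains <- function(map, mask = NULL) {
  stopifnot(is(map, "HeightMap"))
  H <- map@heights
  if (is.null(mask)) mask <- matrix(TRUE, nrow(H), ncol(H))
  h <- H[mask]
  hist <- graphics::hist(h, breaks = "FD", plot = FALSE)
  uh <- unique(h)
  if (length(uh) == 1L)
    segmentationFailure("uniform height map: no domains to segment", hist)
  if (length(uh) == 2L) {
    ## two exact levels (e.g. a noiseless checkerboard): threshold midway
    thr <- mean(uh)
  } else {
    checkBimodal(h, hist)
    modes <- fitHeightModes(h)
    thr <- if (is.null(modes)) otsuThreshold(h) else mean(modes$mean)
  }
  high <- H > thr
  labels <- matrix(NA_character_, nrow(H), ncol(H))
  labels[mask] <- ifelse(high[mask], "high", "low")
  nAnalyzed <- sum(mask)
  hf <- 100 * sum(high & mask) / nAnalyzed
  list(labels = labels,
       fractions = new("DomainFractions", lowFraction = 100 - hf,
                       highFraction = hf, threshold = thr))
}
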