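## Synthetic-data generators. Each returns the dataset plus a SyntheticTruth
## record that, with the seed, regenerates it bit-exactly. All randomness is
## local to the call (the global RNG state is untouched).

truthRecord <- function(kind, seed, ...) {
  new("SyntheticTruth", kind = kind, parameters = list(...),
      seed = as.integer(seed))
}

#' Generate a rolling movie with a logistic area schedule
#'
#' Renders a bright circular membrane patch on a dark background whose area
#' is consumed by rolling fronts advancing inward from seed points on the
#' free edge (circular-arc erosion). The cumulative consumed area follows
#' \eqn{A/(1+\exp(-(t-t_0)/\tau))} with \eqn{t_0} set so that the
#' 5\%-of-A crossing equals `onset`. Consumed pixels darken to background
#' and a bright 2-px roll rim leads each front; Gaussian noise is added
#' everywhere.
#'
#' Default geometry mirrors a typical epifluorescence setting: 10 frames/s
#' and 0.32 um/px on a 512 px field (a modest crop of a scientific-CMOS
#' sensor); `dim` and `frameInterval` are parameters, so long-time-constant
#' movies can be generated at a coarser frame interval.
#'
#' @param patchRadius patch radius, um.
#' @param tau rolling time constant, s.
#' @param onset rolling onset time (5\% of A consumed), s.
#' @param mode "uni" (one front) or "multi" (`nFronts` >= 2 fronts).
#' @param nFronts number of rolling fronts for `mode = "multi"`.
#' @param noiseSigma Gaussian noise SD as a fraction of the patch-background
#'   intensity contrast (the inverse of the SNR).
#' @param pixelSize um per pixel.
#' @param frameInterval s per frame.
#' @param nFrames number of frames; the default covers `t0 + 5 tau`.
#' @param dim frame side, px.
#' @param seed RNG seed.
#' @return `list(stack = FrameStack, truth = SyntheticTruth)`; the truth
#'   carries tau, onset, t0 and the exact patch area (amplitude, um^2).
#' @export
genRollingMovie <- function(patchRadius = 40, tau = 10, onset = 20,
                            mode = c("uni", "multi"), nFronts = 3L,
                            noiseSigma = 0.05, pixelSize = 0.32,
                            frameInterval = 0.1, nFrames = NULL,
                            dim = 512L, seed = 1L) {
  mode <- match.arg(mode)
  if (tau <= 0 || onset <= 0) stop("tau and onset must be > 0")
  if (mode == "multi" && nFronts < 2L) stop("mode 'multi' needs nFronts >= 2")
  if (mode == "uni") nFronts <- 1L
  ## t0 such that the rendered (renormalized) consumed fraction crosses 5%
  ## exactly at `onset`: fixed point of t0 = onset + tau ln(1/s - 1) with
  ## s = 0.05 (1 - s0) + s0, s0 = 1/(1 + exp(t0/tau))
  t0 <- onset + tau * log(19)
  for (k in 1:5) {
    s0 <- 1 / (1 + exp(t0 / tau))
    t0 <- onset + tau * log(1 / (0.05 * (1 - s0) + s0) - 1)
  }
  if (is.null(nFrames)) nFrames <- ceiling((t0 + 5 * tau) / frameInterval) + 1L
  span <- (nFrames - 1L) * frameInterval
  if (t0 > span)
    stop(sprintf("logistic mid-rise t0 = %.1f s falls outside the %.1f s movie span",
                 t0, span))
  rPx <- patchRadius / pixelSize
  if (2.2 * rPx > dim) stop("patch does not fit in the frame; increase dim")
  ctr <- (dim + 1) / 2
  xi <- matrix(seq_len(dim), dim, dim) - ctr
  yi <- t(xi)
  inPatch <- xi^2 + yi^2 <= rPx^2
  A <- sum(inPatch) * pixelSize^2            # exact rendered patch area
  withSeed(seed, {
    ## consumption order: distance to the nearest front seed on the edge
    thSeeds <- stats::runif(nFronts, 0, 2 * pi)
    dist2 <- Inf
    for (th in thSeeds) {
      sx <- rPx * cos(th); sy <- rPx * sin(th)
      dist2 <- pmin(dist2, (xi - sx)^2 + (yi - sy)^2)
    }
    rank <- sqrt(dist2)
    rank[!inPatch] <- Inf
    rankSorted <- sort(rank[inPatch])
    times <- (seq_len(nFrames) - 1L) * frameInterval
    sched <- 1 / (1 + exp(-(times - t0) / tau))
    sched <- (sched - sched[1]) / (1 - sched[1])   # consumed fraction, 0 at t = 0
    bg <- 0.1; fg <- 1.0
    frames <- array(0, c(dim, dim, nFrames))
    for (i in seq_len(nFrames)) {
      nCons <- floor(sched[i] * length(rankSorted))
      frame <- matrix(bg, dim, dim)
      if (nCons < length(rankSorted)) {
        cut <- rankSorted[nCons + 1L]
        alive <- inPatch & rank >= cut
        frame[alive] <- fg
        rim <- alive & rank < cut + 2
        frame[rim] <- fg * 1.8                      # bright leading roll rim
      }
      if (noiseSigma > 0)
        frame <- frame + stats::rnorm(dim * dim, 0, noiseSigma * (fg - bg))
      frames[, , i] <- frame
    }
  })
  stack <- frameStack(frames, pixelSize, frameInterval, channels = "dye")
  list(stack = stack,
       truth = truthRecord("movie", seed, tau = tau, onset = onset, t0 = t0,
                           amplitude_um2 = A, mode = mode, nFronts = nFronts,
                           frontAngles = thSeeds, patchRadius_um = patchRadius,
                           noiseSigma = noiseSigma, pixelSize_um = pixelSize,
                           frameInterval_s = frameInterval,
                           nFrames = nFrames, dim_px = dim))
}

#' Generate an unrolling movie with a linear area schedule
#'
#' A bright disc whose area grows linearly as
#' `area(t) = initialArea * (1 + growth * t)`; `growth = 0` models a fully
#' crosslinked patch that cannot unroll. Gaussian noise is added.
#'
#' @param initialArea patch area at t = 0, um^2.
#' @param growth relative area growth rate, 1/s (>= 0).
#' @param duration movie length, s.
#' @param noiseSigma noise SD as a fraction of the patch-background contrast.
#' @inheritParams genRollingMovie
#' @return `list(stack = FrameStack, truth = SyntheticTruth)`.
#' @export
genUnrollingMovie <- function(initialArea = 100, growth = 0.01,
                              duration = 80, noiseSigma = 0.05,
                              pixelSize = 0.32, frameInterval = 1,
                              dim = 256L, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (growth < 0) stop("growth must be >= 0 (unrolling only adds area)")
  nFrames <- floor(duration / frameInterval) + 1L
  times <- (seq_len(nFrames) - 1L) * frameInterval
  ctr <- (dim + 1) / 2
  xi <- matrix(seq_len(dim), dim, dim) - ctr
  yi <- t(xi)
  r2 <- xi^2 + yi^2
  bg <- 0.1; fg <- 1.0
  withSeed(seed, {
    frames <- array(0, c(dim, dim, nFrames))
    for (i in seq_len(nFrames)) {
      area <- initialArea * (1 + growth * times[i])
      rPx <- sqrt(area / pi) / pixelSize
      if (2 * rPx > dim) stop("patch outgrows the frame; increase dim")
      frame <- matrix(bg, dim, dim)
      frame[r2 <= rPx^2] <- fg
      if (noiseSigma > 0)
        frame <- frame + stats::rnorm(dim * dim, 0, noiseSigma * (fg - bg))
      frames[, , i] <- frame
    }
  })
  list(stack = frameStack(frames, pixelSize, frameInterval, channels = "dye"),
       truth = truthRecord("unroll", seed, initialArea_um2 = initialArea,
                           growth_per_s = growth, duration_s = duration,
                           noiseSigma = noiseSigma, pixelSize_um = pixelSize,
                           frameInterval_s = frameInterval, dim_px = dim))
}

#' Generate a synthetic AFM scan of a trimer crystal with height domains
#'
#' Gaussian bumps on a hexagonal lattice with the requested row spacing
#' model the close-packed trimer crystal; a second domain, laid out by
#' thresholded smoothed noise to occupy the requested area fraction, is
#' raised by `heightStep` (default 2.7 nm, the GFP height-differential
#' scale) and carries a randomized texture instead of the lattice.
#' Surface roughness is added everywhere.
#'
#' @param spacing lattice row spacing, nm (must exceed 3 pixels).
#' @param domainFractionHigh percent of the image in the raised domain
#'   (0 gives a pure crystal; 100 a pure raised domain).
#' @param heightStep height offset of the raised domain, nm.
#' @param roughness RMS surface roughness, nm.
#' @param pixelSize nm per pixel.
#' @param sizePx image side, px.
#' @param angle lattice rotation, radians.
#' @param tilt optional background plane `c(a, b)` adding `a x + b y` nm
#'   across the scan (tests the flattening path).
#' @param seed RNG seed.
#' @return `list(map = HeightMap, truth = SyntheticTruth)`.
#' @export
genAfmImage <- function(spacing = 9.08, domainFractionHigh = 0,
                        heightStep = 2.7, roughness = 0.1,
                        pixelSize = 0.5, sizePx = 256L, angle = 0,
                        tilt = c(0, 0), seed = 1L) {
  if (spacing <= 3 * pixelSize)
    stop("spacing must exceed 3 pixels for the lattice to be resolvable")
  if (domainFractionHigh < 0 || domainFractionHigh > 100)
    stop("domainFractionHigh must lie in [0, 100]")
  n <- sizePx
  x <- (matrix(seq_len(n), n, n) - 1) * pixelSize
  y <- t(x)
  ## rotate coordinates, then build the lattice as a sum of plane-wave
  ## cosines of a hexagonal packing (three rows of spacing d at 60 degrees);
  ## bump-like maxima appear at the lattice points
  ## hexagonal lattice of Gaussian bumps: row spacing = `spacing`, lattice
  ## constant a = 2 spacing / sqrt(3); bumps rendered additively within a
  ## 3-sigma window
  a <- 2 * spacing / sqrt(3)
  ext <- n * pixelSize
  R <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  kmax <- ceiling(1.6 * ext / a) + 2L
  ij <- expand.grid(i = -kmax:kmax, j = -kmax:kmax)
  pts <- cbind(ij$i * a + ij$j * a / 2, ij$j * a * sqrt(3) / 2) %*% t(R)
  pts <- sweep(pts, 2, c(ext / 2, ext / 2), `+`)
  bumpSigma <- spacing / 4
  win <- ceiling(3 * bumpSigma / pixelSize)
  keep <- pts[, 1] > -3 * bumpSigma & pts[, 1] < ext + 3 * bumpSigma &
          pts[, 2] > -3 * bumpSigma & pts[, 2] < ext + 3 * bumpSigma
  pts <- pts[keep, , drop = FALSE]
  lattice <- matrix(0, n, n)
  ax1 <- (seq_len(n) - 1) * pixelSize
  for (p in seq_len(nrow(pts))) {
    ic <- round(pts[p, 1] / pixelSize) + 1
    jc <- round(pts[p, 2] / pixelSize) + 1
    if (ic + win < 1 || ic - win > n || jc + win < 1 || jc - win > n) next
    ii <- max(1, ic - win):min(n, ic + win)
    jj <- max(1, jc - win):min(n, jc + win)
    lattice[ii, jj] <- lattice[ii, jj] +
      outer(exp(-(ax1[ii] - pts[p, 1])^2 / (2 * bumpSigma^2)),
            exp(-(ax1[jj] - pts[p, 2])^2 / (2 * bumpSigma^2)))
  }
  lattice <- lattice - mean(lattice)   # ~1 nm bump amplitude, zero mean
  withSeed(seed, {
    H <- lattice
    highMask <- matrix(FALSE, n, n)
    if (domainFractionHigh > 0) {
      blob <- periodicGaussianSmooth(matrix(stats::rnorm(n * n), n, n),
                                     sigma = n / 16)
      thr <- stats::quantile(blob, 1 - domainFractionHigh / 100)
      highMask <- blob > thr
      texture <- periodicGaussianSmooth(matrix(stats::rnorm(n * n), n, n), 2)
      texture <- 0.3 * texture / stats::sd(texture)
      H[highMask] <- heightStep + texture[highMask]
    }
    if (roughness > 0) H <- H + stats::rnorm(n * n, 0, roughness)
    H <- H + tilt[1] * x + tilt[2] * y
  })
  list(map = heightMap(H, pixelSize),
       truth = truthRecord("afm", seed, spacing_nm = spacing,
                           domainFractionHigh = 100 * mean(highMask),
                           requestedFractionHigh = domainFractionHigh,
                           heightStep_nm = heightStep, roughness_nm = roughness,
                           pixelSize_nm = pixelSize, sizePx = n,
                           angle_rad = angle, tilt = tilt))
}

## analytic surfaces for membrane frames; each returns list(f, fx, fy)
## evaluated at (x, y) with the origin at the box centre
analyticSurface <- function(spec) {
  type <- spec$type
  if (type == "flat") {
    list(f = function(x, y) 0 * x, name = "flat")
  } else if (type == "sphere-cap") {
    ## spherical dome of radius R truncated at rhoMax (slope 0.75 at the
    ## default rhoMax = 0.6 R), continuous with the flat surround
    R <- spec$R
    rhoMax <- if (!is.null(spec$rhoMax)) spec$rhoMax else 0.6 * R
    zEdge <- sqrt(R^2 - rhoMax^2)
    list(f = function(x, y) {
      rho2 <- x^2 + y^2
      ifelse(rho2 < rhoMax^2, sqrt(pmax(R^2 - rho2, 0)) - zEdge, 0)
    }, name = "sphere-cap", R = R, rhoMax = rhoMax)
  } else if (type == "gaussian-dimple") {
    A <- spec$A; s <- spec$sigma
    list(f = function(x, y) -A * exp(-(x^2 + y^2) / (2 * s^2)),
         name = "gaussian-dimple", A = A, sigma = s)
  } else stop("unknown surface type: ", type)
}

#' Generate a lipid-particle frame sampling an analytic midplane
#'
#' Particles are placed uniformly in x, y over the periodic box and at
#' `z = f(x, y) +/- thickness/2` plus Gaussian z-noise, with leaflet labels.
#' The truth record carries the surface specification, from which the
#' closed-form mean curvature is available for validation.
#'
#' @param surface surface spec: `list(type = "flat")`,
#'   `list(type = "sphere-cap", R = )` (R in nm; the cap is truncated where
#'   its slope reaches 1) or `list(type = "gaussian-dimple", A = , sigma = )`.
#' @param box periodic box lengths (x, y), nm.
#' @param nPerLeaflet particles per leaflet (>= 100).
#' @param thickness bilayer thickness, nm.
#' @param zNoise Gaussian z-noise SD, nm (lipid-protrusion scale ~0.2 nm).
#' @param seed RNG seed.
#' @return `list(frame = ParticleFrame, truth = SyntheticTruth)`.
#' @export
genMembraneFrame <- function(surface = list(type = "flat"),
                             box = c(40, 40), nPerLeaflet = 2000L,
                             thickness = 4, zNoise = 0, seed = 1L) {
  if (nPerLeaflet < 100L) stop("need at least 100 particles per leaflet")
  surf <- analyticSurface(surface)
  ## Monge sampling requires modest slopes: check on a probe grid
  px <- seq(-box[1] / 2, box[1] / 2, length.out = 64)
  pg <- expand.grid(x = px, y = px)
  eps <- 1e-4
  gx <- (surf$f(pg$x + eps, pg$y) - surf$f(pg$x - eps, pg$y)) / (2 * eps)
  gy <- (surf$f(pg$x, pg$y + eps) - surf$f(pg$x, pg$y - eps)) / (2 * eps)
  if (max(sqrt(gx^2 + gy^2)) > 1)
    stop("surface slope exceeds 1; too steep for Monge-gauge sampling")
  withSeed(seed, {
    n <- 2L * nPerLeaflet
    x <- stats::runif(n, 0, box[1])
    y <- stats::runif(n, 0, box[2])
    z0 <- surf$f(x - box[1] / 2, y - box[2] / 2)
    leaflet <- rep(c("upper", "lower"), each = nPerLeaflet)
    z <- z0 + ifelse(leaflet == "upper", thickness / 2, -thickness / 2)
    if (zNoise > 0) z <- z + stats::rnorm(n, 0, zNoise)
  })
  frame <- particleFrame(cbind(x, y, z), leaflet, box)
  list(frame = frame,
       truth = truthRecord("membrane", seed, surface = surface,
                           box_nm = box, nPerLeaflet = nPerLeaflet,
                           thickness_nm = thickness, zNoise_nm = zNoise))
}
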