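## Helfrich spiral rolling-energetics model.
##
## The rolled patch is modelled as an Archimedean spiral
##   r(theta) = r0 + (b / 2 pi) * theta,
## rolled length L measured as arclength from the inner end. Per unit roll
## width, the energy difference between the rolled and flat states is
##
##   dE(L) = int_0^L [ (kc/2) * ((1/r(s) - c0)^2 - c0^2) + wad ] ds
##
## - the rolled membrane relaxes its c0-frustration (gain relative to the
## flat state, where the bending energy density is (kc/2) c0^2) but pays the
## adhesion energy wad it loses by detaching from the support. Rolling stops
## where the integrand turns non-negative (marginal condition), which gives
## the equilibrium rolled length L*.

## exact arclength of the spiral from r0 to r; a = b/(2 pi)
spiralArclengthExact <- function(r, r0, b) {
  a <- b / (2 * pi)
  Fr <- function(r) (r * sqrt(r^2 + a^2) + a^2 * asinh(r / a)) / (2 * a)
  Fr(r) - Fr(r0)
}

## thin-pitch approximation L ~ pi (r^2 - r0^2) / b and its inverse
spiralArclengthApprox <- function(r, r0, b) pi * (r^2 - r0^2) / b
spiralRadiusApprox <- function(s, r0, b) sqrt(r0^2 + b * s / pi)

## invert the exact arclength: r(s), vectorized Newton from the thin-pitch
## start (ds/dr = sqrt(r^2 + a^2) / a)
spiralRadiusExact <- function(s, r0, b) {
  a <- b / (2 * pi)
  r <- spiralRadiusApprox(s, r0, b)
  for (i in 1:50) {
    delta <- (spiralArclengthExact(r, r0, b) - s) * a / sqrt(r^2 + a^2)
    r <- r - delta
    if (max(abs(delta)) < 1e-12 * max(r0, max(r))) break
  }
  r
}

## integrand g(s) expressed through r
rollIntegrand <- function(r, params) {
  (params@kc / 2) * ((1 / r - params@c0)^2 - params@c0^2) + params@wad
}

#' Rolling energy profile dE(L)
#'
#' Computes the energy difference per unit roll width between the rolled and
#' flat states on a uniform grid of rolled lengths, by trapezoidal
#' quadrature of the Helfrich integrand along the roll spiral (see the
#' package vignette for the model). The quadrature error vanishes as
#' `nPoints` grows.
#'
#' @param params a [RollModelParams-class] object.
#' @param lMax largest rolled length on the grid, m.
#' @param nPoints number of grid points (>= 2).
#' @param mapping "exact" inverts the closed-form spiral arclength; the
#'   "thin-pitch" fast path uses \eqn{L \approx \pi (r^2 - r_0^2)/b}, which
#'   agrees with the exact mapping to well below 1\% at the reference pitch.
#' @return An [EnergyProfile-class] with `dE(0) = 0`.
#' @examples
#' ep <- energyProfile(rollModelParams(), lMax = 2e-4, nPoints = 2001)
#' plot(as.data.frame(ep), type = "l")
#' @export
energyProfile <- function(params, lMax, nPoints = 1000L,
                          mapping = c("exact", "thin-pitch")) {
  stopifnot(is(params, "RollModelParams"))
  mapping <- match.arg(mapping)
  if (!is.finite(lMax) || lMax <= 0) stop("lMax must be finite and > 0")
  if (nPoints < 2L) stop("nPoints must be >= 2")
  L <- seq(0, lMax, length.out = nPoints)
  r <- if (mapping == "exact") spiralRadiusExact(L, params@r0, params@b)
       else spiralRadiusApprox(L, params@r0, params@b)
  g <- rollIntegrand(r, params)
  dE <- cumtrapz(L, g)
  new("EnergyProfile", lengths = L, energyPerWidth = dE)
}

## dE between arclengths via adaptive quadrature in r (used when the
## integrand starts positive and the global minimum must be compared to 0)
energyBetween <- function(params, r1, r2) {
  a <- params@b / (2 * pi)
  stats::integrate(function(r) rollIntegrand(r, params) * sqrt(r^2 + a^2) / a,
                   r1, r2, rel.tol = 1e-10)$value
}

#' Equilibrium rolled length L*
#'
#' Minimizes the rolling energy `dE(L)` over L >= 0. Because the integrand
#' is monotone in the local curvature `1/r(s)`, the minimizer is where the
#' integrand first turns non-negative: the marginal condition
#' \eqn{(k_c/2)(c_0^2 - (1/r - c_0)^2) = w_{ad}}. Rolling is never
#' favourable (L* = 0) when \eqn{w_{ad} \ge (k_c/2) c_0^2}, or when the
#' innermost turn is already too wide to enter the favourable curvature
#' band. Values below the optical resolution limit are returned as-is;
#' classifying them as "no rolling" is the caller's concern.
#'
#' @inheritParams energyProfile
#' @param resolutionLimit optical resolution limit, m (carried for the
#'   caller's classification; does not alter the returned value).
#' @return Rolled length L*, m (0 when rolling is unfavourable).
#' @export
rolledLength <- function(params, resolutionLimit = 1e-6) {
  stopifnot(is(params, "RollModelParams"))
  D <- params@c0^2 - 2 * params@wad / params@kc
  if (D <= 0) return(0)
  uStop <- params@c0 - sqrt(D)       # lower edge of the favourable 1/r band
  uHigh <- params@c0 + sqrt(D)
  u0 <- 1 / params@r0
  if (u0 <= uStop) return(0)         # spiral starts below the band, g >= 0
  rStop <- 1 / uStop
  if (u0 <= uHigh)                   # favourable from s = 0
    return(spiralArclengthExact(rStop, params@r0, params@b))
  ## integrand starts positive (r0 tighter than the favourable band):
  ## compare dE at the late minimum with the unrolled state
  dE <- energyBetween(params, params@r0, rStop)
  if (dE < 0) spiralArclengthExact(rStop, params@r0, params@b) else 0
}

## shared sweep machinery: L* as a function of a multiplier, plus bisection
## refinement of the factor at which L* crosses the resolution limit
sweepCore <- function(lengthAt, factors, resolutionLimit, which) {
  L <- vapply(factors, lengthAt, numeric(1))
  below <- L <= resolutionLimit
  crit <- NA_real_
  ## scan in the direction of increasing factor for "adhesion" (smallest
  ## factor below limit), decreasing fraction for "curvature" (largest
  ## fraction below limit); in both orderings L* decreases along the scan
  ord <- if (which == "adhesion") order(factors) else order(-factors)
  Lo <- L[ord]; fo <- factors[ord]; bo <- below[ord]
  i <- which(bo)[1]
  if (!is.na(i) && i > 1) {
    crit <- stats::uniroot(function(f) lengthAt(f) - resolutionLimit,
                           lower = min(fo[i - 1], fo[i]),
                           upper = max(fo[i - 1], fo[i]),
                           tol = 1e-9)$root
  } else if (!is.na(i) && i == 1 && Lo[1] == resolutionLimit) {
    crit <- fo[1]
  }
  list(L = L, crit = crit)
}

#' Sweep the adhesion energy
#'
#' Recomputes the equilibrium rolled length with the adhesion energy
#' multiplied by each factor (modelling progressively stronger crosslinking
#' of the patch to the support), and locates the critical factor at which
#' L* first falls to the resolution limit by bisection between the
#' bracketing sweep points.
#'
#' @inheritParams rolledLength
#' @param factors positive, strictly monotone multipliers applied to
#'   `params@wad`.
#' @param resolutionLimit rolled length regarded as "no rolling", m
#'   (default 1 micrometre).
#' @return A [SweepResult-class]; `criticalFactor` is NA when no sweep pair
#'   brackets the crossing.
#' @examples
#' sw <- sweepAdhesion(rollModelParams(), factors = seq(1, 10, by = 0.5))
#' criticalFactor(sw)
#' @export
sweepAdhesion <- function(params, factors, resolutionLimit = 1e-6) {
  stopifnot(is(params, "RollModelParams"))
  if (!length(factors)) stop("factors must be non-empty")
  if (any(factors <= 0)) stop("factors must be positive")
  lengthAt <- function(f) {
    p <- params; p@wad <- params@wad * f
    rolledLength(p)
  }
  res <- sweepCore(lengthAt, factors, resolutionLimit, "adhesion")
  new("SweepResult", factors = factors, rolledLengths = res$L,
      criticalFactor = res$crit, parameter = "adhesion",
      resolutionLimit = resolutionLimit)
}

#' Sweep the spontaneous curvature downward
#'
#' Recomputes the equilibrium rolled length with the spontaneous curvature
#' multiplied by each fraction <= 1 (modelling a lower surface density of
#' curvature-inducing protein), and locates the largest fraction at which
#' L* is at the resolution limit. The reported `criticalFactor` is the
#' fraction of the reference `c0`; the percent reduction is
#' `100 * (1 - criticalFactor)`.
#'
#' @inheritParams sweepAdhesion
#' @param fractions strictly monotone multipliers in (0, 1] applied to
#'   `params@c0`.
#' @param r0Convention with "follow_c0" (default) the inner radius is reset
#'   to `1/(c0 * fraction)` so the innermost turn stays at the spontaneous
#'   radius; "fixed" keeps `params@r0`.
#' @return A [SweepResult-class].
#' @export
sweepSpontaneousCurvature <- function(params, fractions,
                                      resolutionLimit = 1e-6,
                                      r0Convention = c("follow_c0", "fixed")) {
  stopifnot(is(params, "RollModelParams"))
  r0Convention <- match.arg(r0Convention)
  if (!length(fractions)) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  lengthAt <- function(f) {
    p <- params; p@c0 <- params@c0 * f
    if (r0Convention == "follow_c0") p@r0 <- 1 / p@c0
    rolledLength(p)
  }
  res <- sweepCore(lengthAt, fractions, resolutionLimit, "curvature")
  new("SweepResult", factors = fractions, rolledLengths = res$L,
      criticalFactor = res$crit, parameter = "curvature",
      resolutionLimit = resolutionLimit)
}
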