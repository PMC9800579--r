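## Internal helpers: condition classes, quadrature, periodic grid ops.

## Conditions with data attached, so callers can inspect diagnostics instead
## of parsing messages.
fitFailure <- function(message, diagnostics = list()) {
  stop(structure(class = c("patchRoll_fitFailure", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

segmentationFailure <- function(message, histogram = NULL) {
  stop(structure(class = c("patchRoll_segmentationFailure", "error",
                           "condition"),
                 list(message = message, call = sys.call(-1),
                      histogram = histogram)))
}

## cumulative trapezoid on a uniform or non-uniform grid
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n) * 0)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

## run code with a local RNG state seeded from `seed`; global .Random.seed
## is untouched
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## circular shift of a matrix by (di, dj); positive shifts move content down/right
cshift <- function(m, di = 0L, dj = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  i <- ((seq_len(nr) - 1L - di) %% nr) + 1L
  j <- ((seq_len(nc) - 1L - dj) %% nc) + 1L
  m[i, j, drop = FALSE]
}

## periodic Gaussian smoothing of a matrix via FFT (sigma in cells)
periodicGaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fi <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  fj <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  gi <- exp(-2 * pi^2 * sigma^2 * fi^2)
  gj <- exp(-2 * pi^2 * sigma^2 * fj^2)
  ker <- outer(gi, gj)
  Re(fft(fft(m) * ker, inverse = TRUE)) / (nr * nc)
}

## zero-padded (non-periodic) shift of a matrix
shiftPad <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

## 3x3 median of a binary (logical/0-1) matrix: >= 5 of the 9 neighbours set
## (edges zero-padded); vectorized matrix shifts, no per-pixel loop
binaryMedian3x3 <- function(m) {
  m <- m * 1
  acc <- m
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) acc <- acc + shiftPad(m, di, dj)
  acc >= 5
}

## bilinear sampling of matrix `m` at fractional (row, col) coordinates
bilinearSample <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(ri, 1), nr)
  ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

## Otsu threshold on a numeric vector (EBImage::otsu needs an Image in [0,1])
otsuThreshold <- function(x) {
  lo <- min(x); hi <- max(x)
  img <- EBImage::Image(matrix((x - lo) / (hi - lo), nrow = 1))
  EBImage::otsu(img, range = c(0, 1)) * (hi - lo) + lo
}
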