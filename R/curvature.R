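## Membrane midplane fitting and Monge-gauge mean curvature from
## lipid-particle coordinates. x and y are periodic, z free; the grid rows
## index x cells and columns y cells.

#' Fit the membrane midplane surface to a particle frame
#'
#' Bins particles into an x-y grid and sets each cell's midplane height to
#' the mean of the upper-leaflet z and the lower-leaflet z means, halved
#' (i.e. the midpoint between the two leaflet surfaces). Cells empty in
#' either leaflet are filled by iterative periodic bilinear interpolation
#' from their neighbours and flagged.
#'
#' @param frame a [ParticleFrame-class].
#' @param cellSize lateral cell size, nm; choose it so the mean occupancy is
#'   at least ~2 particles per cell per leaflet.
#' @return A [MidplaneSurface-class].
#' @section Errors: when more than 20\% of cells are empty in a leaflet the
#'   grid is under-sampled and an error advises a larger `cellSize`.
#' @export
fitMidplane <- function(frame, cellSize) {
  stopifnot(is(frame, "ParticleFrame"))
  nx <- max(4L, round(frame@box[1] / cellSize))
  ny <- max(4L, round(frame@box[2] / cellSize))
  ## honour the periodic box exactly; the effective cell size is box/n
  csx <- frame@box[1] / nx; csy <- frame@box[2] / ny
  ix <- pmin(floor(frame@positions[, 1] / csx), nx - 1L) + 1L
  iy <- pmin(floor(frame@positions[, 2] / csy), ny - 1L) + 1L
  cell <- (iy - 1L) * nx + ix
  leafletMean <- function(which) {
    sel <- frame@leaflet == which
    s <- rowsum(frame@positions[sel, 3], cell[sel])
    n <- rowsum(rep(1, sum(sel)), cell[sel])
    out <- matrix(NA_real_, nx, ny)
    cnt <- matrix(0, nx, ny)
    idx <- as.integer(rownames(s))
    out[idx] <- s / n
    cnt[idx] <- n
    list(mean = out, count = cnt)
  }
  up <- leafletMean("upper"); lo <- leafletMean("lower")
  emptyFrac <- max(mean(up$count == 0), mean(lo$count == 0))
  if (emptyFrac > 0.2)
    stop(sprintf(
      "a leaflet is empty in %.0f%% of cells; increase cellSize (grid %d x %d)",
      100 * emptyFrac, nx, ny))
  grid <- (up$mean + lo$mean) / 2
  filled <- is.na(grid)
  ## iterative periodic 4-neighbour fill for empty cells
  while (anyNA(grid)) {
    nb <- array(c(cshift(grid, 1, 0), cshift(grid, -1, 0),
                  cshift(grid, 0, 1), cshift(grid, 0, -1)),
                dim = c(nx, ny, 4))
    est <- apply(nb, c(1, 2), function(v) mean(v, na.rm = TRUE))
    fill <- is.na(grid) & !is.nan(est)
    if (!any(fill)) stop("cannot interpolate empty cells: no occupied neighbours")
    grid[fill] <- est[fill]
  }
  new("MidplaneSurface", grid = grid, cellSize = (csx + csy) / 2,
      occupancy = pmin(up$count, lo$count), filled = filled)
}

## periodic central differences along rows (x); spacing h
ddx <- function(m, h) (cshift(m, -1, 0) - cshift(m, 1, 0)) / (2 * h)
ddy <- function(m, h) (cshift(m, 0, -1) - cshift(m, 0, 1)) / (2 * h)

#' Mean-curvature field of a midplane surface in Monge gauge
#'
#' Computes
#' \deqn{H = \frac{(1+z_x^2) z_{yy} - 2 z_x z_y z_{xy} + (1+z_y^2) z_{xx}}
#'            {2 (1 + z_x^2 + z_y^2)^{3/2}}}
#' with derivatives by periodic central differences. The sign convention
#' takes the surface normal along +z (the protein-bound side), so a
#' membrane dimpling away from the protein has negative H; a flat surface
#' has H identically 0.
#'
#' An optional periodic Gaussian smooth (sigma in grid cells) is applied to
#' the surface before differentiation to suppress particle-protrusion
#' noise; it is on by default for measured frames and must be turned off
#' when validating against analytic surfaces.
#'
#' @param surface a [MidplaneSurface-class] (at least 8 x 8 cells).
#' @param smoothSigma Gaussian smoothing sigma in cells; 0 disables.
#' @return A [CurvatureField-class] in 1/nm.
#' @export
meanCurvatureField <- function(surface, smoothSigma = 1) {
  stopifnot(is(surface, "MidplaneSurface"))
  z <- surface@grid
  if (nrow(z) < 8L || ncol(z) < 8L) stop("surface grid must be at least 8 x 8")
  if (!all(is.finite(z))) stop("surface heights must be finite")
  if (smoothSigma > 0) z <- periodicGaussianSmooth(z, smoothSigma)
  h <- surface@cellSize
  zx <- ddx(z, h); zy <- ddy(z, h)
  zxx <- (cshift(z, -1, 0) - 2 * z + cshift(z, 1, 0)) / h^2
  zyy <- (cshift(z, 0, -1) - 2 * z + cshift(z, 0, 1)) / h^2
  zxy <- ddy(zx, h)
  H <- ((1 + zx^2) * zyy - 2 * zx * zy * zxy + (1 + zy^2) * zxx) /
    (2 * (1 + zx^2 + zy^2)^1.5)
  new("CurvatureField", meanCurvature = H, cellSize = h,
      signConvention = "normal along +z (protein-bound side); dimple away from protein has H < 0")
}

#' Mean curvature under a protein footprint, aggregated across frames
#'
#' Averages H over the footprint region in each frame (or replica), then
#' reports the across-frame mean and standard deviation. The scalar
#' reported is the arithmetic mean of H (signed); the same aggregation of
#' |H| is also returned for transparency. For replica-level statistics pass
#' one field per replica (e.g. each already time-averaged): the result is
#' then the mean of replica means with the SD across replica means.
#'
#' @param fields a [CurvatureField-class] or list of them (equal grids).
#' @param region the footprint: a logical matrix matching the grid, or a
#'   rectangle `c(row1, row2, col1, col2)` of grid-cell indices.
#' @return A [FootprintStat-class].
#' @export
footprintMeanCurvature <- function(fields, region) {
  if (is(fields, "CurvatureField")) fields <- list(fields)
  stopifnot(length(fields) >= 1L, all(vapply(fields, is, logical(1),
                                             "CurvatureField")))
  dims <- dim(fields[[1]]@meanCurvature)
  if (is.matrix(region)) {
    if (!all(dim(region) == dims)) stop("region mask must match the grid")
    sel <- which(region != 0)
  } else {
    sel <- as.vector(outer(region[1]:region[2],
                           (region[3]:region[4] - 1) * dims[1], `+`))
  }
  if (!length(sel)) stop("footprint region is empty")
  perFrame <- vapply(fields, function(f) mean(f@meanCurvature[sel]),
                     numeric(1))
  perFrameAbs <- vapply(fields, function(f) mean(abs(f@meanCurvature[sel])),
                        numeric(1))
  new("FootprintStat", meanH = mean(perFrame),
      sdAcrossFrames = if (length(perFrame) > 1) stats::sd(perFrame) else 0,
      meanAbsH = mean(perFrameAbs), perFrame = perFrame,
      nFrames = length(fields), nCells = length(sel))
}
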