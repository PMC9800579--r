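#' Construct rolling-model parameters
#'
#' Two presets ship with the package, differing only in the bending modulus:
#' \describe{
#'   \item{"results"}{\eqn{k_c = 1.0\times10^{-19}} J (default).}
#'   \item{"methods"}{\eqn{k_c = 4.0\times10^{-20}} J.}
#' }
#' Both use \eqn{c_0 = 3.33\times10^{7}} m\eqn{^{-1}},
#' \eqn{w_{ad} = 1.0\times10^{-5}} J/m\eqn{^2}, pitch \eqn{b = 2.1} nm and
#' inner radius \eqn{r_0 = 1/c_0} (the innermost turn sits at the spontaneous
#' radius, so its local curvature frustration is zero). Any field can be
#' overridden. Note rolling is only favourable when
#' \eqn{w_{ad} < (k_c/2)\,c_0^2} (about \eqn{5.5\times10^{-5}} J/m^2 at the
#' reference \eqn{c_0}), which is why the adhesion energy reference is on the
#' 1e-5 scale.
#'
#' @param preset "results" or "methods" (see Details), or "custom".
#' @param kc bending modulus, J.
#' @param c0 spontaneous curvature, 1/m.
#' @param wad adhesion energy density, J/m^2.
#' @param b roll-spiral pitch per turn, m.
#' @param r0 innermost roll radius, m; defaults to 1/c0.
#' @return A [RollModelParams-class] object.
#' @examples
#' p <- rollModelParams()
#' rolledLength(p)  # ~ 1.5e-4 m at the reference parameterization
#' @export
rollModelParams <- function(preset = c("results", "methods", "custom"),
                            kc = NULL, c0 = 3.33e7, wad = 1.0e-5,
                            b = 2.1e-9, r0 = 1 / c0) {
  preset <- match.arg(preset)
  if (is.null(kc))
    kc <- switch(preset, results = 1.0e-19, methods = 4.0e-20,
                 custom = stop("preset 'custom' requires an explicit kc"))
  new("RollModelParams", kc = kc, c0 = c0, wad = wad, b = b, r0 = r0,
      preset = preset)
}

#' Construct a time-lapse frame stack
#'
#' @param frames 3D array `[row, col, frame]`, 4D array
#'   `[row, col, channel, frame]`, or a list of equally shaped matrices
#'   (one per frame, single channel).
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds per frame.
#' @param channels channel labels; defaults to "dye" for single-channel.
#' @return A [FrameStack-class] object.
#' @export
frameStack <- function(frames, pixelSize, frameInterval, channels = NULL) {
  if (is.list(frames)) {
    shp <- vapply(frames, dim, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
      stop("all frames must share the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shp[1, 1], shp[2, 1], length(frames)))
  }
  nd <- length(dim(frames))
  if (is.null(channels))
    channels <- if (nd == 4L) paste0("ch", seq_len(dim(frames)[3])) else "dye"
  new("FrameStack", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval, channels = channels)
}

#' Construct an AFM-style height map
#'
#' @param heights matrix of heights, nm.
#' @param pixelSize nm per pixel.
#' @return A [HeightMap-class] object.
#' @export
heightMap <- function(heights, pixelSize) {
  new("HeightMap", heights = heights, pixelSize = pixelSize)
}

#' Construct a lipid-particle coordinate frame
#'
#' Coordinates are wrapped into the periodic box in x and y; z is free.
#'
#' @param positions n x 3 matrix of (x, y, z), nm.
#' @param leaflet character or factor of "upper"/"lower" labels; when NULL,
#'   leaflets are assigned by z relative to the global midplane.
#' @param box periodic box lengths (x, y), nm.
#' @return A [ParticleFrame-class] object.
#' @export
particleFrame <- function(positions, leaflet = NULL, box) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  positions[, 1] <- positions[, 1] %% box[1]
  positions[, 2] <- positions[, 2] %% box[2]
  if (is.null(leaflet)) {
    mid <- stats::median(positions[, 3])
    leaflet <- ifelse(positions[, 3] >= mid, "upper", "lower")
  }
  leaflet <- factor(as.character(leaflet), levels = c("lower", "upper"))
  new("ParticleFrame", positions = positions, leaflet = leaflet,
      box = as.numeric(box[1:2]))
}
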