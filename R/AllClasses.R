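#' @import methods
NULL

## Central S4 containers. Validity methods enforce the physical invariants
## (positivity, grid consistency, monotonicity) so downstream numerics can
## assume well-formed objects.

#' Physical parameters of the spiral rolling-length model
#'
#' Holds the constants of the Helfrich rolling-energetics model: the mean
#' curvature elastic modulus \eqn{k_c} (J), the spontaneous curvature
#' \eqn{c_0} (1/m) induced by one-sided annexin binding, the adhesion energy
#' density \eqn{w_{ad}} (J/m^2) binding the patch to the underlying membrane,
#' the roll-spiral pitch \eqn{b} (m, radial spacing between successive wraps)
#' and the innermost roll radius \eqn{r_0} (m).
#'
#' @slot kc bending modulus, J.
#' @slot c0 spontaneous curvature, 1/m.
#' @slot wad adhesion energy density, J/m^2.
#' @slot b roll-spiral pitch (interlayer spacing), m.
#' @slot r0 innermost roll radius, m.
#' @slot preset name of the parameter preset used, or "custom".
#' @seealso [rollModelParams()]
#' @exportClass RollModelParams
setClass("RollModelParams",
  representation(kc = "numeric", c0 = "numeric", wad = "numeric",
                 b = "numeric", r0 = "numeric", preset = "character"),
  validity = function(object) {
    v <- c(kc = object@kc, c0 = object@c0, wad = object@wad,
           b = object@b, r0 = object@r0)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all of kc, c0, wad, b, r0 must be finite and strictly positive")
    TRUE
  })

#' Rolling energy profile
#'
#' \eqn{\Delta E(L)}: energy difference (rolled minus flat, per unit roll
#' width, J/m) as a function of rolled membrane length \eqn{L} (m).
#'
#' @slot lengths rolled lengths L, m, strictly increasing from 0.
#' @slot energyPerWidth \eqn{\Delta E(L)}, J/m; 0 at L = 0.
#' @exportClass EnergyProfile
setClass("EnergyProfile",
  representation(lengths = "numeric", energyPerWidth = "numeric"),
  validity = function(object) {
    if (length(object@lengths) != length(object@energyPerWidth))
      return("lengths and energyPerWidth must have equal length")
    if (length(object@lengths) && any(diff(object@lengths) <= 0))
      return("lengths must be strictly increasing")
    if (length(object@lengths) && object@lengths[1] == 0 &&
        abs(object@energyPerWidth[1]) > 0)
      return("energyPerWidth must be 0 at L = 0")
    TRUE
  })

#' Parameter-sweep result of the rolling model
#'
#' @slot factors dimensionless multipliers applied to the reference parameter.
#' @slot rolledLengths equilibrium rolled lengths L*, m.
#' @slot criticalFactor multiplier at which L* first reaches the resolution
#'   limit (NA when no sweep point brackets the crossing).
#' @slot parameter which parameter was swept ("adhesion" or "curvature").
#' @slot resolutionLimit the optical resolution limit used, m.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(factors = "numeric", rolledLengths = "numeric",
                 criticalFactor = "numeric", parameter = "character",
                 resolutionLimit = "numeric"),
  validity = function(object) {
    if (length(object@factors) != length(object@rolledLengths))
      return("factors and rolledLengths must have equal length")
    d <- diff(object@factors)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      return("factors must be strictly monotone")
    if (any(object@rolledLengths < 0)) return("rolledLengths must be >= 0")
    TRUE
  })

#' Time-lapse fluorescence image stack
#'
#' Frames are stored as a numeric array: `[row, col, frame]` for a single
#' channel or `[row, col, channel, frame]` for multi-channel stacks.
#'
#' @slot frames numeric array of intensities (3D or 4D as above).
#' @slot pixelSize physical pixel size, micrometres per pixel.
#' @slot frameInterval time between frames, seconds.
#' @slot channels channel labels (e.g. "dye", "protein").
#' @seealso [frameStack()], [readFrameStack()]
#' @exportClass FrameStack
setClass("FrameStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameInterval = "numeric", channels = "character"),
  validity = function(object) {
    nd <- length(dim(object@frames))
    if (!nd %in% c(3L, 4L))
      return("frames must be a 3D [row,col,frame] or 4D [row,col,channel,frame] array")
    if (dim(object@frames)[nd] < 2L) return("a stack needs at least 2 frames")
    if (nd == 4L && dim(object@frames)[3L] != length(object@channels))
      return("channel dimension must match length(channels)")
    if (object@pixelSize <= 0 || object@frameInterval <= 0)
      return("pixelSize and frameInterval must be > 0")
    TRUE
  })

#' Cumulative and incremental rolled area over time
#'
#' @slot times frame times, s.
#' @slot incrementalArea newly rolled area per frame, square micrometres.
#' @slot cumulativeArea running sum of incrementalArea, square micrometres.
#' @exportClass RollingTrace
setClass("RollingTrace",
  representation(times = "numeric", incrementalArea = "numeric",
                 cumulativeArea = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@incrementalArea) != n || length(object@cumulativeArea) != n)
      return("times, incrementalArea and cumulativeArea must have equal length")
    if (any(object@incrementalArea < 0)) return("incrementalArea must be >= 0")
    if (any(diff(object@cumulativeArea) < -1e-9))
      return("cumulativeArea must be non-decreasing")
    TRUE
  })

#' Logistic fit of a rolling trace
#'
#' Parameters of the least-squares fit of
#' \eqn{A / (1 + \exp(-(t - t_0)/\tau))} to cumulative rolled area.
#'
#' @slot tau rolling time constant, s.
#' @slot t0 midpoint (half-maximum) time, s.
#' @slot amplitude final rolled area A, square micrometres.
#' @slot onsetTime time at which cumulative area first exceeds the onset
#'   fraction of A, s.
#' @slot fitResidual root-mean-square misfit, square micrometres.
#' @slot fitted fitted cumulative-area curve at the trace times.
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(tau = "numeric", t0 = "numeric", amplitude = "numeric",
                 onsetTime = "numeric", fitResidual = "numeric",
                 fitted = "numeric"),
  validity = function(object) {
    if (object@tau <= 0) return("tau must be > 0")
    if (object@amplitude <= 0) return("amplitude must be > 0")
    if (is.finite(object@onsetTime) && object@onsetTime > object@t0)
      return("onsetTime must not exceed the midpoint t0")
    TRUE
  })

#' Relative-area trace of a patch unrolling from the maximally rolled state
#'
#' @slot times seconds since the maximally rolled state.
#' @slot relativeArea area(t)/area(0), dimensionless; 1 at t = 0.
#' @exportClass UnrollTrace
setClass("UnrollTrace",
  representation(times = "numeric", relativeArea = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@relativeArea))
      return("times and relativeArea must have equal length")
    if (object@times[1] != 0) return("times must start at 0")
    if (abs(object@relativeArea[1] - 1) > 1e-12)
      return("relativeArea must start at 1")
    TRUE
  })

#' Multi-channel intensity line profile
#'
#' @slot positions positions along the sampled segment, micrometres,
#'   strictly increasing.
#' @slot intensities matrix [position, channel] of min-max normalized
#'   intensities in [0, 1] (a constant channel maps to 0).
#' @slot peaks peak position per channel, micrometres (NA when the channel
#'   has no isolated peak).
#' @exportClass LineProfile
setClass("LineProfile",
  representation(positions = "numeric", intensities = "matrix",
                 peaks = "numeric"),
  validity = function(object) {
    if (nrow(object@intensities) != length(object@positions))
      return("intensities must have one row per position")
    if (any(diff(object@positions) <= 0))
      return("positions must be strictly increasing")
    rng <- range(object@intensities)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("intensities must be normalized to [0, 1]")
    TRUE
  })

#' AFM-style height map
#'
#' @slot heights matrix of heights, nm.
#' @slot pixelSize lateral pixel size, nm per pixel.
#' @seealso [heightMap()], [readHeightMap()], [scanSize()]
#' @exportClass HeightMap
setClass("HeightMap",
  representation(heights = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@heights))) return("heights must be finite")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    TRUE
  })

#' Lattice-period result from the 2D power spectrum of a height map
#'
#' @slot period mean first-order period (row spacing), nm; NA when no
#'   crystalline peaks were found.
#' @slot latticeConstant hexagonal lattice constant a = 2 d / sqrt(3), nm.
#' @slot peakWavevectors matrix [peak, (qx, qy)] of angular spatial
#'   frequencies, rad/nm.
#' @slot crystallinity TRUE when at least 4 discrete Bragg-like peaks exceed
#'   the radial background.
#' @slot binWidth radial frequency-bin width of the spectrum, rad/nm.
#' @exportClass LatticeResult
setClass("LatticeResult",
  representation(period = "numeric", latticeConstant = "numeric",
                 peakWavevectors = "matrix", crystallinity = "logical",
                 binWidth = "numeric"))

#' Height-domain area fractions
#'
#' @slot lowFraction percent of analyzed area in the lower height mode.
#' @slot highFraction percent in the higher mode; sums to 100 with lowFraction.
#' @slot threshold height threshold separating the modes, nm.
#' @exportClass DomainFractions
setClass("DomainFractions",
  representation(lowFraction = "numeric", highFraction = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    if (abs(object@lowFraction + object@highFraction - 100) > 1e-6)
      return("low and high fractions must sum to 100")
    TRUE
  })

#' Lipid-particle coordinate frame
#'
#' @slot positions matrix [particle, (x, y, z)], nm.
#' @slot leaflet factor with levels "lower", "upper" per particle.
#' @slot box periodic box lengths (x, y), nm.
#' @seealso [particleFrame()], [readParticleFrames()]
#' @exportClass ParticleFrame
setClass("ParticleFrame",
  representation(positions = "matrix", leaflet = "factor", box = "numeric"),
  validity = function(object) {
    if (ncol(object@positions) != 3L) return("positions must be n x 3")
    if (nrow(object@positions) != length(object@leaflet))
      return("one leaflet label per particle required")
    if (!all(levels(object@leaflet) %in% c("lower", "upper")))
      return("leaflet levels must be 'lower' and 'upper'")
    if (!all(c("lower", "upper") %in% as.character(object@leaflet)))
      return("both leaflets must be non-empty")
    if (length(object@box) != 2L || any(object@box <= 0))
      return("box must be two positive lengths (x, y)")
    TRUE
  })

#' Gridded membrane midplane surface
#'
#' @slot grid matrix of midplane heights z(x, y), nm (rows index x cells,
#'   columns y cells).
#' @slot cellSize lateral cell size, nm.
#' @slot occupancy samples per cell (min over leaflets).
#' @slot filled logical matrix flagging cells filled by interpolation.
#' @exportClass MidplaneSurface
setClass("MidplaneSurface",
  representation(grid = "matrix", cellSize = "numeric",
                 occupancy = "matrix", filled = "matrix"),
  validity = function(object) {
    if (!all(dim(object@grid) == dim(object@occupancy)) ||
        !all(dim(object@grid) == dim(object@filled)))
      return("grid, occupancy and filled must share dimensions")
    if (object@cellSize <= 0) return("cellSize must be > 0")
    TRUE
  })

#' Mean-curvature field of a midplane surface
#'
#' @slot meanCurvature matrix H(x, y), 1/nm.
#' @slot cellSize lateral cell size, nm.
#' @slot signConvention description of the normal orientation; with the
#'   normal along +z (the protein-bound side), a membrane dimpling away from
#'   the protein has negative H.
#' @exportClass CurvatureField
setClass("CurvatureField",
  representation(meanCurvature = "matrix", cellSize = "numeric",
                 signConvention = "character"),
  validity = function(object) {
    if (!all(is.finite(object@meanCurvature)))
      return("meanCurvature must be finite everywhere")
    TRUE
  })

#' Footprint curvature statistic
#'
#' Mean curvature averaged over a protein-footprint region, aggregated
#' across frames or replicas.
#'
#' @slot meanH across-frame mean of the region-averaged mean curvature, 1/nm.
#' @slot sdAcrossFrames standard deviation across frames/replicas, 1/nm.
#' @slot meanAbsH same aggregation applied to |H|, 1/nm.
#' @slot perFrame region-averaged H per frame, 1/nm.
#' @slot nFrames number of frames/replicas aggregated.
#' @slot nCells number of grid cells in the footprint region.
#' @exportClass FootprintStat
setClass("FootprintStat",
  representation(meanH = "numeric", sdAcrossFrames = "numeric",
                 meanAbsH = "numeric", perFrame = "numeric",
                 nFrames = "integer", nCells = "integer"),
  validity = function(object) {
    if (object@nCells < 1L) return("footprint region must be non-empty")
    if (is.finite(object@sdAcrossFrames) && object@sdAcrossFrames < 0)
      return("sd must be >= 0")
    TRUE
  })

#' Ground-truth record of a synthetic dataset
#'
#' Every generator returns one of these next to the dataset; together with
#' the seed it is sufficient to regenerate the dataset bit-exactly.
#'
#' @slot kind one of "movie", "unroll", "afm", "membrane".
#' @slot parameters named list of all generator parameters plus derived
#'   ground-truth quantities (e.g. analytic curvature, exact areas).
#' @slot seed the RNG seed used.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(kind = "character", parameters = "list", seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("movie", "unroll", "afm", "membrane"))
      return("kind must be movie, unroll, afm or membrane")
    TRUE
  })
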