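## Accessors and show methods. Slot access from user code should go through
## these, per the usual S4 etiquette.

#' @describeIn rollModelParams Accessors for model parameters.
#' @param object,x a package object.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @export
setMethod("modelParams", "RollModelParams", function(object)
  c(kc = object@kc, c0 = object@c0, wad = object@wad, b = object@b,
    r0 = object@r0))

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `rollTau`,
#' `rollOnset` and `rollAmplitude` read a [LogisticFit-class];
#' `criticalFactor` reads a [SweepResult-class]; `period` and
#' `latticeConstant` read a [LatticeResult-class]; `fractions` reads a
#' [DomainFractions-class]; `heights`, `pixelSize` and `scanSize` read a
#' [HeightMap-class]; `frames` and `pixelSize` read a [FrameStack-class];
#' `meanCurvature` reads a [CurvatureField-class]; `surfaceGrid` and
#' `occupancy` read a [MidplaneSurface-class]; `truthParams` reads a
#' [SyntheticTruth-class].
#'
#' @param object the object to read from.
#' @return The slot value (see each class's documentation for units).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rollTau", function(object) standardGeneric("rollTau"))
#' @rdname accessors
#' @export
setGeneric("rollOnset", function(object) standardGeneric("rollOnset"))
#' @rdname accessors
#' @export
setGeneric("rollAmplitude", function(object) standardGeneric("rollAmplitude"))
#' @rdname accessors
#' @export
setGeneric("criticalFactor", function(object) standardGeneric("criticalFactor"))
#' @rdname accessors
#' @export
setGeneric("period", function(object) standardGeneric("period"))
#' @rdname accessors
#' @export
setGeneric("latticeConstant", function(object) standardGeneric("latticeConstant"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("scanSize", function(object) standardGeneric("scanSize"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("meanCurvature", function(object) standardGeneric("meanCurvature"))
#' @rdname accessors
#' @export
setGeneric("surfaceGrid", function(object) standardGeneric("surfaceGrid"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("truthParams", function(object) standardGeneric("truthParams"))

#' @export
setMethod("rollTau", "LogisticFit", function(object) object@tau)
#' @export
setMethod("rollOnset", "LogisticFit", function(object) object@onsetTime)
#' @export
setMethod("rollAmplitude", "LogisticFit", function(object) object@amplitude)
#' @export
setMethod("criticalFactor", "SweepResult", function(object) object@criticalFactor)
#' @export
setMethod("period", "LatticeResult", function(object) object@period)
#' @export
setMethod("latticeConstant", "LatticeResult", function(object) object@latticeConstant)
#' @export
setMethod("fractions", "DomainFractions", function(object)
  c(low = object@lowFraction, high = object@highFraction))
#' @export
setMethod("heights", "HeightMap", function(object) object@heights)
#' @export
setMethod("pixelSize", "HeightMap", function(object) object@pixelSize)
#' @export
setMethod("pixelSize", "FrameStack", function(object) object@pixelSize)
#' @export
setMethod("scanSize", "HeightMap", function(object)
  dim(object@heights) * object@pixelSize)
#' @export
setMethod("frames", "FrameStack", function(object) object@frames)
#' @export
setMethod("meanCurvature", "CurvatureField", function(object) object@meanCurvature)
#' @export
setMethod("surfaceGrid", "MidplaneSurface", function(object) object@grid)
#' @export
setMethod("occupancy", "MidplaneSurface", function(object) object@occupancy)
#' @export
setMethod("truthParams", "SyntheticTruth", function(object) object@parameters)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "FrameStack", function(object) {
  d <- dim(object@frames)
  d[length(d)]
})

## data.frame coercions for the tabular objects
#' @export
as.data.frame.RollingTrace <- function(x, ...)
  data.frame(time_s = x@times, incremental_um2 = x@incrementalArea,
             cumulative_um2 = x@cumulativeArea)
#' @export
as.data.frame.UnrollTrace <- function(x, ...)
  data.frame(time_s = x@times, relative_area = x@relativeArea)
#' @export
as.data.frame.SweepResult <- function(x, ...)
  data.frame(factor = x@factors, L_star_m = x@rolledLengths)
#' @export
as.data.frame.LineProfile <- function(x, ...) {
  df <- data.frame(position_um = x@positions)
  cbind(df, as.data.frame(x@intensities))
}
#' @export
as.data.frame.EnergyProfile <- function(x, ...)
  data.frame(L_m = x@lengths, dE_J_per_m = x@energyPerWidth)

#' @export
setMethod("show", "RollModelParams", function(object) {
  cat(sprintf("RollModelParams (preset '%s')\n", object@preset))
  cat(sprintf("  kc  = %.3g J\n  c0  = %.3g 1/m\n  wad = %.3g J/m^2\n",
              object@kc, object@c0, object@wad))
  cat(sprintf("  b   = %.3g m\n  r0  = %.3g m\n", object@b, object@r0))
})

#' @export
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult (%s sweep, %d points)\n", object@parameter,
              length(object@factors)))
  cat(sprintf("  L* range: %.3g - %.3g m\n", min(object@rolledLengths),
              max(object@rolledLengths)))
  cat(sprintf("  critical factor at %.2g m limit: %s\n",
              object@resolutionLimit,
              if (is.na(object@criticalFactor)) "not bracketed"
              else sprintf("%.4g", object@criticalFactor)))
})

#' @export
setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d px, %d frame(s), %s channel(s)\n",
              d[1], d[2], d[length(d)], paste(object@channels, collapse = "/")))
  cat(sprintf("  %.3g um/px, %.3g s/frame\n", object@pixelSize,
              object@frameInterval))
})

#' @export
setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit: A / (1 + exp(-(t - t0)/tau))\n")
  cat(sprintf("  tau = %.4g s, t0 = %.4g s, A = %.4g um^2\n",
              object@tau, object@t0, object@amplitude))
  cat(sprintf("  onset = %.4g s, RMS residual = %.3g um^2\n",
              object@onsetTime, object@fitResidual))
})

#' @export
setMethod("show", "HeightMap", function(object) {
  d <- dim(object@heights)
  cat(sprintf("HeightMap: %d x %d px at %.3g nm/px (%.3g x %.3g nm)\n",
              d[1], d[2], object@pixelSize, d[1] * object@pixelSize,
              d[2] * object@pixelSize))
})

#' @export
setMethod("show", "LatticeResult", function(object) {
  if (is.na(object@period)) {
    cat("LatticeResult: no crystalline lattice detected\n")
  } else {
    cat(sprintf(
      "LatticeResult: period %.3g nm (lattice constant %.3g nm, %d peaks%s)\n",
      object@period, object@latticeConstant, nrow(object@peakWavevectors),
      if (object@crystallinity) ", crystalline" else "; crystallinity uncertain"))
  }
})

#' @export
setMethod("show", "DomainFractions", function(object) {
  cat(sprintf("DomainFractions: low %.4g%% / high %.4g%% (threshold %.3g nm)\n",
              object@lowFraction, object@highFraction, object@threshold))
})

#' @export
setMethod("show", "ParticleFrame", function(object) {
  cat(sprintf("ParticleFrame: %d particles (%d lower / %d upper), box %.3g x %.3g nm\n",
              nrow(object@positions), sum(object@leaflet == "lower"),
              sum(object@leaflet == "upper"), object@box[1], object@box[2]))
})

#' @export
setMethod("show", "CurvatureField", function(object) {
  cat(sprintf("CurvatureField: %d x %d cells at %.3g nm, H in [%.3g, %.3g] 1/nm\n",
              nrow(object@meanCurvature), ncol(object@meanCurvature),
              object@cellSize, min(object@meanCurvature),
              max(object@meanCurvature)))
  cat(" sign convention:", object@signConvention, "\n")
})

#' @export
setMethod("show", "FootprintStat", function(object) {
  cat(sprintf("FootprintStat: mean H = %.4g 1/nm (SD %.4g over %d frame(s), %d cells)\n",
              object@meanH, object@sdAcrossFrames, object@nFrames,
              object@nCells))
})

#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (%s, seed %d):\n", object@kind, object@seed))
  utils::str(object@parameters, max.level = 1, give.attr = FALSE)
})
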