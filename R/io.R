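## Readers and writers for the package's standard formats. Physical metadata
## (pixel size, frame interval) is always supplied explicitly by the caller
## (or a sidecar parameter file), never guessed from TIFF tags silently.

#' Read a time-lapse stack from multi-page TIFF
#'
#' @param path one TIFF path (single channel, or channel-interleaved pages
#'   with `interleaved = TRUE`), or a vector of paths, one file per channel.
#' @param pixelSize um per pixel.
#' @param frameInterval s per frame.
#' @param channels channel labels.
#' @param interleaved TRUE when the pages of one file alternate channels.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(path, pixelSize, frameInterval,
                           channels = NULL, interleaved = FALSE) {
  readOne <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  }
  if (length(path) > 1L) {
    chans <- lapply(path, readOne)
    nf <- length(chans[[1]])
    d <- dim(chans[[1]][[1]])
    arr <- array(0, c(d[1], d[2], length(path), nf))
    for (ch in seq_along(chans)) for (i in seq_len(nf))
      arr[, , ch, i] <- chans[[ch]][[i]]
    if (is.null(channels)) channels <- paste0("ch", seq_along(path))
    return(frameStack(arr, pixelSize, frameInterval, channels))
  }
  pages <- readOne(path)
  if (interleaved) {
    if (is.null(channels)) channels <- c("dye", "protein")
    nch <- length(channels)
    nf <- length(pages) %/% nch
    d <- dim(pages[[1]])
    arr <- array(0, c(d[1], d[2], nch, nf))
    for (i in seq_len(nf)) for (ch in seq_len(nch))
      arr[, , ch, i] <- pages[[(i - 1L) * nch + ch]]
    return(frameStack(arr, pixelSize, frameInterval, channels))
  }
  frameStack(pages, pixelSize, frameInterval,
             channels = if (is.null(channels)) "dye" else channels)
}

#' Write a frame stack as multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] over the whole stack (TIFF float
#' pages); the scale factor is returned invisibly.
#'
#' @param stack a [FrameStack-class] (single channel).
#' @param path output path.
#' @export
writeFrameStack <- function(stack, path) {
  f <- stack@frames
  if (length(dim(f)) == 4L) stop("write one channel at a time")
  lo <- min(f); hi <- max(f)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(f)[3]), function(i) (f[, , i] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(c(offset = lo, scale = scale))
}

#' Read an AFM height map
#'
#' Plain-text whitespace matrix (`.txt`), CSV (`.csv`) or single-page TIFF
#' (`.tif`/`.tiff`, heights in nm as float samples).
#'
#' @param path input path.
#' @param pixelSize nm per pixel.
#' @return A [HeightMap-class].
#' @export
readHeightMap <- function(path, pixelSize) {
  ext <- tolower(tools::file_ext(path))
  H <- switch(ext,
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    tif = , tiff = {
      m <- tiff::readTIFF(path, as.is = FALSE)
      if (length(dim(m)) == 3L) m[, , 1] else m
    },
    as.matrix(utils::read.table(path, header = FALSE)))
  dimnames(H) <- NULL
  heightMap(H, pixelSize)
}

#' @rdname readHeightMap
#' @param map a [HeightMap-class] to write as a whitespace text matrix.
#' @export
writeHeightMap <- function(map, path) {
  utils::write.table(map@heights, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read lipid-particle frames
#'
#' Accepts whitespace-delimited text or CSV with columns `x y z [leaflet]`
#' (nm; header optional; lines starting with `#` separate frames and are
#' otherwise ignored), or a minimal GRO dialect (fixed-width coordinate
#' columns in nm, converted on read; residue/atom names ignored). Without a
#' leaflet column, leaflets are assigned by z relative to the global
#' midplane of each frame.
#'
#' @param path input path.
#' @param box periodic box lengths (x, y), nm; for GRO input the box line is
#'   used when `box` is NULL.
#' @return A list of [ParticleFrame-class] objects (possibly length 1).
#' @export
readParticleFrames <- function(path, box = NULL) {
  lines <- readLines(path)
  if (tolower(tools::file_ext(path)) == "gro")
    return(list(parseGro(lines, box)))
  sep <- grepl("^\\s*#", lines)
  blocks <- split(lines[!sep], cumsum(sep)[!sep])
  blocks <- Filter(function(b) length(b) > 0, blocks)
  lapply(blocks, function(b) {
    tok1 <- strsplit(trimws(b[1]), "[,[:space:]]+")[[1]][1]
    hasHeader <- is.na(suppressWarnings(as.numeric(tok1)))
    txt <- if (grepl(",", b[1])) {
      utils::read.csv(text = b, header = hasHeader)
    } else {
      utils::read.table(text = b, header = hasHeader)
    }
    pos <- as.matrix(txt[, 1:3])
    leaflet <- if (ncol(txt) >= 4) as.character(txt[[4]]) else NULL
    if (is.null(box)) stop("box lengths are required for text input")
    particleFrame(pos, leaflet, box)
  })
}

## minimal GRO dialect: title, natoms, fixed-width atom lines, box line;
## coordinates are nm in columns 21-28 / 29-36 / 37-44
parseGro <- function(lines, box = NULL) {
  n <- as.integer(trimws(lines[2]))
  atoms <- lines[3:(2 + n)]
  pos <- cbind(as.numeric(substr(atoms, 21, 28)),
               as.numeric(substr(atoms, 29, 36)),
               as.numeric(substr(atoms, 37, 44)))
  if (is.null(box)) {
    bx <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
    box <- bx[1:2]
  }
  particleFrame(pos, NULL, box)
}

#' Read rolling-model parameters from YAML or JSON
#'
#' Keys: `k_c`, `c0`, `w_ad`, `b`, `r0` (all SI) and/or `preset`
#' ("results"/"methods"); explicit keys override the preset values.
#'
#' @param path parameter file.
#' @return A [RollModelParams-class].
#' @export
readModelParams <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  preset <- if (!is.null(cfg$preset)) cfg$preset else "results"
  p <- rollModelParams(preset)
  if (!is.null(cfg$k_c)) p@kc <- cfg$k_c
  if (!is.null(cfg$c0)) p@c0 <- cfg$c0
  if (!is.null(cfg$w_ad)) p@wad <- cfg$w_ad
  if (!is.null(cfg$b)) p@b <- cfg$b
  p@r0 <- if (!is.null(cfg$r0)) cfg$r0 else 1 / p@c0
  validObject(p)
  p
}

#' Write a tabular result as CSV
#'
#' Works for [RollingTrace-class], [UnrollTrace-class], [SweepResult-class],
#' [LineProfile-class] and [EnergyProfile-class] (via their `as.data.frame`
#' methods) and for [LogisticFit-class] (one-row parameter table).
#'
#' @param object the object to write.
#' @param path output path.
#' @export
writeCSV <- function(object, path) {
  df <- if (is(object, "LogisticFit")) {
    data.frame(tau_s = object@tau, t0_s = object@t0,
               amplitude_um2 = object@amplitude,
               onset_s = object@onsetTime,
               rms_residual_um2 = object@fitResidual)
  } else as.data.frame(object)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth record (or any result list) as JSON
#'
#' @param object a [SyntheticTruth-class], [LatticeResult-class],
#'   [DomainFractions-class] or [FootprintStat-class].
#' @param path output path.
#' @export
writeJSON <- function(object, path) {
  x <- if (is(object, "SyntheticTruth")) {
    list(kind = object@kind, seed = object@seed,
         parameters = object@parameters)
  } else if (is(object, "LatticeResult")) {
    list(period_nm = object@period, lattice_constant_nm = object@latticeConstant,
         crystallinity = object@crystallinity,
         peak_wavevectors = object@peakWavevectors)
  } else if (is(object, "DomainFractions")) {
    list(low_percent = object@lowFraction, high_percent = object@highFraction,
         threshold_nm = object@threshold)
  } else if (is(object, "FootprintStat")) {
    list(mean_H_per_nm = object@meanH, sd_per_nm = object@sdAcrossFrames,
         mean_abs_H_per_nm = object@meanAbsH, n_frames = object@nFrames,
         n_cells = object@nCells)
  } else object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
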