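#' Construct a hyperspectral cube
#'
#' A `HyperCube` is a 3-D array of non-negative values indexed
#' `(line, sample, band)` together with the band-center wavelengths in
#' nanometres and free-form acquisition metadata. Values are raw sensor
#' counts before [calibrate()] and dimensionless relative reflectance after.
#'
#' @param data numeric 3-D array, dimensions `(lines, samples, bands)`.
#' @param wavelengths_nm strictly increasing numeric vector of band-center
#'   wavelengths (nm); length must equal `dim(data)[3]`.
#' @param meta named list of acquisition metadata (free-form).
#' @return An object of class `HyperCube` (list with `data`,
#'   `wavelengths_nm`, `meta`).
#' @examples
#' cube <- hypercube(array(runif(2 * 2 * 3), c(2, 2, 3)), c(500, 600, 700))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths_nm, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_input("`data` must be a 3-D array (line, sample, band)")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3])
    stop_input("band dimension (", dim(data)[3], ") does not match ",
               "wavelength list length (", length(wavelengths_nm), ")")
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop_input("wavelengths_nm must be strictly increasing")
  if (!all(is.finite(data)))
    stop_input("cube contains non-finite values")
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 meta = as.list(meta)),
            class = "HyperCube")
}

#' @export
print.HyperCube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("HyperCube: %d lines x %d samples x %d bands (%.2f-%.2f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.HyperCube <- function(x) dim(x$data)

#' White/dark reference pair for reflectance calibration
#'
#' References may be full cubes (same dimensions as the raw scan), per-line
#' averaged frames (`samples x bands` matrices, the common whiteboard-strip
#' acquisition), or plain per-band spectra (length-`bands` vectors); they are
#' broadcast over the missing dimensions during [calibrate()].
#'
#' @param white whiteboard reference values.
#' @param dark dark-current reference values.
#' @return An object of class `CalibrationPair`.
#' @export
calibration_pair <- function(white, dark) {
  dw <- dim(white) %||% length(white)
  dd <- dim(dark) %||% length(dark)
  if (!identical(dw, dd))
    stop_input("white and dark references must have identical shapes")
  structure(list(white = white, dark = dark), class = "CalibrationPair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Broadcast a reference (vector of length B, matrix S x B, or full cube) to
# the cube's (L, S, B) dimensions.
broadcast_ref <- function(x, dims) {
  L <- dims[1]; S <- dims[2]; B <- dims[3]
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!identical(dim(x), dims))
      stop_input("reference cube dimensions ", paste(dim(x), collapse = "x"),
                 " do not match raw cube ", paste(dims, collapse = "x"))
    return(x)
  }
  if (is.matrix(x)) {
    if (!identical(dim(x), c(S, B)))
      stop_input("reference matrix must be samples x bands (",
                 S, "x", B, ")")
    return(aperm(array(x, c(S, B, L)), c(3L, 1L, 2L)))
  }
  if (length(x) == B)
    return(aperm(array(as.numeric(x), c(B, L, S)), c(2L, 3L, 1L)))
  stop_input("reference must be a length-", B, " vector, a ", S, "x", B,
             " matrix, or a full cube")
}

#' Convert raw counts to relative reflectance
#'
#' Applies the standard two-point radiometric correction
#' `CS = (CR - CD) / (CW - CD)` per pixel and band, where `CR` is the raw
#' scan, `CW` the whiteboard reference and `CD` the dark current. Output is
#' double precision and deliberately not clipped to `[0, 1]`: specular
#' pixels may legitimately exceed 1, and clipping would bias per-seed means.
#'
#' @param raw a raw-count [hypercube()].
#' @param refs a [calibration_pair()]; broadcastable to `raw`'s shape.
#' @param epsilon positive guard: wherever `white - dark <= 0` (dead pixels)
#'   the denominator is clamped to `epsilon` and a warning is emitted rather
#'   than aborting the whole cube.
#' @return A reflectance `HyperCube` with unchanged wavelengths and metadata.
#' @examples
#' raw <- hypercube(array(50, c(1, 1, 2)), c(500, 600))
#' refs <- calibration_pair(white = c(90, 90), dark = c(10, 10))
#' calibrate(raw, refs)$data  # (50-10)/(90-10) = 0.5
#' @export
calibrate <- function(raw, refs, epsilon = 1e-8) {
  stopifnot(inherits(raw, "HyperCube"), inherits(refs, "CalibrationPair"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop_input("epsilon must be a positive scalar")
  dims <- dim(raw$data)
  w <- broadcast_ref(refs$white, dims)
  d <- broadcast_ref(refs$dark, dims)
  denom <- w - d
  bad <- denom <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel-band location(s) with white <= dark; ",
            "denominator clamped to epsilon = ", epsilon)
    denom[bad] <- epsilon
  }
  out <- (raw$data - d) / denom
  storage.mode(out) <- "double"
  hypercube(out, raw$wavelengths_nm, raw$meta)
}

#' Index of the band nearest a target wavelength
#'
#' Segmentation operates on the single clearest band (598.71 nm for the
#' reference instrument); this resolves that wavelength to a band index on
#' an arbitrary grid. Ties (target exactly midway between two band centers)
#' break toward the lower index.
#'
#' @param cube a [hypercube()].
#' @param target_nm target wavelength in nm.
#' @return Integer band index (1-based).
#' @export
nearest_band <- function(cube, target_nm) {
  stopifnot(inherits(cube, "HyperCube"), length(target_nm) == 1L)
  which.min(abs(cube$wavelengths_nm - target_nm))
}
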