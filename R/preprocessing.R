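# Chemometric preprocessing of spectra matrices (rows = seeds, cols = bands).
# All operations are row-separable: each spectrum is transformed on its own
# (MSC against a shared reference), so row permutation commutes with them.

#' Standard normal variate (SNV)
#'
#' Centers and scales every spectrum (row) to mean 0 and sample standard
#' deviation 1, removing per-seed multiplicative/additive scatter without a
#' reference spectrum.
#'
#' @param X numeric matrix, seeds x bands.
#' @return Matrix of the same shape; each row has mean 0, sd 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop_input("zero-variance row(s): ", paste(head(bad, 5), collapse = ", "),
               " - SNV undefined")
  (X - mu) / sdv
}

#' Multiplicative scatter correction (MSC)
#'
#' Fits every spectrum to a reference by ordinary least squares,
#' `x_i = a_i * ref + b_i`, and inverts the fitted gain/offset:
#' `corrected_i = (x_i - b_i) / a_i`. The reference defaults to the column
#' mean of `X`; for train/test hygiene, fit on training rows and pass the
#' stored `reference` when correcting new spectra.
#'
#' @param X numeric matrix, seeds x bands.
#' @param reference length-`ncol(X)` reference spectrum, or `NULL` to use
#'   the column mean of `X` (requires >= 2 rows).
#' @param tol smallest acceptable |gain|.
#' @return List with `X` (corrected matrix), `gain`, `offset` (per-row
#'   fitted coefficients), and `reference`.
#' @export
msc <- function(X, reference = NULL, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(reference)) {
    if (nrow(X) < 2)
      stop_input("MSC needs >= 2 rows when no reference is given")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X))
    stop_input("reference length must equal band count")
  rc <- reference - mean(reference)
  vref <- sum(rc^2)
  if (vref == 0) stop_input("constant reference spectrum: MSC undefined")
  Xc <- X - rowMeans(X)
  gain <- as.numeric(Xc %*% rc) / vref
  bad <- which(abs(gain) < tol)
  if (length(bad))
    stop_input("near-zero MSC gain for row(s): ",
               paste(head(bad, 5), collapse = ", "))
  offset <- rowMeans(X) - gain * mean(reference)
  list(X = (X - offset) / gain, gain = gain, offset = offset,
       reference = reference)
}

# Savitzky-Golay engine. C maps the `window` values around a point to the
# fitted local polynomial's coefficients; interior points use the centered
# fit, edge points re-evaluate the first/last full-window fit at their
# offset (same-length output keeps band indices aligned with wavelengths).
sg_coef_matrix <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  solve(crossprod(A), t(A))
}

sg_poly_eval <- function(coef, t, deriv) {
  p <- length(coef) - 1L
  if (deriv > p) return(0)
  j <- deriv:p
  sum(coef[j + 1L] * factorial(j) / factorial(j - deriv) * t^(j - deriv))
}

sg_filter_row <- function(x, C, window, deriv, delta) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  # interior: centered window
  w_center <- factorial(deriv) * C[deriv + 1L, ]
  if (n >= window) {
    for (i in (h + 1L):(n - h))
      out[i] <- sum(w_center * x[(i - h):(i + h)])
    cl <- C %*% x[1:window]
    cr <- C %*% x[(n - window + 1L):n]
    for (i in seq_len(h)) {
      out[i] <- sg_poly_eval(cl, i - h - 1L, deriv)
      out[n - h + i] <- sg_poly_eval(cr, i, deriv)
    }
  }
  out / delta^deriv
}

check_sg_args <- function(window, polyorder, B) {
  if (window %% 2 != 1 || window < 3)
    stop_input("window must be an odd integer >= 3")
  if (polyorder < 0 || polyorder >= window)
    stop_input("polyorder must satisfy 0 <= polyorder < window")
  if (window > B)
    stop_input("window (", window, ") exceeds band count (", B, ")")
}

#' Savitzky-Golay smoothing
#'
#' Per-row local polynomial least-squares smoothing. Polynomials up to
#' `polyorder` pass through unchanged; boundary points are filled by
#' re-evaluating the first/last full-window fit so output length equals
#' input length.
#'
#' @param X numeric matrix, seeds x bands (bands >= window).
#' @param window odd window length (default 11).
#' @param polyorder local polynomial degree (default 2), < window.
#' @return Smoothed matrix, same shape.
#' @export
sg_smooth <- function(X, window = 11L, polyorder = 2L) {
  X <- as.matrix(X)
  check_sg_args(window, polyorder, ncol(X))
  C <- sg_coef_matrix(window, polyorder)
  t(apply(X, 1, sg_filter_row, C = C, window = window, deriv = 0L,
          delta = 1))
}

#' Savitzky-Golay spectral derivative
#'
#' First or second derivative of each spectrum with respect to wavelength,
#' estimated by local polynomial fitting (robust to the noise amplification
#' of finite differencing). Requires a uniform wavelength grid; values are
#' scaled by the grid step so units are reflectance per nm (per nm^2 for
#' order 2).
#'
#' @param X numeric matrix, seeds x bands.
#' @param wavelengths_nm uniform band grid (nm).
#' @param order derivative order, 1 or 2.
#' @param window,polyorder Savitzky-Golay parameters; `polyorder` must be
#'   >= `order`.
#' @param grid_tol maximum allowed relative deviation from a uniform grid.
#' @return Matrix of derivatives, same shape as `X`.
#' @export
sg_derivative <- function(X, wavelengths_nm, order = 1L, window = 11L,
                          polyorder = 2L, grid_tol = 1e-6) {
  X <- as.matrix(X)
  if (!order %in% c(1L, 2L)) stop_input("order must be 1 or 2")
  check_sg_args(window, polyorder, ncol(X))
  if (polyorder < order)
    stop_input("polyorder must be >= derivative order")
  if (length(wavelengths_nm) != ncol(X))
    stop_input("wavelength grid length must equal band count")
  steps <- diff(wavelengths_nm)
  delta <- mean(steps)
  if (max(abs(steps - delta)) > grid_tol * abs(delta))
    stop_input("wavelength grid is not uniform (needed for per-nm scaling)")
  C <- sg_coef_matrix(window, polyorder)
  t(apply(X, 1, sg_filter_row, C = C, window = window, deriv = order,
          delta = delta))
}

#' Apply a named preprocessing method to a spectra table
#'
#' Convenience dispatcher used by the pipeline and CLI. Method `"none"`
#' returns the table untouched (the default pipeline setting: classification
#' runs on raw reflectance unless preprocessing is requested).
#'
#' @param table a [seed_spectra_table()].
#' @param method one of `"none"`, `"snv"`, `"msc"`, `"smooth"`, `"d1"`,
#'   `"d2"`.
#' @param window,polyorder Savitzky-Golay parameters for the smoothing and
#'   derivative methods.
#' @param reference optional MSC reference spectrum.
#' @return A preprocessed `SeedSpectraTable`.
#' @export
preprocess_table <- function(table, method = c("none", "snv", "msc", "smooth",
                                               "d1", "d2"),
                             window = 11L, polyorder = 2L, reference = NULL) {
  stopifnot(inherits(table, "SeedSpectraTable"))
  method <- match.arg(method)
  X <- switch(method,
    none = table$spectra,
    snv = snv(table$spectra),
    msc = msc(table$spectra, reference = reference)$X,
    smooth = sg_smooth(table$spectra, window, polyorder),
    d1 = sg_derivative(table$spectra, table$wavelengths_nm, 1L, window,
                       polyorder),
    d2 = sg_derivative(table$spectra, table$wavelengths_nm, 2L, window,
                       max(polyorder, 2L)))
  seed_spectra_table(X, table$wavelengths_nm, table$seed_id,
                     table$class_label)
}
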