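# Ground-truthed synthetic data emulating a five-class mildew-severity
# experiment: reflectance templates whose 500-700 nm and 700-900 nm peaks
# decay monotonically with severity, per-seed affine scatter + additive
# noise (exactly what SNV/MSC target), and seed plates rendered as ellipse
# blobs on a dark matte background (exercising Otsu + morphology).

#' Synthetic experiment configuration
#'
#' Defaults state the emulated world: 5 ordered severity classes, 60 seeds
#' per class, a 462-band grid over 400-1000 nm, peak amplitudes decaying by
#' `delta` = 0.15 per severity step, additive noise sd 0.02 and per-seed
#' gain/offset scatter of a few percent. Smaller band grids (e.g. 50) are
#' supported for fast tests.
#'
#' @param n_classes number of ordered severity classes.
#' @param seeds_per_class seeds per class (cube layouts use two grid
#'   columns per class, so this should be even for [generate_cube()]).
#' @param n_bands,wl_min,wl_max band grid definition (nm).
#' @param delta per-class fractional decay of the template peaks.
#' @param noise_sd additive Gaussian noise per pixel/band.
#' @param gain_range,offset_range per-seed multiplicative/additive scatter
#'   ranges (set to `c(1, 1)` / `c(0, 0)` to disable).
#' @param ellipse_rx,ellipse_ry seed semi-axes in pixels.
#' @param spacing_px grid cell size for the plate layout.
#' @param background background reflectance of the matte plate.
#' @param white_level,dark_level per-band raw counts of the whiteboard and
#'   dark-current references.
#' @param informative_bands optional integer vector; when set, class
#'   templates are flat except at these bands, which shift by
#'   `informative_strength` per severity step (for feature-selection
#'   tests).
#' @param informative_strength see `informative_bands`.
#' @param rng_seed integer seed; all generators are fully deterministic
#'   given it.
#' @return Object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_classes = 5L, seeds_per_class = 60L,
                             n_bands = 462L, wl_min = 400, wl_max = 1000,
                             delta = 0.15, noise_sd = 0.02,
                             gain_range = c(0.95, 1.05),
                             offset_range = c(-0.02, 0.02),
                             ellipse_rx = 7L, ellipse_ry = 5L,
                             spacing_px = 20L, background = 0.05,
                             white_level = 1000, dark_level = 100,
                             informative_bands = NULL,
                             informative_strength = 0.05,
                             rng_seed = 1L) {
  if (delta < 0 || delta * (n_classes - 1) >= 1)
    stop_input("delta must keep all class amplitudes positive")
  if (2 * ellipse_rx + 2 >= spacing_px || 2 * ellipse_ry + 2 >= spacing_px)
    stop_input("seeds do not fit inside the grid spacing without touching")
  structure(list(n_classes = as.integer(n_classes),
                 seeds_per_class = as.integer(seeds_per_class),
                 wavelengths_nm = seq(wl_min, wl_max, length.out = n_bands),
                 delta = delta, noise_sd = noise_sd,
                 gain_range = gain_range, offset_range = offset_range,
                 ellipse_rx = as.integer(ellipse_rx),
                 ellipse_ry = as.integer(ellipse_ry),
                 spacing_px = as.integer(spacing_px),
                 background = background,
                 white_level = white_level, dark_level = dark_level,
                 informative_bands = informative_bands,
                 informative_strength = informative_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "SyntheticConfig")
}

#' Deterministic class reflectance template
#'
#' Smooth baseline plus Gaussian peaks near 560 nm and 800 nm whose
#' amplitudes scale by `1 - delta * class_index`: severity class k+1 is
#' dominated by class k at every wavelength in the 500-900 nm window,
#' strictly at the peaks — the monotone-severity signature of progressive
#' mold light absorption.
#'
#' @param class_index severity class, 0 (healthy) .. K-1 (heavy mold).
#' @param wavelengths_nm band grid; must lie within 400-1000 nm.
#' @param delta per-class amplitude decay (default 0.15).
#' @param informative_bands,informative_strength optional override: flat
#'   templates separated only at the given band indices (feature-selection
#'   benchmarks).
#' @return Numeric reflectance spectrum.
#' @export
class_template <- function(class_index, wavelengths_nm, delta = 0.15,
                           informative_bands = NULL,
                           informative_strength = 0.05) {
  if (length(class_index) != 1L || class_index < 0)
    stop_input("class_index must be a single non-negative integer")
  if (any(wavelengths_nm < 400 | wavelengths_nm > 1000))
    stop_input("wavelengths outside the 400-1000 nm instrument range")
  if (!is.null(informative_bands)) {
    tmpl <- rep(0.4, length(wavelengths_nm))
    tmpl[informative_bands] <- tmpl[informative_bands] +
      informative_strength * class_index
    return(tmpl)
  }
  scale <- 1 - delta * class_index
  if (scale <= 0) stop_input("delta * class_index >= 1: amplitude vanishes")
  peak1 <- 0.30 * exp(-((wavelengths_nm - 560) / 55)^2)
  peak2 <- 0.40 * exp(-((wavelengths_nm - 800) / 70)^2)
  0.22 + scale * (peak1 + peak2)
}

config_templates <- function(config) {
  vapply(seq_len(config$n_classes) - 1L, class_template,
         numeric(length(config$wavelengths_nm)),
         wavelengths_nm = config$wavelengths_nm, delta = config$delta,
         informative_bands = config$informative_bands,
         informative_strength = config$informative_strength)
}

#' Generate a labeled spectra table (fast path bypassing imaging)
#'
#' Each row is `a_i * template(class) + b_i + noise` with per-seed gain
#' `a_i`, offset `b_i` drawn from the configured scatter ranges and i.i.d.
#' Gaussian noise per band. Classes are balanced.
#'
#' @param config a [synthetic_config()].
#' @return List with `table` (a [seed_spectra_table()] with labels 0..K-1),
#'   `templates` (bands x classes matrix of noiseless class spectra).
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  templates <- config_templates(config)
  B <- length(config$wavelengths_nm)
  n <- config$n_classes * config$seeds_per_class
  with_seed(config$rng_seed, {
    labels <- rep(seq_len(config$n_classes) - 1L,
                  each = config$seeds_per_class)
    gains <- runif(n, config$gain_range[1], config$gain_range[2])
    offsets <- runif(n, config$offset_range[1], config$offset_range[2])
    X <- t(templates[, labels + 1L, drop = FALSE]) * gains + offsets +
      matrix(rnorm(n * B, sd = config$noise_sd), n, B)
    list(table = seed_spectra_table(X, config$wavelengths_nm, seq_len(n),
                                    labels),
         templates = templates,
         gains = gains, offsets = offsets)
  })
}

#' Render a synthetic raw acquisition (cube + references + ground truth)
#'
#' Seeds are laid out as ellipses on a plate of `2 * n_classes` grid
#' columns (two columns per class, mirroring a one-class-per-plate-region
#' design) and `seeds_per_class / 2` grid rows. Per-pixel reflectance
#' follows the class template with per-seed affine scatter and additive
#' noise; raw counts invert the reflectance calibration
#' (`raw = reflectance * (white - dark) + dark`), so
#' [calibrate()] recovers the planted reflectance exactly at zero noise.
#'
#' @param config a [synthetic_config()] (even `seeds_per_class`).
#' @return List: `raw` (raw-count [hypercube()]), `refs`
#'   (a [calibration_pair()] of per-band vectors), `labels` (ground-truth
#'   label matrix, ids in raster order), `classes` (severity class of each
#'   seed id), `reflectance` (planted reflectance cube), `templates`.
#' @export
generate_cube <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$seeds_per_class %% 2L != 0L)
    stop_input("cube layout needs an even seeds_per_class (two columns per class)")
  templates <- config_templates(config)
  wl <- config$wavelengths_nm
  B <- length(wl)
  ncols <- 2L * config$n_classes
  nrows <- config$seeds_per_class %/% 2L
  sp <- config$spacing_px
  S <- ncols * sp; L <- nrows * sp
  n_seeds <- ncols * nrows
  labels <- matrix(0L, L, S)
  classes <- integer(n_seeds)
  rx <- config$ellipse_rx; ry <- config$ellipse_ry
  k <- 0L
  for (gr in seq_len(nrows)) {
    for (gc in seq_len(ncols)) {
      k <- k + 1L
      classes[k] <- (gc - 1L) %/% 2L
      cy <- (gr - 0.5) * sp; cx <- (gc - 0.5) * sp
      rows <- floor(cy - ry):ceiling(cy + ry)
      cols <- floor(cx - rx):ceiling(cx + rx)
      for (r in rows) for (cc in cols) {
        if (((r - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1)
          labels[r, cc] <- k
      }
    }
  }
  with_seed(config$rng_seed, {
    gains <- runif(n_seeds, config$gain_range[1], config$gain_range[2])
    offsets <- runif(n_seeds, config$offset_range[1], config$offset_range[2])
    refl <- array(config$background, c(L, S, B))
    if (config$noise_sd > 0)
      refl <- refl + array(rnorm(L * S * B, sd = config$noise_sd),
                           c(L, S, B))
    flat <- matrix(refl, L * S, B)
    lab_vec <- as.integer(labels)
    for (id in seq_len(n_seeds)) {
      px <- which(lab_vec == id)
      base <- gains[id] * templates[, classes[id] + 1L] + offsets[id]
      noise <- if (config$noise_sd > 0)
        matrix(rnorm(length(px) * B, sd = config$noise_sd), length(px), B)
      else 0
      flat[px, ] <- matrix(base, length(px), B, byrow = TRUE) + noise
    }
    refl <- array(flat, c(L, S, B))
    white <- rep(config$white_level, B)
    dark <- rep(config$dark_level, B)
    raw <- refl * rep(white - dark, each = L * S) +
      rep(dark, each = L * S)
    list(raw = hypercube(array(raw, c(L, S, B)), wl,
                         meta = list(generator = "moldseed-synthetic",
                                     rng_seed = config$rng_seed)),
         refs = calibration_pair(white = white, dark = dark),
         labels = labels, classes = classes,
         reflectance = hypercube(refl, wl),
         templates = templates)
  })
}
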