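# Wavelength selection: random-forest impurity importance (screening rule
# "importance > 0") and competitive adaptive reweighted sampling (CARS):
# Monte Carlo calibration subsets + PLS1 coefficient magnitudes + an
# exponentially decreasing retention schedule, scored by RMSECV.

# NIPALS PLS1: univariate-response partial least squares. Returns enough to
# form the regression coefficients at any number of components <= ncomp.
pls1_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    p_a <- crossprod(E, t) / tt
    q_a <- sum(f * t) / tt
    E <- E - t %*% t(p_a)
    f <- f - t * q_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
  }
  if (ncomp < 1L) stop_input("PLS found no usable component (constant data?)")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # coefficients on the original scale
  R <- W %*% solve(crossprod(P, W))
  coef <- as.numeric(R %*% q)
  list(coef = coef, intercept = ym - sum(xm * coef), ncomp = ncomp,
       x_mean = xm, y_mean = ym)
}

pls1_predict <- function(fit, X)
  as.numeric(as.matrix(X) %*% fit$coef + fit$intercept)

# RMSE of k-fold cross-validated PLS1 at a fixed component count; `folds`
# is a precomputed assignment so comparisons across band subsets share the
# exact same partition.
pls1_rmsecv <- function(X, y, ncomp, folds) {
  X <- as.matrix(X)
  err2 <- 0
  for (fl in sort(unique(folds))) {
    tr <- folds != fl
    fit <- pls1_nipals(X[tr, , drop = FALSE], y[tr], ncomp)
    pred <- pls1_predict(fit, X[!tr, , drop = FALSE])
    err2 <- err2 + sum((y[!tr] - pred)^2)
  }
  sqrt(err2 / length(y))
}

# Best RMSECV over component counts 1..ncomp_max (component count chosen by
# cross-validation, capped).
pls1_rmsecv_best <- function(X, y, ncomp_max, folds) {
  cap <- min(ncomp_max, ncol(as.matrix(X)), nrow(as.matrix(X)) - 2L)
  min(vapply(seq_len(max(1L, cap)), function(a)
    pls1_rmsecv(X, y, a, folds), numeric(1)))
}

#' Random-forest wavelength importance
#'
#' Fits a random forest on the labeled spectra and returns every band's
#' mean-decrease-in-impurity importance, normalized to sum to 1. Used to
#' screen the full band set down to the informative subset via
#' [select_positive_importance()].
#'
#' @param table a [seed_spectra_table()] with class labels (>= 2 classes).
#' @param n_trees forest size (default 200; importance stabilizes with
#'   trees).
#' @param seed integer RNG seed (scores are deterministic given it).
#' @return `data.frame` with `band_index`, `wavelength_nm`, `importance`,
#'   ordered by band index.
#' @export
rf_band_importance <- function(table, n_trees = 200L, seed = 1L) {
  stopifnot(inherits(table, "SeedSpectraTable"))
  if (is.null(table$class_label))
    stop_input("table has no class labels")
  if (length(unique(table$class_label)) < 2)
    stop_input("importance needs >= 2 classes")
  fit <- rf_fit(table$spectra, table$class_label, n_trees = n_trees,
                seed = seed)
  data.frame(band_index = seq_len(ncol(table$spectra)),
             wavelength_nm = table$wavelengths_nm,
             importance = fit$importance)
}

#' Select bands above an importance threshold
#'
#' The screening rule keeps bands with importance strictly greater than the
#' threshold (default 0, i.e. every band that ever contributed a split).
#'
#' @param scores data.frame from [rf_band_importance()].
#' @param threshold importance cutoff (default 0).
#' @return Ascending integer vector of selected band indices.
#' @export
select_positive_importance <- function(scores, threshold = 0) {
  sort(scores$band_index[scores$importance > threshold])
}

# Exponentially decreasing retention schedule with the canonical boundary
# conditions r_1 = 1 (all B bands) and r_N = 2/B (two bands):
# r_i = a exp(-k i), a = (B/2)^(1/(N-1)), k = log(B/2)/(N-1).
cars_edf_counts <- function(B, n_runs) {
  a <- (B / 2)^(1 / (n_runs - 1))
  k <- log(B / 2) / (n_runs - 1)
  # tiny slack before the ceiling so the exact endpoints (r_1 B = B,
  # r_N B = 2) are not bumped up by floating-point error
  pmax(2L, pmin(B, as.integer(ceiling(a * exp(-k * seq_len(n_runs)) * B -
                                        1e-9))))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iterates `n_runs` Monte Carlo rounds: draw a random calibration subset
#' of rows, fit PLS1 on the currently retained bands, rank bands by
#' absolute regression coefficient, and cut the retained set to the
#' exponentially decreasing (EDF) schedule count. Each round's retained set
#' is scored by `cv_folds`-fold RMSECV (component count chosen by CV,
#' capped at `n_components`) on a fold partition shared across rounds; the
#' selected subset is the minimum-RMSECV round's band set. Class labels
#' should be regression-coded (ordinal severity 0-4) for the internal PLS.
#'
#' @param X numeric spectra matrix (rows = seeds).
#' @param y numeric response (ordinal-coded class labels).
#' @param n_runs Monte Carlo rounds (default 50).
#' @param cal_fraction fraction of rows in each calibration draw
#'   (default 0.8).
#' @param n_components maximum PLS components (default 10).
#' @param cv_folds RMSECV folds (default 5).
#' @param seed integer seed; the run is reproducible bit-for-bit from it.
#' @return Object of class `CarsResult`: `selected` (band indices of the
#'   best round), `best_iteration`, `rmsecv` (per round), `retained_sets`
#'   (list of per-round band index vectors), `edf_counts`, `seed`.
#' @export
cars_select <- function(X, y, n_runs = 50L, cal_fraction = 0.8,
                        n_components = 10L, cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (n_runs < 2L) stop_input("n_runs must be >= 2")
  if (cal_fraction <= 0 || cal_fraction >= 1)
    stop_input("cal_fraction must be in (0, 1)")
  n <- nrow(X); B <- ncol(X)
  counts <- cars_edf_counts(B, n_runs)
  with_seed(seed, {
    folds <- (seq_len(n) %% cv_folds) + 1L
    folds <- folds[sample.int(n)]
    retained <- seq_len(B)
    retained_sets <- vector("list", n_runs)
    rmsecv <- rep(NA_real_, n_runs)
    for (i in seq_len(n_runs)) {
      if (length(retained) < max(2L, min(n_components, 2L))) break
      cal <- sample.int(n, max(cv_folds, round(cal_fraction * n)))
      fit <- pls1_nipals(X[cal, retained, drop = FALSE], y[cal],
                         n_components)
      w <- abs(fit$coef)
      keep_n <- min(counts[i], length(retained))
      # EDF cut: keep the top-weighted bands at the scheduled count; ties
      # broken by band order. Round-to-round diversity comes from the Monte
      # Carlo calibration draw feeding the coefficients.
      retained <- sort(retained[order(-w, retained)[seq_len(keep_n)]])
      retained_sets[[i]] <- retained
      rmsecv[i] <- pls1_rmsecv_best(X[, retained, drop = FALSE], y,
                                    n_components, folds)
      if (length(retained) <= 2L && i < n_runs) break
    }
    done <- which(!is.na(rmsecv))
    if (!length(done)) stop_input("CARS made no valid iteration")
    best <- done[which.min(rmsecv[done])]
    structure(list(selected = retained_sets[[best]],
                   best_iteration = best,
                   rmsecv = rmsecv[done],
                   retained_sets = retained_sets[done],
                   edf_counts = counts[done],
                   seed = as.integer(seed)),
              class = "CarsResult")
  })
}

#' @export
print.CarsResult <- function(x, ...) {
  cat(sprintf(
    "CarsResult: %d bands selected at iteration %d (RMSECV %.4f of %d runs)\n",
    length(x$selected), x$best_iteration, min(x$rmsecv), length(x$rmsecv)))
  invisible(x)
}
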