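# Shared fixtures, all generated in code (no stored binaries).

tiny_cube <- function() {
  hypercube(array(as.numeric(1:12), c(2, 2, 3)), c(500, 600, 700),
            meta = list(instrument = "synthetic-rig", scan_speed = "3.4"))
}

# Independent brute-force Otsu oracle: exhaustive scan of all 256-bin cuts
# maximizing between-class variance, written against the definition (not
# the package's vectorized path).
otsu_bruteforce <- function(v, nbins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  n <- length(v)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 1:(nbins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):nbins] * mids[(t + 1):nbins]) / n1
    s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  edges[best_t + 1L]
}

random_bimodal_image <- function(seed, n = 400L) {
  set.seed(seed)
  v <- c(rnorm(n / 2, mean = 0.25, sd = 0.05),
         rnorm(n / 2, mean = 0.75, sd = 0.07))
  matrix(v, 20)
}

# Regression-coded spectra whose response depends linearly on bands
# {5, 25, 45} (the CARS recovery benchmark).
cars_benchmark <- function(seed, n = 100L, B = 50L, noise_sd = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * B), n, B)
  y <- X[, 5] + X[, 25] + X[, 45] + rnorm(n, sd = noise_sd)
  list(X = X, y = y, informative = c(5L, 25L, 45L))
}

# Two well-separated Gaussian clusters (perfectly separable classes).
separable_data <- function(seed, n_per = 30L, p = 10L, gap = 8) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = gap), n_per))
  list(X = X, y = rep(0:1, each = n_per))
}

rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)

# 20x20 lattice objective: a quantized multimodal surface (Rastrigin around
# a random grid center) with a unique known minimum; continuous positions
# snap to the nearest cell. The exhaustive scan of all 400 cells is the
# independent oracle.
lattice_objective <- function(seed) {
  set.seed(seed)
  ctr <- sample(5:16, 2, replace = TRUE)
  Z <- outer(1:20, 1:20,
             Vectorize(function(i, j) rastrigin(c(i, j) - ctr) + 0.5))
  f <- function(x) {
    i <- pmin(pmax(round(x[1]), 1), 20)
    j <- pmin(pmax(round(x[2]), 1), 20)
    Z[i, j]
  }
  list(f = f, Z = Z, minimum = min(Z))
}

fast_cube_config <- function(seed, noise_sd = 0.02, n_bands = 50L)
  synthetic_config(n_bands = n_bands, seeds_per_class = 12L,
                   noise_sd = noise_sd, rng_seed = seed)

jaccard <- function(a, b) sum(a & b) / sum(a | b)
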