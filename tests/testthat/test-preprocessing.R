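test_that("SNV centers and scales every row", {
  expect_equal(as.numeric(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(5)
  X <- matrix(rnorm(10 * 50, mean = 3, sd = 2), 10)
  out <- snv(X)
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))
  # idempotence
  expect_equal(snv(out), out, tolerance = 1e-12)
  expect_error(snv(rbind(X[1, ], rep(2, 50))), "zero-variance")
})

test_that("MSC inverts an exact affine distortion and leaves the reference alone", {
  set.seed(6)
  wl <- seq(400, 1000, length.out = 80)
  ref <- class_template(0, wl)
  a <- runif(8, 0.7, 1.3); b <- runif(8, -0.1, 0.1)
  X <- t(sapply(seq_along(a), function(i) a[i] * ref + b[i]))
  out <- msc(X, reference = ref)
  expect_equal(out$X, matrix(ref, 8, 80, byrow = TRUE), tolerance = 1e-10)
  expect_equal(out$gain, a, tolerance = 1e-10)
  expect_equal(out$offset, b, tolerance = 1e-10)
  one <- msc(matrix(ref, 1), reference = ref)
  expect_equal(as.numeric(one$X), ref, tolerance = 1e-12)
  expect_equal(one$gain, 1, tolerance = 1e-12)
  expect_equal(one$offset, 0, tolerance = 1e-12)
})

test_that("MSC reduces scatter-induced deviation by >= 90% at sigma 0.01", {
  set.seed(7)
  wl <- seq(400, 1000, length.out = 100)
  tmpl <- class_template(1, wl)
  n <- 40
  a <- runif(n, 0.7, 1.3); b <- runif(n, -0.15, 0.15)
  X <- t(sapply(seq_len(n), function(i)
    a[i] * tmpl + b[i] + rnorm(100, sd = 0.01)))
  corrected <- msc(X, reference = tmpl)$X
  msd <- function(M) mean((M - matrix(tmpl, n, 100, byrow = TRUE))^2)
  expect_lt(msd(corrected), 0.1 * msd(X))
})

test_that("all preprocessing operations commute with row permutation", {
  set.seed(8)
  wl <- seq(400, 1000, length.out = 60)
  X <- t(sapply(0:4, function(k) class_template(k, wl) + rnorm(60, sd = 0.01)))
  perm <- c(3, 5, 1, 4, 2)
  ref <- colMeans(X)
  for (f in list(snv,
                 function(M) msc(M, reference = ref)$X,
                 function(M) sg_smooth(M, 7, 2),
                 function(M) sg_derivative(M, wl, 1, 7, 2))) {
    expect_equal(f(X)[perm, ], f(X[perm, ]), tolerance = 1e-12)
  }
})

test_that("Savitzky-Golay reproduces polynomials up to its order", {
  wl <- seq(400, 1000, length.out = 50)
  quad <- 0.5 + 0.001 * wl + 2e-6 * wl^2
  out <- sg_smooth(matrix(quad, 1), window = 11, polyorder = 2)
  expect_equal(as.numeric(out), quad, tolerance = 1e-10)
  const <- matrix(0.7, 1, 50)
  expect_equal(sg_smooth(const, 11, 2), const, tolerance = 1e-12)
})

test_that("smoothing attenuates additive noise on a sine", {
  set.seed(9)
  wl <- seq(400, 1000, length.out = 200)
  clean <- sin(wl / 40)
  noisy <- clean + rnorm(200, sd = 0.05)
  sm <- as.numeric(sg_smooth(matrix(noisy, 1), 11, 2))
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("SG derivatives match analytic derivatives per nm", {
  wl <- seq(400, 1000, length.out = 60)
  interior <- 6:55
  d1 <- sg_derivative(matrix(2 * wl, 1), wl, order = 1)
  expect_equal(as.numeric(d1)[interior], rep(2, 50), tolerance = 1e-8)
  d0 <- sg_derivative(matrix(0.3, 1, 60), wl, order = 1)
  expect_equal(as.numeric(d0), rep(0, 60), tolerance = 1e-12)
  d2 <- sg_derivative(matrix(wl^2, 1), wl, order = 2, polyorder = 3)
  expect_equal(as.numeric(d2)[interior], rep(2, 50), tolerance = 1e-8)
})

test_that("derivative of a cumulative sum of a non-negative row is non-negative", {
  set.seed(10)
  for (rep in 1:5) {
    x <- cumsum(runif(80))
    wl <- seq(400, 1000, length.out = 80)
    d <- as.numeric(sg_derivative(matrix(x, 1), wl, 1, window = 5,
                                  polyorder = 1))
    expect_true(all(d[3:78] >= -1e-12))
  }
})

test_that("parameter validation catches bad SG settings and grids", {
  X <- matrix(rnorm(40), 2)
  wl <- seq(400, 1000, length.out = 20)
  expect_error(sg_smooth(X, window = 8), "odd")
  expect_error(sg_smooth(X, window = 5, polyorder = 5), "polyorder")
  expect_error(sg_smooth(X, window = 31), "band count")
  expect_error(sg_derivative(X, c(wl[1:19], 1200), 1), "uniform|instrument")
  expect_error(sg_derivative(X, wl, order = 3), "order")
})

test_that("preprocess_table dispatches and preserves labels", {
  sim <- generate_table(synthetic_config(n_bands = 30, seeds_per_class = 4))
  for (m in c("none", "snv", "msc", "smooth", "d1", "d2")) {
    out <- preprocess_table(sim$table, m, window = 7)
    expect_equal(out$class_label, sim$table$class_label, label = m)
    expect_equal(dim(out$spectra), dim(sim$table$spectra), label = m)
  }
  expect_identical(preprocess_table(sim$table, "none")$spectra,
                   sim$table$spectra)
})
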