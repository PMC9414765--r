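sphere <- function(x) sum(x^2)

base_cfg <- function(...) jyssa_config(lower = c(-10, -10), upper = c(10, 10), ...)

test_that("config validation enforces the stated parameter ranges", {
  expect_error(jyssa_config(c(0, 0), c(1, -1)), "lower < upper")
  expect_error(base_cfg(PD = 0), "PD")
  expect_error(base_cfg(SD = 0.3), "SD")
  expect_error(base_cfg(ST = 0.4), "ST")
  expect_error(base_cfg(epsilon = 0), "epsilon")
})

test_that("initialization respects bounds, role counts, and finiteness", {
  cfg <- base_cfg(pop_size = 30, rng_seed = 3)
  set.seed(3)
  pop <- init_population(cfg, sphere)
  expect_true(all(pop$X >= -10 & pop$X <= 10))
  expect_true(all(is.finite(pop$f)))
  expect_equal(sum(pop$roles == "producer"), round(0.2 * 30))
  expect_equal(pop$fg, min(pop$f))
  expect_equal(pop$fw, max(pop$f))
  expect_equal(sphere(pop$Xbest), pop$fg)
})

test_that("elite opposition never acts on a constant fitness landscape", {
  cfg <- base_cfg(pop_size = 20, rng_seed = 5)
  set.seed(5); with_elite <- init_population(cfg, function(x) 1)
  cfg2 <- base_cfg(pop_size = 20, rng_seed = 5, use_elite = FALSE)
  set.seed(5); plain <- init_population(cfg2, function(x) 1)
  expect_identical(with_elite$X, plain$X) # candidates never strictly fitter
})

test_that("elite opposition at init does not hurt mean fitness (paired seeds)", {
  corner <- function(x) sum((x - 10)^2)
  diffs <- vapply(1:50, function(s) {
    set.seed(s); a <- init_population(base_cfg(pop_size = 20), corner)
    set.seed(s); b <- init_population(base_cfg(pop_size = 20,
                                               use_elite = FALSE), corner)
    mean(a$f) - mean(b$f)
  }, numeric(1))
  expect_lte(mean(diffs), 0)
})

test_that("producer update reproduces hand-computed positions", {
  cfg <- jyssa_config(lower = -10, upper = 10, pop_size = 2, max_iter = 50,
                      ST = 0.8, PD = 0.5)
  pop <- list(X = matrix(c(4, -6), 2, 1), f = c(1, 2), t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  expect_equal(pop$roles, c("producer", "follower"))
  set.seed(11)
  out <- producer_update(pop, cfg)
  # independent scalar oracle replaying the same RNG stream
  set.seed(11)
  R2 <- runif(1)
  expected <- if (R2 < 0.8) {
    alpha <- 1 - runif(1)
    4 * exp(-1 / (alpha * 50))
  } else 4 + rnorm(1)
  expect_equal(out$X[1, 1], min(max(expected, -10), 10))
  expect_equal(out$X[2, 1], -6) # followers untouched by producer step
})

test_that("the contraction branch shrinks positive positions", {
  cfg <- jyssa_config(lower = 0.01, upper = 10, pop_size = 4, ST = 1,
                      PD = 0.5, max_iter = 50)
  pop <- list(X = matrix(c(5, 7, 2, 3), 4, 1), f = 1:4, t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  set.seed(2) # R2 < 1 always: contraction branch guaranteed
  out <- producer_update(pop, cfg)
  prod_rows <- which(pop$roles == "producer")
  expect_true(all(out$X[prod_rows, 1] < pop$X[prod_rows, 1]))
  expect_true(all(out$X[prod_rows, 1] > 0))
})

test_that("follower plunder branch lands on Xp or its reflection at d = 1", {
  cfg <- jyssa_config(lower = -100, upper = 100, pop_size = 4, PD = 0.25)
  # ranks: row1 best (producer, Xp), rows 2 follower in better half
  pop <- list(X = matrix(c(2, 5, 9, 11), 4, 1), f = c(1, 2, 3, 4), t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  set.seed(7)
  out <- follower_update(pop, cfg)
  # rank-2 follower (better half): Xp +/- |X - Xp|
  expect_true(out$X[2, 1] %in% c(2 + 3, 2 - 3))
  # follower exactly at Xp stays at Xp
  pop2 <- list(X = matrix(c(2, 2, 9, 11), 4, 1), f = c(1, 2, 3, 4), t = 1L)
  pop2 <- moldseed:::reassign_roles(pop2, cfg)
  set.seed(8)
  out2 <- follower_update(pop2, cfg)
  expect_equal(out2$X[2, 1], 2)
})

test_that("follower starvation branch reproduces its closed form", {
  cfg <- jyssa_config(lower = -100, upper = 100, pop_size = 4, PD = 0.25)
  pop <- list(X = matrix(c(2, 5, 9, 11), 4, 1), f = c(1, 2, 3, 4), t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  set.seed(9)
  out <- follower_update(pop, cfg)
  set.seed(9)
  # replay: rank-2 follower draws A first (plunder), ranks 3 and 4 starve
  A <- sample(c(-1, 1), 1); q3 <- rnorm(1); q4 <- rnorm(1)
  expect_equal(out$X[3, 1], q3 * exp((11 - 9) / 9))
  expect_equal(out$X[4, 1], q4 * exp((11 - 11) / 16))
})

test_that("scout update honors its two branches", {
  cfg <- jyssa_config(lower = -100, upper = 100, pop_size = 4, PD = 0.25)
  pop <- list(X = matrix(c(2, 5, 9, 11), 4, 1), f = c(1, 2, 3, 4), t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  # best-fitness scout sitting at Xworst: zero step
  pop_at_worst <- pop
  pop_at_worst$X[1, 1] <- 11
  pop_at_worst$Xworst <- 11; pop_at_worst$Xbest <- 11
  set.seed(10)
  out <- scout_update(pop_at_worst, cfg, scouts = 1L)
  expect_equal(out$X[1, 1], 11)
  # worse-than-best scout at Xbest stays for any beta
  pop_at_best <- pop
  pop_at_best$X[3, 1] <- pop$Xbest
  set.seed(11)
  out2 <- scout_update(pop_at_best, cfg, scouts = 3L)
  expect_equal(out2$X[3, 1], pop$Xbest)
  # hand-computed toward-best move
  set.seed(12)
  out3 <- scout_update(pop, cfg, scouts = 3L)
  set.seed(12)
  beta <- rnorm(1, 1, 1)
  expect_equal(out3$X[3, 1], 2 + beta * abs(9 - 2))
})

test_that("elite reverse is greedy: the best fitness never degrades", {
  cfg <- base_cfg(pop_size = 10, rng_seed = 1)
  set.seed(1)
  pop <- init_population(cfg, sphere)
  for (i in 1:10) {
    fg_before <- pop$fg
    pop <- elite_reverse(pop, cfg, sphere)
    expect_lte(pop$fg, fg_before)
  }
})

test_that("a single-member elite box is degenerate and leaves it unchanged", {
  cfg <- jyssa_config(lower = c(-5, -5), upper = c(5, 5), pop_size = 5,
                      elite_fraction = 0.1)
  pop <- list(X = matrix(c(3, 1, 2, -1, 0, 3, 1, 2, -1, 0), 5, 2),
              f = c(1, 2, 3, 4, 5), t = 1L)
  pop <- moldseed:::reassign_roles(pop, cfg)
  set.seed(4)
  out <- elite_reverse(pop, cfg, function(x) sum(abs(x)))
  expect_equal(out$X[1, ], pop$X[1, ]) # da = db = X: candidate is X itself
})

test_that("optimize is reproducible bit-for-bit and stays in bounds", {
  cfg <- base_cfg(pop_size = 20, max_iter = 30, rng_seed = 99)
  a <- jyssa_optimize(sphere, cfg)
  b <- jyssa_optimize(sphere, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$best_position, b$best_position)
  expect_true(all(a$best_position >= -10 & a$best_position <= 10))
  expect_true(all(diff(a$history) <= 0))
})

test_that("constant fitness yields a flat history", {
  cfg <- base_cfg(pop_size = 10, max_iter = 25, patience = 100, rng_seed = 2)
  res <- jyssa_optimize(function(x) 3.5, cfg)
  expect_true(all(res$history == 3.5))
})

test_that("non-finite fitness is reported with the offending position", {
  cfg <- base_cfg(pop_size = 5, max_iter = 5, rng_seed = 3)
  expect_error(jyssa_optimize(function(x) NaN, cfg), "non-finite fitness")
})

test_that("the optimizer does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(0))
  jyssa_optimize(sphere, base_cfg(pop_size = 10, max_iter = 5, rng_seed = 4))
  after <- runif(3)
  expect_identical(before, after)
})
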