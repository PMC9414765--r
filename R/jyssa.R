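# Sparrow search algorithm (SSA) with an elite opposition ("reverse")
# strategy. Roles: producers/explorers lead the search, followers exploit
# them, scouts perturb danger-aware. The elite-reverse step mirrors the best
# individuals inside the elite set's dynamic bounding box and keeps the
# fitter of each pair, which is the mechanism credited with escaping local
# optima. Minimization convention throughout.

#' Optimizer configuration
#'
#' @param lower,upper numeric per-dimension bounds (`lower < upper`).
#' @param pop_size population size n (default 30).
#' @param max_iter iteration cap (default 50).
#' @param ST safety threshold in (0.5, 1]; when the per-iteration alarm
#'   value R2 is below it, producers contract exponentially, otherwise they
#'   take a Gaussian step (default 0.8).
#' @param PD producer fraction (default 0.2).
#' @param SD scout fraction, in \[0.10, 0.20\] (default 0.15); scout
#'   membership is resampled every iteration.
#' @param elite_fraction fraction treated as the elite group for the
#'   opposition step (default 0.10).
#' @param epsilon guard constant avoiding division by zero in the scout
#'   update.
#' @param beta_mean mean of the scout step factor beta ~ N(beta_mean, 1);
#'   default 1 (set 0 for the classical choice).
#' @param use_elite enable the elite-reverse strategy (default TRUE; FALSE
#'   gives the plain SSA baseline).
#' @param tol,patience stop early when the best fitness improves by less
#'   than `tol` for `patience` consecutive iterations.
#' @param rng_seed integer seed; the whole run is bit-reproducible from it.
#' @return Object of class `JyssaConfig`.
#' @export
jyssa_config <- function(lower, upper, pop_size = 30L, max_iter = 50L,
                         ST = 0.8, PD = 0.2, SD = 0.15,
                         elite_fraction = 0.10, epsilon = 1e-10,
                         beta_mean = 1, use_elite = TRUE,
                         tol = 1e-6, patience = 20L, rng_seed = 1L) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper))
    stop_input("bounds must satisfy lower < upper per dimension")
  if (PD <= 0 || PD >= 1) stop_input("PD must be in (0, 1)")
  if (SD < 0.10 || SD > 0.20)
    stop_input("SD must be in [0.10, 0.20]")
  if (ST <= 0.5 || ST > 1) stop_input("ST must be in (0.5, 1]")
  if (epsilon <= 0) stop_input("epsilon must be positive")
  structure(list(lower = lower, upper = upper, d = length(lower),
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), ST = ST, PD = PD, SD = SD,
                 elite_fraction = elite_fraction, epsilon = epsilon,
                 beta_mean = beta_mean, use_elite = isTRUE(use_elite),
                 tol = tol, patience = as.integer(patience),
                 rng_seed = as.integer(rng_seed)),
            class = "JyssaConfig")
}

clamp_rows <- function(X, lower, upper) {
  for (j in seq_len(ncol(X)))
    X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
  X
}

eval_fitness <- function(fitness_fn, X) {
  f <- apply(X, 1, fitness_fn)
  if (any(!is.finite(f))) {
    i <- which(!is.finite(f))[1]
    stop_input("non-finite fitness at position (",
               paste(signif(X[i, ], 6), collapse = ", "), ")")
  }
  as.numeric(f)
}

n_producers <- function(config)
  max(1L, min(config$pop_size - 1L, round(config$PD * config$pop_size)))

# Assign producer/follower roles by fitness rank (best individuals produce)
# and refresh the best/worst bookkeeping.
reassign_roles <- function(pop, config) {
  ord <- order(pop$f)
  roles <- rep("follower", config$pop_size)
  roles[ord[seq_len(n_producers(config))]] <- "producer"
  pop$roles <- roles
  pop$rank <- match(seq_len(config$pop_size), ord) # 1 = fittest
  ib <- ord[1]; iw <- ord[config$pop_size]
  pop$Xbest <- pop$X[ib, ]; pop$fg <- pop$f[ib]
  pop$Xworst <- pop$X[iw, ]; pop$fw <- pop$f[iw]
  pop
}

# Opposition candidates inside the elite set's dynamic box [da, db]:
# X' = k (da + db) - X with fresh k ~ U(0,1); out-of-box coordinates are
# resampled uniformly inside the box.
opposition_candidate <- function(x, da, db) {
  k <- runif(1)
  cand <- k * (da + db) - x
  oob <- cand < da | cand > db
  if (any(oob)) {
    w <- db[oob] - da[oob]
    cand[oob] <- ifelse(w > 0, da[oob] + runif(sum(oob)) * w, da[oob])
  }
  cand
}

#' Initialize the sparrow population
#'
#' Positions are drawn uniformly in the bounds; when the elite-reverse
#' strategy is enabled, the best `elite_fraction` of the initial draw also
#' get an opposition candidate (mirrored in the elite set's bounding box)
#' that replaces them when strictly fitter. Roles are assigned by fitness
#' rank. Uses the current RNG state; seed management belongs to
#' [jyssa_optimize()].
#'
#' @param config a [jyssa_config()].
#' @param fitness_fn function mapping a position vector to a finite scalar.
#' @return A `Population` list (`X`, `f`, `roles`, `rank`, `Xbest`, `fg`,
#'   `Xworst`, `fw`, `t`).
#' @export
init_population <- function(config, fitness_fn) {
  n <- config$pop_size; d <- config$d
  X <- matrix(runif(n * d), n, d)
  X <- sweep(sweep(X, 2, config$upper - config$lower, `*`), 2,
             config$lower, `+`)
  f <- eval_fitness(fitness_fn, X)
  if (config$use_elite) {
    ne <- max(1L, ceiling(config$elite_fraction * n))
    elite <- order(f)[seq_len(ne)]
    da <- apply(X[elite, , drop = FALSE], 2, min)
    db <- apply(X[elite, , drop = FALSE], 2, max)
    for (i in elite) {
      cand <- opposition_candidate(X[i, ], da, db)
      fc <- fitness_fn(cand)
      if (is.finite(fc) && fc < f[i]) {
        X[i, ] <- cand; f[i] <- fc
      }
    }
  }
  pop <- list(X = X, f = f, t = 0L)
  reassign_roles(pop, config)
}

#' Producer (explorer) position update
#'
#' One alarm value R2 ~ U(0, 1) is drawn per iteration. Below the safety
#' threshold ST each producer contracts multiplicatively,
#' `X * exp(-i / (alpha * max_iter))` with its fitness rank `i` and a fresh
#' `alpha ~ U(0, 1]`; otherwise it takes an isotropic Gaussian step
#' `X + Q * L` with scalar `Q ~ N(0, 1)`. Positions are clamped to bounds.
#'
#' @param pop population from [init_population()] (roles current).
#' @param config a [jyssa_config()].
#' @return Updated population (fitness values not yet re-evaluated).
#' @export
producer_update <- function(pop, config) {
  R2 <- runif(1)
  prod_idx <- which(pop$roles == "producer")
  prod_idx <- prod_idx[order(pop$rank[prod_idx])]
  for (i in seq_along(prod_idx)) {
    p <- prod_idx[i]
    if (R2 < config$ST) {
      alpha <- 1 - runif(1) # U(0, 1]
      pop$X[p, ] <- pop$X[p, ] * exp(-i / (alpha * config$max_iter))
    } else {
      pop$X[p, ] <- pop$X[p, ] + rnorm(1)
    }
  }
  pop$X <- clamp_rows(pop$X, config$lower, config$upper)
  pop
}

#' Follower (scrounger) position update
#'
#' Followers ranked in the worse half of the population take a starvation
#' jump `Q * exp((Xworst - X) / i^2)`; the better half plunder the best
#' producer's position Xp: `Xp + |X - Xp| . A+ . L` with a random +/-1 row
#' A and its pseudo-inverse `A+ = A' (A A')^{-1}` (= `A'/d`).
#'
#' @inheritParams producer_update
#' @return Updated population.
#' @export
follower_update <- function(pop, config) {
  d <- config$d
  prod_idx <- which(pop$roles == "producer")
  Xp <- pop$X[prod_idx[which.min(pop$f[prod_idx])], ]
  n <- config$pop_size
  fol_idx <- which(pop$roles == "follower")
  for (p in fol_idx) {
    i <- pop$rank[p]
    if (i > n / 2) {
      pop$X[p, ] <- rnorm(1) * exp((pop$Xworst - pop$X[p, ]) / i^2)
    } else {
      A <- sample(c(-1, 1), d, replace = TRUE)
      s <- sum(abs(pop$X[p, ] - Xp) * A) / d
      pop$X[p, ] <- Xp + s
    }
  }
  pop$X <- clamp_rows(pop$X, config$lower, config$upper)
  pop
}

#' Scout (danger-aware) position update
#'
#' `round(SD * n)` individuals are resampled as scouts each iteration. A
#' scout with worse-than-best fitness moves toward the global best,
#' `Xbest + beta * |X - Xbest|` (`beta ~ N(beta_mean, 1)`); a scout already
#' at the best fitness jitters relative to the worst,
#' `X + K * |X - Xworst| / ((fi - fw) + epsilon)` with `K ~ U(-1, 1)`.
#'
#' @inheritParams producer_update
#' @param scouts optional explicit scout index vector (tests); default
#'   resampled at random.
#' @return Updated population.
#' @export
scout_update <- function(pop, config, scouts = NULL) {
  n <- config$pop_size
  if (is.null(scouts))
    scouts <- sample.int(n, max(1L, round(config$SD * n)))
  for (p in scouts) {
    if (pop$f[p] > pop$fg) {
      beta <- rnorm(1, mean = config$beta_mean, sd = 1)
      pop$X[p, ] <- pop$Xbest + beta * abs(pop$X[p, ] - pop$Xbest)
    } else {
      K <- runif(1, -1, 1)
      pop$X[p, ] <- pop$X[p, ] +
        K * (abs(pop$X[p, ] - pop$Xworst) / ((pop$f[p] - pop$fw) +
                                               config$epsilon))
    }
  }
  pop$X <- clamp_rows(pop$X, config$lower, config$upper)
  pop
}

#' Elite reverse (opposition) step
#'
#' The best `ceil(elite_fraction * n)` individuals define dynamic
#' per-dimension boundaries `[da, db]`; each elite member's opposition
#' candidate `k (da + db) - X` (fresh `k ~ U(0,1)`, out-of-box coordinates
#' resampled inside the box) replaces it only when strictly fitter (greedy
#' selection), so the best fitness can never degrade.
#'
#' @inheritParams producer_update
#' @param fitness_fn fitness function (candidates must be evaluated).
#' @return Updated population with refreshed fitness bookkeeping.
#' @export
elite_reverse <- function(pop, config, fitness_fn) {
  n <- config$pop_size
  ne <- max(1L, ceiling(config$elite_fraction * n))
  elite <- order(pop$f)[seq_len(ne)]
  da <- apply(pop$X[elite, , drop = FALSE], 2, min)
  db <- apply(pop$X[elite, , drop = FALSE], 2, max)
  for (i in elite) {
    cand <- opposition_candidate(pop$X[i, ], da, db)
    fc <- fitness_fn(cand)
    if (is.finite(fc) && fc < pop$f[i]) {
      pop$X[i, ] <- cand; pop$f[i] <- fc
    }
  }
  reassign_roles(pop, config)
}

#' Run the sparrow search optimizer
#'
#' The full loop: initialize (with elite opposition when enabled), then per
#' iteration reassign roles by fitness rank, apply producer, follower and
#' scout updates, re-evaluate fitness, apply the elite-reverse step, and
#' track the best-so-far solution. Stops at `max_iter` or when the best
#' fitness improves by less than `tol` for `patience` consecutive
#' iterations. The whole run is reproducible bit-for-bit from
#' `config$rng_seed`.
#'
#' @param fitness_fn function from a length-`d` position to a finite scalar
#'   (deterministic; manage any internal randomness with your own fixed
#'   seed).
#' @param config a [jyssa_config()].
#' @return List with `best_position`, `best_fitness`, `history`
#'   (best-so-far fitness per iteration, non-increasing), `iterations`, and
#'   `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- jyssa_config(lower = c(-10, -10), upper = c(10, 10), rng_seed = 7)
#' res <- jyssa_optimize(sphere, cfg)
#' res$best_fitness
#' @export
jyssa_optimize <- function(fitness_fn, config) {
  stopifnot(inherits(config, "JyssaConfig"))
  with_seed(config$rng_seed, {
    pop <- init_population(config, fitness_fn)
    ib <- which.min(pop$f)
    best_x <- pop$X[ib, ]; best_f <- pop$f[ib]
    history <- numeric(0)
    stall <- 0L
    for (t in seq_len(config$max_iter)) {
      pop$t <- t
      pop <- reassign_roles(pop, config)
      pop <- producer_update(pop, config)
      pop <- follower_update(pop, config)
      pop <- scout_update(pop, config)
      pop$f <- eval_fitness(fitness_fn, pop$X)
      pop <- reassign_roles(pop, config)
      if (config$use_elite)
        pop <- elite_reverse(pop, config, fitness_fn)
      if (pop$fg < best_f - config$tol) stall <- 0L else stall <- stall + 1L
      if (pop$fg < best_f) {
        best_f <- pop$fg; best_x <- pop$Xbest
      }
      history <- c(history, best_f)
      if (stall >= config$patience) break
    }
    list(best_position = best_x, best_fitness = best_f, history = history,
         iterations = length(history), config = config)
  })
}
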