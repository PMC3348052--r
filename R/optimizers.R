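#' Optimizer configuration
#'
#' Hyperparameters shared by the three population optimizers. The velocity
#' bound `v_max = 0.2` is the value conventionally used with PSO on this
#' problem; the remaining defaults are canonical literature settings
#' (inertia-form PSO with constriction-equivalent coefficients, BLX-0.5
#' crossover with tournament selection for the GA part, DE/rand/1/bin).
#'
#' @param population number of individuals (>= 2; >= 4 for DE).
#' @param generations generation budget.
#' @param ga_fraction `r`, the fraction of the population discarded each
#'   generation and rebuilt by GA operators in the hybrid GA-PSO; the best
#'   `(1-r)` fraction advances through PSO.
#' @param tournament_size GA tournament size.
#' @param inertia,cognitive,social PSO coefficients `w`, `c1`, `c2`.
#' @param v_max componentwise velocity bound.
#' @param crossover_rate BLX-0.5 blend crossover probability.
#' @param mutation_rate per-component Gaussian mutation probability;
#'   `NULL` means `1 / n_params`.
#' @param mutation_sigma_frac mutation s.d. as a fraction of the active
#'   bound width.
#' @param de_F,de_CR differential evolution scale factor and crossover rate.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(population = 200L, generations = 1000L,
                             ga_fraction = 0.5, tournament_size = 3L,
                             inertia = 0.729, cognitive = 1.49445,
                             social = 1.49445, v_max = 0.2,
                             crossover_rate = 0.9, mutation_rate = NULL,
                             mutation_sigma_frac = 0.1,
                             de_F = 0.5, de_CR = 0.9) {
  population <- as.integer(population)
  if (population < 2L) stop("population must be at least 2")
  if (v_max <= 0) stop("v_max must be positive")
  if (ga_fraction < 0 || ga_fraction > 1) stop("ga_fraction must be in [0, 1]")
  structure(list(population = population,
                 generations = as.integer(generations),
                 ga_fraction = ga_fraction,
                 tournament_size = as.integer(tournament_size),
                 inertia = inertia, cognitive = cognitive, social = social,
                 v_max = v_max, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma_frac = mutation_sigma_frac,
                 de_F = de_F, de_CR = de_CR),
            class = "optimizer_config")
}

#' Per-parameter box constraints
#'
#' @param low,high numeric vectors of bounds, `low <= high`.
#' @param tag per-parameter tag, one of `"sensitive"`, `"insensitive"`,
#'   `"unconstrained"`.
#' @param labels optional parameter labels used as row names.
#' @return A `bound_set`: data frame with columns `low`, `high`, `tag`.
#' @export
bound_set <- function(low, high, tag = "unconstrained", labels = NULL) {
  stopifnot(length(low) == length(high))
  if (any(low > high)) stop("bounds must satisfy low <= high")
  tag <- rep_len(tag, length(low))
  if (!all(tag %in% c("sensitive", "insensitive", "unconstrained")))
    stop("unknown bound tag")
  out <- data.frame(low = as.numeric(low), high = as.numeric(high),
                    tag = tag, stringsAsFactors = FALSE)
  if (!is.null(labels)) rownames(out) <- labels
  class(out) <- c("bound_set", "data.frame")
  out
}

#' Box constraints spanning the initial search region
#'
#' @param region a [search_region()].
#' @param n_genes number of genes.
#' @return A [bound_set()] over all `2N(N+1)` parameters (kinetic orders get
#'   the kinetic region, rate constants the rate region), tagged
#'   `unconstrained`.
#' @export
bounds_from_region <- function(region, n_genes) {
  info <- param_info(n_genes)
  kin <- info$kind == "kinetic"
  bound_set(ifelse(kin, region$kinetic[1], region$rate[1]),
            ifelse(kin, region$kinetic[2], region$rate[2]),
            labels = info$label)
}

# Fold positions into [low, high] by reflection; returns the folded matrix
# and a logical matrix of components that moved (the caller negates their
# velocities). Degenerate zero-width bounds collapse to `low`.
reflect_into_bounds <- function(X, low, high) {
  n <- nrow(X); m <- ncol(X)
  Lo <- matrix(low, n, m, byrow = TRUE)
  W <- matrix(high - low, n, m, byrow = TRUE)
  Y <- X - Lo
  pos <- W > 0
  Y[pos] <- Y[pos] %% (2 * W[pos])
  over <- pos & (Y > W)
  Y[over] <- 2 * W[over] - Y[over]
  Y[!pos] <- 0
  Xr <- Lo + Y
  list(X = Xr, changed = Xr != X)
}

# uniform population inside bounds, velocities in +-v_max, evaluated
init_population <- function(evaluator, bounds, config) {
  m <- nrow(bounds)
  n <- config$population
  X <- matrix(runif(n * m), n, m)
  X <- sweep(sweep(X, 2L, bounds$high - bounds$low, "*"), 2L, bounds$low, "+")
  V <- matrix(runif(n * m, -config$v_max, config$v_max), n, m)
  fit <- evaluate_batch(evaluator, X)
  b <- which.min(fit)
  list(X = X, V = V, fit = fit, pbX = X, pbF = fit,
       best_x = X[b, ], best_f = fit[b], bounds = bounds,
       n_evals = n)
}

# keep the best-ever solution present: if the current population lost it,
# overwrite the worst slot
inject_elite <- function(state) {
  if (min(state$fit) > state$best_f) {
    w <- which.max(state$fit)
    state$X[w, ] <- state$best_x
    state$fit[w] <- state$best_f
    state$pbX[w, ] <- state$best_x
    state$pbF[w] <- state$best_f
  }
  state
}

update_best <- function(state) {
  b <- which.min(state$pbF)
  if (state$pbF[b] < state$best_f) {
    state$best_f <- state$pbF[b]
    state$best_x <- state$pbX[b, ]
  }
  state
}

# canonical PSO update of the rows `idx` of the population
pso_update_rows <- function(state, idx, config) {
  X <- state$X[idx, , drop = FALSE]
  V <- state$V[idx, , drop = FALSE]
  pbX <- state$pbX[idx, , drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  Gb <- matrix(state$best_x, n, m, byrow = TRUE)
  r1 <- matrix(runif(n * m), n, m)
  r2 <- matrix(runif(n * m), n, m)
  V <- config$inertia * V + config$cognitive * r1 * (pbX - X) +
    config$social * r2 * (Gb - X)
  V <- pmin(pmax(V, -config$v_max), config$v_max)
  Xn <- X + V
  ref <- reflect_into_bounds(Xn, state$bounds$low, state$bounds$high)
  V[ref$changed] <- -V[ref$changed]
  state$X[idx, ] <- ref$X
  state$V[idx, ] <- V
  state
}

#' One particle swarm generation
#'
#' Canonical PSO velocity/position update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, `x <- x + v`, with the
#' velocity clamped componentwise to `+-v_max` and positions reflected back
#' into the active bounds (the reflected components' velocities are
#' negated). Personal and global bests are refreshed after evaluation, and
#' the best-ever solution is kept in the population (elitism).
#'
#' @param state population state as produced by [ea_optimize()] internals:
#'   a list with `X`, `V`, `fit`, `pbX`, `pbF`, `best_x`, `best_f`,
#'   `bounds`, `n_evals`.
#' @param evaluator fitness oracle ([make_evaluator()]).
#' @param config an [optimizer_config()].
#' @return Updated state.
#' @export
pso_step <- function(state, evaluator, config) {
  state <- pso_update_rows(state, seq_len(nrow(state$X)), config)
  state$fit <- evaluate_batch(evaluator, state$X)
  state$n_evals <- state$n_evals + nrow(state$X)
  imp <- state$fit < state$pbF
  state$pbX[imp, ] <- state$X[imp, , drop = FALSE]
  state$pbF[imp] <- state$fit[imp]
  state <- update_best(state)
  inject_elite(state)
}

#' GA offspring from an elite pool
#'
#' Tournament selection picks parent pairs from the elites; each offspring
#' is produced by BLX-0.5 blend crossover (with probability
#' `crossover_rate`, else a copy of the first parent) followed by
#' per-component Gaussian mutation (probability `mutation_rate`, s.d.
#' `mutation_sigma_frac` of the bound width), and reflected into `bounds`.
#'
#' @param elite_X matrix of elite positions (one per row).
#' @param elite_f their fitness values.
#' @param n_children number of offspring.
#' @param bounds active [bound_set()].
#' @param config an [optimizer_config()].
#' @return `n_children x n_params` matrix of offspring positions.
#' @export
ga_offspring <- function(elite_X, elite_f, n_children, bounds, config) {
  np <- nrow(elite_X); m <- ncol(elite_X)
  if (np < 1L) stop("elite pool is empty")
  ts <- min(config$tournament_size, np)
  # tournaments draw ts distinct contestants; the fittest contestant wins
  pick <- function(k) {
    vapply(seq_len(k), function(.) {
      r <- if (ts == np) seq_len(np) else sample.int(np, ts)
      r[which.min(elite_f[r])]
    }, integer(1))
  }
  p1 <- pick(n_children); p2 <- pick(n_children)
  A <- elite_X[p1, , drop = FALSE]; B <- elite_X[p2, , drop = FALSE]
  C <- A
  do_cx <- runif(n_children) < config$crossover_rate
  if (any(do_cx)) {
    lo <- pmin(A, B); hi <- pmax(A, B); d <- hi - lo
    U <- matrix(runif(n_children * m), n_children, m)
    blend <- (lo - 0.5 * d) + U * (2 * d)
    C[do_cx, ] <- blend[do_cx, , drop = FALSE]
  }
  pm <- if (is.null(config$mutation_rate)) 1 / m else config$mutation_rate
  if (pm > 0) {
    mut <- matrix(runif(n_children * m) < pm, n_children, m)
    if (any(mut)) {
      sig <- matrix(config$mutation_sigma_frac * (bounds$high - bounds$low),
                    n_children, m, byrow = TRUE)
      noise <- matrix(rnorm(n_children * m), n_children, m) * sig
      C[mut] <- C[mut] + noise[mut]
    }
  }
  reflect_into_bounds(C, bounds$low, bounds$high)$X
}

#' One hybrid GA-PSO ("breeding swarms") generation
#'
#' Individuals are ranked by fitness. The best `(1 - r)` fraction is
#' preserved and enhanced by the PSO update; the worst `r` fraction is
#' discarded and replaced by GA offspring bred (tournament selection, blend
#' crossover, Gaussian mutation) from the pre-PSO elites. Population size is
#' conserved and the best-ever solution is never lost.
#'
#' @inheritParams pso_step
#' @return Updated state.
#' @export
gapso_generation <- function(state, evaluator, config) {
  n <- nrow(state$X)
  r <- config$ga_fraction
  n_keep <- max(1L, min(n, round((1 - r) * n)))
  n_child <- n - n_keep
  if (n_child == 0L) return(pso_step(state, evaluator, config))
  ord <- order(state$fit)
  keep <- ord[seq_len(n_keep)]
  elite_X <- state$X[keep, , drop = FALSE]
  elite_f <- state$fit[keep]
  children <- ga_offspring(elite_X, elite_f, n_child, state$bounds, config)
  # reorder state to elites-first, then PSO-update the elite rows
  state$X <- state$X[ord, , drop = FALSE]
  state$V <- state$V[ord, , drop = FALSE]
  state$fit <- state$fit[ord]
  state$pbX <- state$pbX[ord, , drop = FALSE]
  state$pbF <- state$pbF[ord]
  state <- pso_update_rows(state, seq_len(n_keep), config)
  m <- ncol(state$X)
  state$X[n_keep + seq_len(n_child), ] <- children
  state$V[n_keep + seq_len(n_child), ] <-
    matrix(runif(n_child * m, -config$v_max, config$v_max), n_child, m)
  state$fit <- evaluate_batch(evaluator, state$X)
  state$n_evals <- state$n_evals + n
  ek <- seq_len(n_keep)
  imp <- ek[state$fit[ek] < state$pbF[ek]]
  state$pbX[imp, ] <- state$X[imp, , drop = FALSE]
  state$pbF[imp] <- state$fit[imp]
  ck <- n_keep + seq_len(n_child)
  state$pbX[ck, ] <- state$X[ck, , drop = FALSE]
  state$pbF[ck] <- state$fit[ck]
  state <- update_best(state)
  inject_elite(state)
}

#' One differential evolution generation (DE/rand/1/bin)
#'
#' For every target vector a mutant `x_r1 + F (x_r2 - x_r3)` is built from
#' three distinct other individuals, crossed binomially with rate `CR` (one
#' component always comes from the mutant), reflected into bounds, and kept
#' only if not worse than the target (greedy selection), so no slot ever
#' worsens.
#'
#' @inheritParams pso_step
#' @return Updated state.
#' @export
de_generation <- function(state, evaluator, config) {
  n <- nrow(state$X); m <- ncol(state$X)
  if (n < 4L) stop("differential evolution needs a population of at least 4")
  r1 <- integer(n); r2 <- integer(n); r3 <- integer(n)
  for (i in seq_len(n)) {
    r <- sample.int(n - 1L, 3L)
    r <- ifelse(r >= i, r + 1L, r)
    r1[i] <- r[1]; r2[i] <- r[2]; r3[i] <- r[3]
  }
  Mnt <- state$X[r1, , drop = FALSE] +
    config$de_F * (state$X[r2, , drop = FALSE] - state$X[r3, , drop = FALSE])
  mask <- matrix(runif(n * m) < config$de_CR, n, m)
  jr <- sample.int(m, n, replace = TRUE)
  mask[cbind(seq_len(n), jr)] <- TRUE
  Trial <- state$X
  Trial[mask] <- Mnt[mask]
  Trial <- reflect_into_bounds(Trial, state$bounds$low, state$bounds$high)$X
  tf <- evaluate_batch(evaluator, Trial)
  state$n_evals <- state$n_evals + n
  take <- tf <= state$fit
  state$X[take, ] <- Trial[take, , drop = FALSE]
  state$fit[take] <- tf[take]
  state$pbX <- state$X
  state$pbF <- state$fit
  state <- update_best(state)
  state
}

#' Run a population optimizer over bounded parameter vectors
#'
#' Drives `generations` iterations of the chosen method from a random
#' population inside `bounds`. The incremental-evolution controller attaches
#' through `hooks$post`, called after every generation with `(state, gen)`
#' and expected to return a (possibly modified) state — this is where
#' sensitivity analysis, bound updates and exploration restarts happen.
#'
#' @param evaluator fitness oracle from [make_evaluator()].
#' @param method `"pso"`, `"gapso"` or `"de"`.
#' @param bounds initial [bound_set()].
#' @param config an [optimizer_config()].
#' @param seed optional integer seed (`set.seed` is called when supplied);
#'   a fixed seed makes the run bit-reproducible.
#' @param hooks optional list with function `post(state, gen) -> state`.
#' @return List of class `ea_run`: `best` (vector), `best_fitness`,
#'   `history` (best-so-far fitness, length `generations + 1`),
#'   `history_mean` (population mean fitness), `n_evals`, `method`, `seed`,
#'   `config` and the final `state`.
#' @export
ea_optimize <- function(evaluator, method = c("gapso", "pso", "de"), bounds,
                        config = optimizer_config(), seed = NULL,
                        hooks = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  step <- switch(method, pso = pso_step, gapso = gapso_generation,
                 de = de_generation)
  if (method == "de" && config$population < 4L)
    stop("differential evolution needs a population of at least 4")
  state <- init_population(evaluator, bounds, config)
  G <- config$generations
  history <- numeric(G + 1L)
  history_mean <- numeric(G + 1L)
  history[1L] <- state$best_f
  history_mean[1L] <- mean(state$fit)
  if (G >= 1L) for (gen in seq_len(G)) {
    state <- step(state, evaluator, config)
    if (!is.null(hooks$post)) state <- hooks$post(state, gen)
    history[gen + 1L] <- state$best_f
    history_mean[gen + 1L] <- mean(state$fit)
  }
  best <- state$best_x
  names(best) <- rownames(bounds)
  structure(list(best = best, best_fitness = state$best_f,
                 history = history, history_mean = history_mean,
                 n_evals = state$n_evals, method = method, seed = seed,
                 config = config, state = state),
            class = "ea_run")
}
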