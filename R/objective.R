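#' Relative squared-error fitness of a simulated series
#'
#' The objective minimized during inference:
#' \deqn{\sum_{i=1}^N \sum_{t=1}^T \left(\frac{x^a_i(t) - x^d_i(t)}{x^d_i(t)}\right)^2}
#' where \eqn{x^d} is the desired (target) series and \eqn{x^a} the series
#' produced by a candidate model. The value is zero exactly when the two
#' series agree. Target values with `|x^d| < denom_guard` are replaced by
#' `denom_guard` in the denominator only (the number of such substitutions is
#' recorded in the `n_guarded` attribute). A diverged prediction maps to the
#' fixed `penalty` so evolutionary searches always see finite, ordered
#' fitness.
#'
#' @param predicted,target [ss_series()] objects on the same gene set and
#'   time grid.
#' @param mean_form if `TRUE`, divide the sum by `N * T`. The plain sum is
#'   the default.
#' @param denom_guard floor applied to the denominator.
#' @param penalty fitness assigned to diverged predictions.
#' @return Non-negative numeric with attributes `diverged` and `n_guarded`.
#' @examples
#' s <- ss_series(matrix(c(1, 2), 1), c(0, 1))
#' p <- ss_series(matrix(c(2, 4), 1), c(0, 1))
#' ss_fitness(p, s) # ((2-1)/1)^2 + ((4-2)/2)^2 = 2
#' @export
ss_fitness <- function(predicted, target, mean_form = FALSE,
                       denom_guard = 1e-6, penalty = 1e9) {
  stopifnot(inherits(predicted, "ss_series"), inherits(target, "ss_series"))
  if (!isTRUE(all.equal(predicted$times, target$times)))
    stop("predicted and target series are on different time grids")
  if (nrow(predicted$values) != nrow(target$values))
    stop("predicted and target series cover different gene sets")
  if (isTRUE(attr(predicted, "diverged")))
    return(structure(penalty, diverged = TRUE, n_guarded = 0L))
  d <- target$values
  guarded <- abs(d) < denom_guard
  d[guarded] <- denom_guard
  v <- sum(((predicted$values - target$values) / d)^2)
  if (mean_form) v <- v / length(d)
  structure(v, diverged = FALSE, n_guarded = sum(guarded))
}

#' Per-gene restriction of the fitness
#'
#' The objective is a plain sum over genes and time points, so the total
#' fitness equals the sum of `ss_fitness_gene` over all genes. Used with the
#' decoupled per-gene estimation of [ss_simulate_decoupled()].
#'
#' @param profile numeric vector of length `T` (gene `gene`'s simulated
#'   profile), e.g. from [ss_simulate_decoupled()].
#' @param target an [ss_series()].
#' @param gene gene index.
#' @inheritParams ss_fitness
#' @return Non-negative numeric with attributes as in [ss_fitness()].
#' @export
ss_fitness_gene <- function(profile, target, gene, mean_form = FALSE,
                            denom_guard = 1e-6, penalty = 1e9) {
  stopifnot(inherits(target, "ss_series"))
  profile <- as.numeric(profile)
  if (length(profile) != length(target$times))
    stop("profile length does not match the target time grid")
  if (gene < 1L || gene > nrow(target$values)) stop("invalid gene index")
  if (isTRUE(attr(profile, "diverged")) || any(!is.finite(profile)))
    return(structure(penalty, diverged = TRUE, n_guarded = 0L))
  d <- target$values[gene, ]
  guarded <- abs(d) < denom_guard
  d[guarded] <- denom_guard
  v <- sum(((profile - target$values[gene, ]) / d)^2)
  if (mean_form) v <- v / length(d)
  structure(v, diverged = FALSE, n_guarded = sum(guarded))
}

#' Build a fast fitness oracle for a target series
#'
#' Returns a function mapping a flat parameter vector (layout of
#' [param_info()]) to its fitness against `target`: the candidate model is
#' simulated from `x0` on the target grid and scored with the relative
#' squared-error objective. The returned function carries a `"batch"`
#' attribute, a vectorized form taking a matrix with one candidate per row;
#' both run in compiled code. This evaluator is what the optimizers and the
#' sensitivity analysis consume.
#'
#' @param target an [ss_series()] of desired expression profiles.
#' @param x0 initial condition for candidate simulations; defaults to the
#'   first column of `target` (values below `eps` are raised to `eps`).
#' @param substeps RK4 substeps per grid interval. The default of 5 trades a
#'   fitness bias of order 1e-4 on the bundled benchmarks for a large speed
#'   gain over the plotting-quality default of [ss_simulate()]; raise it when
#'   absolute fitness values near that scale matter.
#' @inheritParams ss_fitness
#' @inheritParams ss_simulate
#' @return A function `f(par) -> fitness` with attributes `batch` (matrix
#'   version), `n_genes`, `n_params`, `times` and `penalty`.
#' @export
make_evaluator <- function(target, x0 = NULL, substeps = 5L, eps = 1e-6,
                           guard = 1e6, penalty = 1e9, mean_form = FALSE,
                           denom_guard = 1e-6) {
  stopifnot(inherits(target, "ss_series"))
  n <- nrow(target$values)
  mu <- parameter_count(n)
  if (is.null(x0)) x0 <- target$values[, 1]
  x0 <- pmax(as.numeric(x0), eps)
  tv <- unname(target$values)
  denom <- tv
  denom[abs(denom) < denom_guard] <- denom_guard
  times <- target$times
  substeps <- as.integer(substeps)
  batch <- function(P) {
    P <- as.matrix(P)
    cpp_fitness_batch(P, n, tv, denom, x0, times, substeps, eps, guard,
                      penalty, mean_form)
  }
  f <- function(par) batch(matrix(par, nrow = 1L))[1L]
  attr(f, "batch") <- batch
  attr(f, "n_genes") <- n
  attr(f, "n_params") <- mu
  attr(f, "times") <- times
  attr(f, "penalty") <- penalty
  f
}

# batch form of an evaluator; falls back to row-wise apply for plain functions
evaluate_batch <- function(evaluator, P) {
  b <- attr(evaluator, "batch")
  if (is.function(b)) return(b(P))
  apply(P, 1L, evaluator)
}
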