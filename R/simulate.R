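#' Evaluate the S-system right-hand side at one state
#'
#' Returns the instantaneous rates \eqn{\alpha_i \prod_j x_j^{g_{ij}} -
#' \beta_i \prod_j x_j^{h_{ij}}}. The state is clamped to `eps` before
#' exponentiation (powers of nonpositive values are undefined for real
#' exponents); an exponent of 0 contributes a factor of 1.
#'
#' @param model an [ssystem()] model.
#' @param state numeric vector of `N` concentrations.
#' @param eps clamp floor applied before exponentiation.
#' @return Numeric vector of `N` rates.
#' @export
ss_derivative <- function(model, state, eps = 1e-6) {
  stopifnot(inherits(model, "ssystem"))
  state <- as.numeric(state)
  if (length(state) != model$n_genes)
    stop("state must have length ", model$n_genes)
  if (!all(is.finite(state))) stop("state contains non-finite values")
  lx <- log(pmax(state, eps))
  as.numeric(model$alpha * exp(model$g %*% lx) -
             model$beta * exp(model$h %*% lx))
}

#' Simulate an S-system on a time grid
#'
#' Integrates the coupled power-law ODEs with a fixed-step classical
#' Runge-Kutta (RK4) scheme, taking `substeps` internal steps per grid
#' interval. Integration is deterministic given the inputs. If any state
#' exceeds `guard` in magnitude (or becomes non-finite) the integration is
#' aborted and the returned series is flagged as diverged, with `NA` in the
#' unreached columns; [ss_fitness()] maps such series to a large penalty.
#'
#' @param model an [ssystem()] model.
#' @param x0 positive initial concentrations (length `N`).
#' @param times strictly increasing time grid (the first entry is the time of
#'   `x0`).
#' @param substeps internal RK4 steps per grid interval. The default of 40
#'   keeps the step-halving difference of the bundled benchmark trajectories
#'   below 1e-6.
#' @param eps clamp floor applied to the state before exponentiation only;
#'   the integration state itself is not clamped.
#' @param guard divergence guard on `|x|`.
#' @return An [ss_series()] on the requested grid, with attributes
#'   `diverged` (logical) and `completed` (number of grid points reached).
#' @examples
#' decay <- ssystem(alpha = 0, beta = 1, g = matrix(0), h = matrix(1))
#' s <- ss_simulate(decay, 1, seq(0, 1, by = 0.1))
#' max(abs(s$values - exp(-s$times))) # closed-form exponential decay
#' @export
ss_simulate <- function(model, x0, times, substeps = 40L, eps = 1e-6,
                        guard = 1e6) {
  stopifnot(inherits(model, "ssystem"))
  x0 <- as.numeric(x0)
  times <- as.numeric(times)
  if (length(x0) != model$n_genes) stop("x0 must have length ", model$n_genes)
  if (any(!is.finite(x0)) || any(x0 <= 0)) stop("x0 must be positive")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  if (substeps < 1L) stop("substeps must be >= 1")
  res <- cpp_simulate(model$alpha, model$beta, model$g, model$h,
                      x0, times, as.integer(substeps), eps, guard)
  out <- ss_series(res$values, times, model$gene_names)
  attr(out, "diverged") <- res$diverged
  attr(out, "completed") <- res$completed
  out
}

#' Positive steady state of an S-system
#'
#' At a steady state the production and degradation terms balance, which in
#' log-space is the linear system `(h - g) log(x) = log(alpha / beta)`.
#' Requires strictly positive rate constants and a non-singular `h - g`.
#' The returned state may be dynamically unstable; check the Jacobian or
#' simulate from a perturbation.
#'
#' @param model an [ssystem()] model with `alpha, beta > 0`.
#' @return Numeric vector of `N` positive steady-state concentrations.
#' @export
ss_steady_state <- function(model) {
  stopifnot(inherits(model, "ssystem"))
  if (any(model$alpha <= 0) || any(model$beta <= 0))
    stop("a positive steady state needs strictly positive rate constants")
  y <- solve(model$h - model$g, log(model$alpha / model$beta))
  setNames(exp(y), model$gene_names)
}

#' Simulate one gene's equation against observed profiles (decoupled form)
#'
#' Decoupled S-system estimation integrates only gene `i`'s ODE, substituting
#' the observed time courses of all other genes (linearly interpolated
#' between samples) for `x_j(t)`, `j != i`. This decomposes a tightly coupled
#' system into independent one-dimensional problems, one per gene, so each
#' gene can be inferred separately.
#'
#' @param model an [ssystem()] model (only row `gene` of its parameters is
#'   used).
#' @param gene gene index `i` to integrate.
#' @param observed an [ss_series()] covering all genes on the full grid.
#' @param x0_i positive initial value for gene `i`; defaults to the observed
#'   first value.
#' @inheritParams ss_simulate
#' @return Numeric vector of length `T` (gene `i`'s profile aligned to
#'   `observed$times`), with `diverged`/`completed` attributes as in
#'   [ss_simulate()].
#' @export
ss_simulate_decoupled <- function(model, gene, observed,
                                  x0_i = observed$values[gene, 1],
                                  substeps = 40L, eps = 1e-6, guard = 1e6) {
  stopifnot(inherits(model, "ssystem"), inherits(observed, "ss_series"))
  n <- model$n_genes
  if (nrow(observed$values) != n)
    stop("observed series must cover all ", n, " genes")
  if (length(gene) != 1L || gene < 1L || gene > n) stop("invalid gene index")
  if (!is.finite(x0_i) || x0_i <= 0) stop("x0_i must be positive")
  times <- observed$times
  interp <- lapply(seq_len(n), function(j)
    approxfun(times, observed$values[j, ], rule = 2))
  gi <- model$g[gene, ]; hi <- model$h[gene, ]
  ai <- model$alpha[gene]; bi <- model$beta[gene]
  deriv_i <- function(t, xi) {
    x <- vapply(interp, function(f) f(t), numeric(1))
    x[gene] <- xi
    lx <- log(pmax(x, eps))
    ai * exp(sum(gi * lx)) - bi * exp(sum(hi * lx))
  }
  T_ <- length(times)
  out <- rep(NA_real_, T_)
  out[1] <- xi <- x0_i
  completed <- 1L
  for (t in 2:T_) {
    dt <- (times[t] - times[t - 1]) / substeps
    for (s in seq_len(substeps)) {
      t0 <- times[t - 1] + (s - 1) * dt
      k1 <- deriv_i(t0, xi)
      k2 <- deriv_i(t0 + dt / 2, xi + dt / 2 * k1)
      k3 <- deriv_i(t0 + dt / 2, xi + dt / 2 * k2)
      k4 <- deriv_i(t0 + dt, xi + dt * k3)
      xi <- xi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!is.finite(xi) || abs(xi) > guard) {
        attr(out, "diverged") <- TRUE
        attr(out, "completed") <- completed
        return(out)
      }
    }
    out[t] <- xi
    completed <- completed + 1L
  }
  attr(out, "diverged") <- FALSE
  attr(out, "completed") <- completed
  out
}
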