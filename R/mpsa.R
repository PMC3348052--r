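#' Configuration for the modified multi-parameter sensitivity analysis
#'
#' @param n_samples Monte Carlo draws per parameter (500 by convention).
#' @param n_bins number of equal-width histogram intervals (10 by
#'   convention).
#' @param threshold_multiplier the acceptability threshold `C_r` is this
#'   multiple of the best available objective value (3 by convention).
#' @param range_fraction fraction of the search region's upper magnitude
#'   used as the half-width of each parameter's sampling range (1/3 by
#'   convention; see [parameter_range()]).
#' @param best_scope where "best available objective value" comes from:
#'   `"batch"` (default) uses the minimum over the current parameter's
#'   `n_samples` evaluations; `"run"` additionally includes the fitness of
#'   the base vector (the population-wide best when called from the
#'   inference loop).
#' @return Object of class `mpsa_config`.
#' @export
mpsa_config <- function(n_samples = 500L, n_bins = 10L,
                        threshold_multiplier = 3, range_fraction = 1 / 3,
                        best_scope = c("batch", "run")) {
  best_scope <- match.arg(best_scope)
  n_samples <- as.integer(n_samples); n_bins <- as.integer(n_bins)
  if (n_bins < 2L || n_samples < n_bins)
    stop("need n_samples >= n_bins >= 2")
  if (threshold_multiplier <= 1) stop("threshold_multiplier must exceed 1")
  if (range_fraction <= 0) stop("range_fraction must be positive")
  structure(list(n_samples = n_samples, n_bins = n_bins,
                 threshold_multiplier = threshold_multiplier,
                 range_fraction = range_fraction, best_scope = best_scope),
            class = "mpsa_config")
}

#' Sampling range for one parameter
#'
#' The range is the current value plus/minus `fraction` of the upper
#' magnitude of the parameter's initial search region: with the conventional
#' regions this is +-1.0 for kinetic orders (\[-3, 3\]) and +-10/3 for rate
#' constants (\[0, 10\]). A kinetic order currently at 0.59 therefore gets
#' the range (-0.41, 1.59). Ranges are deliberately not clipped back into
#' the search region.
#'
#' @param kind `"kinetic"` or `"rate"`.
#' @param value current parameter value (range midpoint).
#' @param region a [search_region()].
#' @param fraction half-width as a fraction of the region's upper bound.
#' @return Numeric `c(low, high)`.
#' @examples
#' parameter_range("kinetic", 0.59) # c(-0.41, 1.59)
#' @export
parameter_range <- function(kind, value, region = search_region(),
                            fraction = 1 / 3) {
  if (!kind %in% c("kinetic", "rate"))
    stop("kind must be \"kinetic\" or \"rate\"")
  if (fraction <= 0) stop("fraction must be positive")
  amount <- fraction * abs(region[[kind]][2])
  c(value - amount, value + amount)
}

#' Uniform Monte Carlo draws within a range
#'
#' @param range numeric `c(low, high)` with `low < high`.
#' @param n number of draws.
#' @return `n` i.i.d. uniform values; reproducible under a fixed seed.
#' @export
sample_values <- function(range, n) {
  if (range[1] >= range[2]) stop("range must satisfy low < high")
  runif(n, range[1], range[2])
}

#' Acceptability threshold C_r
#'
#' `C_r` is a multiple of the best available objective value (the triple by
#' convention): a best of 0.52 gives a threshold of 1.56.
#'
#' @param best_fitness best (minimum) objective value available.
#' @param multiplier threshold multiple.
#' @return `multiplier * best_fitness`.
#' @export
acceptability_threshold <- function(best_fitness, multiplier = 3) {
  if (!is.finite(best_fitness) || best_fitness < 0)
    stop("best_fitness must be a non-negative number")
  multiplier * best_fitness
}

#' Split sampled fitness values at the acceptability threshold
#'
#' A sample is unacceptable if its objective value is strictly greater than
#' `c_r`; values exactly at the threshold are acceptable.
#'
#' @param fitnesses numeric vector of objective values.
#' @param c_r acceptability threshold.
#' @return List with integer index sets `acceptable` and `unacceptable`.
#' @export
classify_acceptable <- function(fitnesses, c_r) {
  if (any(!is.finite(fitnesses))) stop("fitnesses must be finite")
  acc <- fitnesses <= c_r
  list(acceptable = which(acc), unacceptable = which(!acc))
}

# histogram counts on n_bins equal-width intervals over [low, high];
# left-closed/right-open, last interval right-closed
bin_counts <- function(values, range, n_bins) {
  if (length(values) == 0L) return(integer(n_bins))
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  tabulate(idx, nbins = n_bins)
}

#' Cumulative-frequency correlation sensitivity score
#'
#' The sampled values of one parameter are split into acceptable and
#' unacceptable sets, each binned into `n_bins` equal intervals over the
#' sampling range, and each histogram is turned into a cumulative relative
#' frequency vector (normalized by its own total). The sensitivity is the
#' Pearson correlation of the two cumulative vectors: values near 1 mean the
#' acceptable and unacceptable distributions are indistinguishable
#' (insensitive parameter); low values mean acceptability depends strongly
#' on where the parameter sits (sensitive parameter).
#'
#' Degenerate cases use sentinels that preserve the "low = sensitive"
#' ordering: an empty acceptable set scores -1 (maximally sensitive), an
#' empty unacceptable set scores +1, and constant cumulative vectors (all
#' mass in the first bin) score +1. The `degenerate` attribute flags these.
#'
#' @param acceptable,unacceptable numeric vectors of sampled parameter
#'   values in each class.
#' @param range the sampling range `c(low, high)`.
#' @param n_bins number of intervals.
#' @return Sensitivity in \[-1, 1\] with attribute `degenerate`.
#' @export
cf_correlation <- function(acceptable, unacceptable, range, n_bins = 10L) {
  if (length(acceptable) == 0L)
    return(structure(-1, degenerate = TRUE))
  if (length(unacceptable) == 0L)
    return(structure(1, degenerate = TRUE))
  ca <- cumsum(bin_counts(acceptable, range, n_bins)) / length(acceptable)
  cu <- cumsum(bin_counts(unacceptable, range, n_bins)) / length(unacceptable)
  if (stats::sd(ca) == 0 || stats::sd(cu) == 0)
    return(structure(1, degenerate = TRUE))
  structure(cor(ca, cu), degenerate = FALSE)
}

#' Modified multi-parameter sensitivity analysis (m-MPSA)
#'
#' One-parameter-at-a-time Monte Carlo sensitivity analysis. For each of the
#' `2N(N+1)` parameters in turn: a sampling range is centred on the base
#' vector's value ([parameter_range()]); `n_samples` uniform draws replace
#' that single entry while the other parameters are held at `base`; each
#' candidate is scored by `evaluator`; the draws are classified against
#' `C_r` = `threshold_multiplier` times the best value
#' ([acceptability_threshold()], [classify_acceptable()]); and the
#' sensitivity is the cumulative-frequency correlation of the two classes
#' ([cf_correlation()]). Parameters are ranked ascending by sensitivity
#' (lowest = most sensitive), ties broken by ascending parameter index.
#'
#' @param base named or unnamed flat parameter vector of length `2N(N+1)`
#'   (the current best solution).
#' @param evaluator fitness oracle from [make_evaluator()] (any function of
#'   a flat vector works; a `"batch"` attribute is used when present).
#' @param region the initial [search_region()] from which sampling ranges
#'   are derived.
#' @param config an [mpsa_config()].
#' @param base_fitness fitness of `base`; only consulted when
#'   `config$best_scope == "run"`.
#' @param keep_hist keep per-parameter acceptable/unacceptable histograms in
#'   the report.
#' @return An object of class `mpsa_report`: a list with `table` (data frame
#'   with columns `label`, `role`, `i`, `j`, `kind`, `sensitivity`, `rank`,
#'   `range_low`, `range_high`, `n_acceptable`, `degenerate`), `ranking`
#'   (parameter indices sorted most-sensitive first), optional histogram
#'   matrices, `n_degenerate` and the configuration used. Deterministic
#'   under a fixed RNG seed.
#' @export
run_mpsa <- function(base, evaluator, region = search_region(),
                     config = mpsa_config(), base_fitness = NULL,
                     keep_hist = TRUE) {
  base <- as.numeric(base)
  mu <- length(base)
  n <- (-1 + sqrt(1 + 2 * mu)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("base vector length ", mu, " is not 2N(N+1) for any integer N")
  n <- as.integer(round(n))
  info <- param_info(n)
  sens <- numeric(mu); degen <- logical(mu)
  n_acc <- integer(mu)
  rlo <- numeric(mu); rhi <- numeric(mu)
  ha <- if (keep_hist) matrix(0L, mu, config$n_bins)
  hu <- if (keep_hist) matrix(0L, mu, config$n_bins)
  if (config$best_scope == "run" && is.null(base_fitness))
    base_fitness <- evaluator(base)
  for (k in seq_len(mu)) {
    rng <- parameter_range(info$kind[k], base[k], region,
                           config$range_fraction)
    vals <- sample_values(rng, config$n_samples)
    P <- matrix(base, config$n_samples, mu, byrow = TRUE)
    P[, k] <- vals
    fits <- tryCatch(evaluate_batch(evaluator, P), error = function(e)
      stop("evaluator failed on parameter ", info$label[k], ": ",
           conditionMessage(e)))
    best <- min(fits)
    if (config$best_scope == "run") best <- min(best, base_fitness)
    cr <- acceptability_threshold(best, config$threshold_multiplier)
    cls <- classify_acceptable(fits, cr)
    s <- cf_correlation(vals[cls$acceptable], vals[cls$unacceptable],
                        rng, config$n_bins)
    sens[k] <- as.numeric(s)
    degen[k] <- attr(s, "degenerate")
    n_acc[k] <- length(cls$acceptable)
    rlo[k] <- rng[1]; rhi[k] <- rng[2]
    if (keep_hist) {
      ha[k, ] <- bin_counts(vals[cls$acceptable], rng, config$n_bins)
      hu[k, ] <- bin_counts(vals[cls$unacceptable], rng, config$n_bins)
    }
  }
  ranking <- order(sens, seq_len(mu)) # ascending sensitivity, ties by index
  rank <- integer(mu); rank[ranking] <- seq_len(mu)
  tab <- cbind(info, data.frame(sensitivity = sens, rank = rank,
                                range_low = rlo, range_high = rhi,
                                n_acceptable = n_acc, degenerate = degen))
  structure(list(table = tab, ranking = ranking,
                 acceptable_hist = ha, unacceptable_hist = hu,
                 n_degenerate = sum(degen), config = config),
            class = "mpsa_report")
}

#' @export
print.mpsa_report <- function(x, n = 10L, ...) {
  mu <- nrow(x$table)
  cat("m-MPSA sensitivity report:", mu, "parameters,",
      x$config$n_samples, "samples each\n")
  if (x$n_degenerate > 0L)
    cat("  (", x$n_degenerate, " degenerate correlations -> sentinels)\n",
        sep = "")
  cat("Most sensitive (lowest cumulative-frequency correlation):\n")
  print(x$table[x$ranking[seq_len(min(n, mu))],
                c("label", "role", "i", "j", "sensitivity", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mpsa_report <- function(x, ...) x$table

#' Local (one-parameter) log-sensitivity by central differences
#'
#' Classical normalized sensitivity
#' \eqn{S = (\partial M / M) / (\partial P / P)} (percentage change in the
#' objective per percentage change in the parameter), estimated by a central
#' difference with relative step `rel_step`. When the base value is zero a
#' relative step is impossible; an absolute step of `rel_step` is used for
#' the derivative and the result (the semi-relative `(dM/dP)/M`) carries
#' attribute `absolute_step = TRUE`.
#'
#' @param evaluator objective function of a flat parameter vector.
#' @param base flat parameter vector.
#' @param k parameter index to perturb.
#' @param rel_step relative step size.
#' @return Numeric sensitivity estimate.
#' @export
local_sensitivity <- function(evaluator, base, k, rel_step = 1e-4) {
  base <- as.numeric(base)
  m0 <- as.numeric(evaluator(base))
  if (m0 == 0) stop("objective is zero at base; relative sensitivity undefined")
  up <- base; dn <- base
  if (base[k] != 0) {
    up[k] <- base[k] * (1 + rel_step)
    dn[k] <- base[k] * (1 - rel_step)
    s <- (as.numeric(evaluator(up)) - as.numeric(evaluator(dn))) /
      m0 / (2 * rel_step)
    structure(s, absolute_step = FALSE)
  } else {
    up[k] <- rel_step; dn[k] <- -rel_step
    dmdp <- (as.numeric(evaluator(up)) - as.numeric(evaluator(dn))) /
      (2 * rel_step)
    structure(dmdp / m0, absolute_step = TRUE)
  }
}
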