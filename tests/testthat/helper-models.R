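# Small fixtures shared across tests; everything is built in code.

# one-gene pure decay: dx/dt = -x, x(t) = x0 * exp(-t)
decay_model <- function() {
  ssystem(alpha = 0, beta = 1, g = matrix(0), h = matrix(1))
}

# three-gene model whose gene 3 sits at a fixed point of 1 and regulates
# nothing: every exponent on x3 is inert because x3^g == 1 throughout
null_gene3_model <- function() {
  g <- matrix(0, 3, 3); h <- matrix(0, 3, 3)
  g[1, 2] <- 1; g[2, 1] <- 2
  h[1, 1] <- 2; h[2, 2] <- 2
  ssystem(alpha = c(8, 10, 5), beta = c(10, 10, 5), g = g, h = h)
}

null_gene3_target <- function() {
  generate_series(null_gene3_model(), x0 = c(2, 1.2, 1),
                  times = seq(0, 2.9, by = 0.1))
}

# sphere objective over flat vectors, for optimizer smoke properties
sphere_evaluator <- function() {
  f <- function(par) sum(par^2)
  attr(f, "batch") <- function(P) rowSums(P^2)
  f
}

sphere_bounds <- function(m) bound_set(rep(-5, m), rep(5, m))

# independently coded Pearson correlation (textbook sum formula), used as
# the oracle against cf_correlation
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# independently coded cumulative relative frequency on equal-width bins
# (loop + explicit interval tests, last bin right-closed)
oracle_cumfreq <- function(values, lo, hi, n_bins) {
  edges <- lo + (hi - lo) * (0:n_bins) / n_bins
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    if (b < n_bins)
      counts[b] <- sum(values >= edges[b] & values < edges[b + 1])
    else
      counts[b] <- sum(values >= edges[b] & values <= edges[b + 1])
  }
  cumsum(counts) / length(values)
}
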