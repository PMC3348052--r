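#' S-system model of a gene regulatory network
#'
#' An S-system describes the expression dynamics of `N` genes by power-law
#' ordinary differential equations
#' \deqn{dx_i/dt = \alpha_i \prod_j x_j^{g_{ij}} - \beta_i \prod_j x_j^{h_{ij}}}
#' where `alpha`, `beta` are non-negative rate constants for production and
#' degradation, and the real kinetic orders `g`, `h` encode the strength and
#' sign of the regulatory influence of gene `j` on gene `i`. A model with `N`
#' genes has `2N(N+1)` free parameters.
#'
#' @param alpha,beta numeric vectors of length `N`, non-negative rate
#'   constants (production and degradation).
#' @param g,h `N x N` numeric matrices of kinetic orders; `g[i, j]` is the
#'   exponent of gene `j` in gene `i`'s production term.
#' @param gene_names optional character vector of `N` gene labels; defaults
#'   to `X1 ... XN`.
#' @return An object of class `ssystem` with fields `n_genes`, `alpha`,
#'   `beta`, `g`, `h`, `gene_names`.
#' @examples
#' m <- ssystem(alpha = 2, beta = 1, g = matrix(0), h = matrix(1))
#' ss_derivative(m, 2) # 2 * x^0 - 1 * x^1 = 0 at x = 2
#' @seealso [ss_simulate()], [ss_encode()], [dataset1_model()]
#' @export
ssystem <- function(alpha, beta, g, h, gene_names = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  g <- as.matrix(g)
  h <- as.matrix(h)
  n <- length(alpha)
  if (n < 1L) stop("an S-system needs at least one gene")
  if (length(beta) != n) stop("alpha and beta must have the same length")
  if (!all(dim(g) == c(n, n)) || !all(dim(h) == c(n, n)))
    stop("g and h must be ", n, " x ", n, " matrices")
  if (!all(is.finite(alpha)) || !all(is.finite(beta)) ||
      !all(is.finite(g)) || !all(is.finite(h)))
    stop("all S-system parameters must be finite")
  if (any(alpha < 0) || any(beta < 0))
    stop("rate constants alpha and beta must be non-negative")
  if (is.null(gene_names)) gene_names <- paste0("X", seq_len(n))
  if (length(gene_names) != n) stop("gene_names must have length ", n)
  structure(
    list(n_genes = n, alpha = alpha, beta = beta,
         g = unname(g), h = unname(h), gene_names = as.character(gene_names)),
    class = "ssystem")
}

#' Number of free parameters of an N-gene S-system
#'
#' Each gene contributes one production and one degradation rate constant and
#' `N` kinetic orders in each of the two terms, so the total is `2N(N+1)`
#' (220 for ten genes, 144 for eight).
#'
#' @param n_genes positive integer number of genes.
#' @return Integer, `2 * n_genes * (n_genes + 1)`.
#' @examples
#' parameter_count(10) # 220
#' parameter_count(8)  # 144
#' @export
parameter_count <- function(n_genes) {
  if (length(n_genes) != 1L || !is.finite(n_genes) ||
      n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a single positive integer")
  as.integer(2 * n_genes * (n_genes + 1))
}

#' Parameter index map for the flat encoding
#'
#' The `2N(N+1)` parameters are laid out in per-gene blocks: gene `i`
#' contributes `alpha_i, g[i,1..N], beta_i, h[i,1..N]`, blocks in ascending
#' `i`. Parameters carry stable 1-based labels `P1 ... Pmu`. (The labels are
#' a convention of this package; there is no canonical published ordering.)
#'
#' @param n_genes number of genes.
#' @return A data frame with one row per parameter: `label`, `role` (one of
#'   `alpha`, `g`, `beta`, `h`), `i` (gene index), `j` (regulator index, `NA`
#'   for rate constants) and `kind` (`rate` or `kinetic`).
#' @examples
#' param_info(2)
#' @export
param_info <- function(n_genes) {
  n <- n_genes
  mu <- parameter_count(n)
  role <- character(mu); gi <- integer(mu); gj <- rep(NA_integer_, mu)
  blk <- 2L * (n + 1L)
  for (i in seq_len(n)) {
    b <- (i - 1L) * blk
    role[b + 1L] <- "alpha"; gi[b + 1L] <- i
    role[b + 1L + seq_len(n)] <- "g"; gi[b + 1L + seq_len(n)] <- i
    gj[b + 1L + seq_len(n)] <- seq_len(n)
    role[b + n + 2L] <- "beta"; gi[b + n + 2L] <- i
    role[b + n + 2L + seq_len(n)] <- "h"; gi[b + n + 2L + seq_len(n)] <- i
    gj[b + n + 2L + seq_len(n)] <- seq_len(n)
  }
  data.frame(label = paste0("P", seq_len(mu)), role = role, i = gi, j = gj,
             kind = ifelse(role %in% c("alpha", "beta"), "rate", "kinetic"),
             stringsAsFactors = FALSE)
}

#' Encode an S-system model as a flat parameter vector
#'
#' @param model an [ssystem()] model.
#' @return Named numeric vector of length `2N(N+1)`; names are the `P` labels
#'   of [param_info()]. `ss_decode(ss_encode(m))` is the identity.
#' @export
ss_encode <- function(model) {
  stopifnot(inherits(model, "ssystem"))
  n <- model$n_genes
  v <- unlist(lapply(seq_len(n), function(i)
    c(model$alpha[i], model$g[i, ], model$beta[i], model$h[i, ])))
  names(v) <- param_info(n)$label
  v
}

#' Decode a flat parameter vector into an S-system model
#'
#' @param values numeric vector of length `2N(N+1)` in the layout of
#'   [param_info()].
#' @param n_genes number of genes; inferred from `length(values)` if omitted.
#' @param gene_names optional gene labels.
#' @return An [ssystem()] model.
#' @export
ss_decode <- function(values, n_genes = NULL, gene_names = NULL) {
  if (is.null(n_genes)) {
    n_genes <- (-1 + sqrt(1 + 2 * length(values))) / 2
    if (abs(n_genes - round(n_genes)) > 1e-9)
      stop("vector length ", length(values), " is not 2N(N+1) for any integer N")
    n_genes <- as.integer(round(n_genes))
  }
  mu <- parameter_count(n_genes)
  if (length(values) != mu)
    stop("parameter vector has length ", length(values),
         " but an S-system with ", n_genes, " genes needs ", mu)
  n <- n_genes
  blk <- 2L * (n + 1L)
  alpha <- numeric(n); beta <- numeric(n)
  g <- matrix(0, n, n); h <- matrix(0, n, n)
  for (i in seq_len(n)) {
    b <- (i - 1L) * blk
    alpha[i] <- values[b + 1L]
    g[i, ] <- values[b + 1L + seq_len(n)]
    beta[i] <- values[b + n + 2L]
    h[i, ] <- values[b + n + 2L + seq_len(n)]
  }
  ssystem(alpha, beta, g, h, gene_names)
}

#' Default search region for S-system parameters
#'
#' The conventional inference search region: kinetic orders in
#' \[-3, 3\] and rate constants in \[0, 10\].
#'
#' @param kinetic,rate numeric length-2 vectors `c(low, high)`.
#' @return An object of class `search_region`.
#' @export
search_region <- function(kinetic = c(-3, 3), rate = c(0, 10)) {
  stopifnot(length(kinetic) == 2L, length(rate) == 2L,
            kinetic[1] < kinetic[2], rate[1] < rate[2])
  structure(list(kinetic = as.numeric(kinetic), rate = as.numeric(rate)),
            class = "search_region")
}

#' Time-course expression series
#'
#' Container for an `N x T` matrix of expression levels over `T` strictly
#' increasing time points, used both for target data and simulated output.
#'
#' @param values numeric `N x T` matrix, genes in rows.
#' @param times numeric vector of `T` strictly increasing time stamps.
#' @param gene_names optional gene labels (default: rownames, else `X1..XN`).
#' @return Object of class `ss_series` with fields `values` (rownames set to
#'   the gene names), `times`, `gene_names`.
#' @export
ss_series <- function(values, times, gene_names = NULL) {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (ncol(values) != length(times))
    stop("values has ", ncol(values), " columns but there are ",
         length(times), " time points")
  if (length(times) < 2L) stop("a time series needs at least two time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(gene_names)) {
    gene_names <- rownames(values)
    if (is.null(gene_names)) gene_names <- paste0("X", seq_len(nrow(values)))
  }
  rownames(values) <- gene_names
  colnames(values) <- NULL
  structure(list(values = values, times = times,
                 gene_names = as.character(gene_names)),
            class = "ss_series")
}

#' @export
as.matrix.ss_series <- function(x, ...) x$values

#' @export
print.ss_series <- function(x, ...) {
  cat("Time-course expression series: ", nrow(x$values), " genes x ",
      length(x$times), " time points (t = ", format(min(x$times)), " .. ",
      format(max(x$times)), ")\n", sep = "")
  if (isTRUE(attr(x, "diverged")))
    cat("  [diverged after ", attr(x, "completed"), " points]\n", sep = "")
  print(utils::head(x$values[, seq_len(min(6L, ncol(x$values))), drop = FALSE]))
  invisible(x)
}

# one production or degradation term as readable text, e.g. "15 X3 X5^-0.1"
format_ss_term <- function(rate, orders, names) {
  parts <- character(0)
  for (j in seq_along(orders)) {
    if (orders[j] == 0) next
    parts <- c(parts, if (orders[j] == 1) names[j] else
      paste0(names[j], "^", format(orders[j])))
  }
  if (length(parts) == 0) return(format(rate))
  paste(c(format(rate), parts), collapse = " ")
}

#' @export
print.ssystem <- function(x, ...) {
  cat("S-system model with", x$n_genes, "genes (",
      parameter_count(x$n_genes), "parameters )\n")
  for (i in seq_len(x$n_genes)) {
    cat(" d", x$gene_names[i], "/dt = ",
        format_ss_term(x$alpha[i], x$g[i, ], x$gene_names), " - ",
        format_ss_term(x$beta[i], x$h[i, ], x$gene_names), "\n", sep = "")
  }
  invisible(x)
}
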