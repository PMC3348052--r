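#' Parameters recurrently sensitive across runs
#'
#' Tallies, over a collection of independent inference runs, how often each
#' parameter appears in a run's final sensitive set, and keeps those with at
#' least `min_support` occurrences (the convention is 15 of 20 runs).
#'
#' @param runs a list whose elements are either character vectors of
#'   sensitive parameter labels or [ss_infer()] fits (the final SA
#'   snapshot's sensitive set is used).
#' @param min_support minimum number of supporting runs.
#' @return Data frame with columns `label` and `support`, sorted by
#'   decreasing support then ascending parameter index. Empty (not an
#'   error) when `min_support` exceeds the number of runs.
#' @export
recurrent_sensitive <- function(runs, min_support) {
  if (length(runs) < 1L) stop("need at least one run")
  sets <- lapply(runs, function(r) {
    if (inherits(r, "ss_fit")) {
      if (length(r$sa_snapshots) == 0L) return(character(0))
      r$sa_snapshots[[length(r$sa_snapshots)]]$sensitive
    } else as.character(r)
  })
  tal <- table(unlist(sets))
  keep <- tal[tal >= min_support]
  labels <- names(keep)
  idx <- suppressWarnings(as.integer(sub("^P", "", labels)))
  ord <- order(-as.integer(keep), idx)
  out <- data.frame(label = labels[ord], support = as.integer(keep)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Qualitative ordering pattern of selected parameters
#'
#' Orders a set of parameter labels by their (descending) values in a
#' solution vector, giving a strict qualitative relationship such as
#' `P64 > P14 > P72`. Exact ties are broken by ascending parameter index and
#' flagged.
#'
#' @param best named flat parameter vector.
#' @param params character vector (length >= 2) of labels to order.
#' @return Object of class `ss_pattern`: list with `labels` (ordered),
#'   `values`, `pattern` (the `"a > b > c"` string) and `tied`.
#' @examples
#' v <- setNames(c(0.8, 2.1, 0.1), c("P14", "P64", "P72"))
#' ordering_pattern(v, c("P64", "P14", "P72"))$pattern # "P64 > P14 > P72"
#' @export
ordering_pattern <- function(best, params) {
  params <- as.character(params)
  if (length(params) < 2L) stop("need at least two parameter labels")
  if (!all(params %in% names(best)))
    stop("unknown parameter label(s): ",
         paste(setdiff(params, names(best)), collapse = ", "))
  v <- best[params]
  idx <- suppressWarnings(as.integer(sub("^P", "", params)))
  if (any(is.na(idx))) idx <- seq_along(params)
  ord <- order(-v, idx)
  labels <- params[ord]
  structure(list(labels = labels, values = unname(v[ord]),
                 pattern = paste(labels, collapse = " > "),
                 tied = anyDuplicated(v) > 0L),
            class = "ss_pattern")
}

#' @export
print.ss_pattern <- function(x, ...) {
  cat(x$pattern, if (x$tied) " (ties broken by index)", "\n", sep = "")
  invisible(x)
}

#' Tabulate recurring ordering patterns across runs
#'
#' Groups identical qualitative orderings and reports each pattern's
#' support (number of runs) and the contributing run ids; patterns below
#' the support floor (5 by convention) are dropped.
#'
#' @param patterns list of [ordering_pattern()] results (or plain ordered
#'   label vectors); element names are used as run ids, else `1..n`.
#' @param min_support support floor.
#' @return Data frame with columns `pattern`, `support`, `runs`
#'   (comma-separated run ids), sorted by decreasing support.
#' @export
pattern_support <- function(patterns, min_support = 5L) {
  if (length(patterns) == 0L)
    return(data.frame(pattern = character(0), support = integer(0),
                      runs = character(0), stringsAsFactors = FALSE))
  keys <- vapply(patterns, function(p) {
    if (inherits(p, "ss_pattern")) p$pattern
    else paste(as.character(p), collapse = " > ")
  }, character(1))
  ids <- names(patterns)
  if (is.null(ids) || any(ids == "")) ids <- as.character(seq_along(patterns))
  grp <- split(ids, keys)
  out <- data.frame(pattern = names(grp),
                    support = vapply(grp, length, integer(1)),
                    runs = vapply(grp, paste, character(1), collapse = ", "),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$support, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network scaffold from sensitive kinetic orders
#'
#' Maps each sensitive kinetic-order parameter to a directed regulatory
#' edge: a sensitive `g[i, j]` (production term) becomes an activation edge
#' from gene `j` to gene `i`, and a sensitive `h[i, j]` (degradation term)
#' an inhibition edge from `j` to `i`. Rate constants yield no edges. The
#' optional `"signed"` mode instead uses the exponent's sign (positive `g`
#' activates, negative inhibits; reversed for `h`), which requires the
#' fitted `values`.
#'
#' @param sensitive character vector of sensitive parameter labels (`P`
#'   labels for a network over `gene_names`).
#' @param gene_names gene labels; their number fixes `N`.
#' @param mode `"default"` (g = activation, h = inhibition) or `"signed"`.
#' @param values named parameter vector, needed for `mode = "signed"`.
#' @return Data frame (edge list) with columns `source`, `target`,
#'   `effect` (`"activation"`/`"inhibition"`) and `parameter` — one row per
#'   sensitive kinetic order.
#' @examples
#' genes <- c("lexA", "uvrA", "uvrD", "recA", "umuD", "polB")
#' info <- param_info(6)
#' labs <- info$label[(info$role == "h" & info$i == 1 & info$j == 1) |
#'                    (info$role == "g" & info$i == 2 & info$j == 1)]
#' infer_structure(labs, genes) # lexA -| lexA and lexA -> uvrA
#' @export
infer_structure <- function(sensitive, gene_names,
                            mode = c("default", "signed"), values = NULL) {
  mode <- match.arg(mode)
  n <- length(gene_names)
  info <- param_info(n)
  rows <- info[match(as.character(sensitive), info$label), , drop = FALSE]
  if (anyNA(rows$label))
    stop("unknown parameter label(s) for a ", n, "-gene network")
  rows <- rows[rows$role %in% c("g", "h"), , drop = FALSE]
  if (nrow(rows) == 0L)
    return(data.frame(source = character(0), target = character(0),
                      effect = character(0), parameter = character(0),
                      stringsAsFactors = FALSE))
  effect <- ifelse(rows$role == "g", "activation", "inhibition")
  if (mode == "signed") {
    if (is.null(values)) stop("mode = \"signed\" needs the parameter values")
    v <- values[rows$label]
    effect <- ifelse(rows$role == "g",
                     ifelse(v >= 0, "activation", "inhibition"),
                     ifelse(v >= 0, "inhibition", "activation"))
  }
  data.frame(source = gene_names[rows$j], target = gene_names[rows$i],
             effect = effect, parameter = rows$label,
             stringsAsFactors = FALSE, row.names = NULL)
}
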