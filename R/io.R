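#' Read and write time-course expression series as TSV
#'
#' The dialect is a plain tab-separated table: a header row whose first cell
#' is `gene` followed by the time stamps, then one row per gene (name,
#' then the expression values). Values round-trip to 12 significant digits.
#'
#' @param series an [ss_series()].
#' @param path file path.
#' @return `read_timeseries` returns an [ss_series()];
#'   `write_timeseries` returns `path` invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "ss_series"))
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c(paste(c("gene", fmt(series$times)), collapse = "\t"),
             vapply(seq_len(nrow(series$values)), function(i)
               paste(c(series$gene_names[i], fmt(series$values[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("time-series file needs a header and data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] != "gene")
    stop("malformed header (line 1): first column must be \"gene\"")
  times <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(times)) stop("malformed header (line 1): non-numeric time stamp")
  if (any(diff(times) <= 0))
    stop("malformed header (line 1): time stamps must be strictly increasing")
  nt <- length(times)
  vals <- matrix(NA_real_, length(lines) - 1L, nt)
  genes <- character(length(lines) - 1L)
  for (r in seq_along(genes)) {
    row <- cells[[r + 1L]]
    if (length(row) != nt + 1L)
      stop("line ", r + 1L, ": expected ", nt + 1L, " columns, found ",
           length(row))
    genes[r] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("line ", r + 1L, " (gene ", row[1L], "), column ", bad + 1L,
           ": missing or non-numeric value")
    }
    vals[r, ] <- v
  }
  ss_series(vals, times, genes)
}

#' Read and write S-system models as JSON
#'
#' The format has keys `n_genes`, `alpha`, `beta`, `g`, `h` (row-major
#' matrices) and `gene_names`. The non-negativity of the rate constants is
#' enforced on read.
#'
#' @param model an [ssystem()] model.
#' @param path file path.
#' @return `read_model` returns an [ssystem()] model; `write_model`
#'   returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ssystem"))
  jsonlite::write_json(
    list(n_genes = model$n_genes, alpha = model$alpha, beta = model$beta,
         g = model$g, h = model$h, gene_names = model$gene_names),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (f in c("n_genes", "alpha", "beta", "g", "h"))
    if (is.null(obj[[f]])) stop("model file is missing field \"", f, "\"")
  if (any(obj$alpha < 0) || any(obj$beta < 0))
    stop("invalid model: rate constants alpha and beta must be non-negative")
  ssystem(obj$alpha, obj$beta, obj$g, obj$h, obj$gene_names)
}

#' Write an m-MPSA report as CSV
#'
#' @param report an [run_mpsa()] report.
#' @param path CSV path for the per-parameter table.
#' @param hist_path optional CSV path for the per-parameter
#'   acceptable/unacceptable bin counts (long format).
#' @return `path`, invisibly.
#' @export
write_mpsa_report <- function(report, path, hist_path = NULL) {
  stopifnot(inherits(report, "mpsa_report"))
  write.csv(report$table, path, row.names = FALSE)
  if (!is.null(hist_path) && !is.null(report$acceptable_hist)) {
    nb <- ncol(report$acceptable_hist)
    long <- data.frame(
      label = rep(report$table$label, each = nb),
      bin = rep(seq_len(nb), nrow(report$table)),
      acceptable = as.vector(t(report$acceptable_hist)),
      unacceptable = as.vector(t(report$unacceptable_hist)))
    write.csv(long, hist_path, row.names = FALSE)
  }
  invisible(path)
}

#' Persist an inference run as a directory of artifacts
#'
#' Writes, under `dir`: `manifest.json` (configuration, seed, package
#' version, event log), `history.csv` (per-generation best and mean fitness
#' with SA/exploration events), `best_model.json`, `best_par.csv`, the
#' target series as `target.tsv`, and one `sa_<generation>.csv` report per
#' sensitivity round. [read_run()] restores the pieces [analyze][recurrent_sensitive]
#' functions need.
#'
#' @param fit an [ss_infer()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(fit, dir) {
  stopifnot(inherits(fit, "ss_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "ssie", version = as.character(packageVersion("ssie")),
    method = fit$method, setting = fit$setting, seed = fit$seed,
    generations = length(fit$history) - 1L,
    population = fit$opt_config$population,
    sa_interval = fit$sa_interval, explore_interval = fit$explore_interval,
    c_const = fit$c_const, substeps = fit$substeps,
    region = unclass(fit$region), sa_config = unclass(fit$sa_config),
    best_fitness = fit$best_fitness, n_evals = fit$n_evals,
    events = fit$events,
    final_sensitive = if (length(fit$sa_snapshots))
      fit$sa_snapshots[[length(fit$sa_snapshots)]]$sensitive
    else character(0))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  gens <- seq_along(fit$history) - 1L
  ev <- vapply(gens, function(g) {
    e <- fit$events$event[fit$events$generation == g]
    paste(e, collapse = "+")
  }, character(1))
  write.csv(data.frame(generation = gens, best_fitness = fit$history,
                       mean_fitness = fit$history_mean, event = ev),
            file.path(dir, "history.csv"), row.names = FALSE)
  write_model(fit$model, file.path(dir, "best_model.json"))
  write.csv(data.frame(label = names(fit$best_par),
                       value = unname(fit$best_par)),
            file.path(dir, "best_par.csv"), row.names = FALSE)
  write_timeseries(fit$target, file.path(dir, "target.tsv"))
  for (snap in fit$sa_snapshots)
    write_mpsa_report(snap$report,
                      file.path(dir, sprintf("sa_%06d.csv", snap$generation)))
  invisible(dir)
}

#' @rdname write_run
#' @return `read_run` returns a list with `manifest`, `best_par` (named
#'   vector), `model`, and `sensitive` (final sensitive label set).
#' @export
read_run <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  bp <- read.csv(file.path(dir, "best_par.csv"), stringsAsFactors = FALSE)
  list(manifest = manifest,
       best_par = setNames(bp$value, bp$label),
       model = read_model(file.path(dir, "best_model.json")),
       sensitive = as.character(unlist(manifest$final_sensitive)))
}
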