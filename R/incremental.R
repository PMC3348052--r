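#' Rising sensitivity-threshold schedule
#'
#' The incremental controller admits a parameter to the sensitive list when
#' its cumulative-frequency correlation is at or below the current
#' threshold. The threshold starts at 0.84 and rises by 0.1 after every
#' sensitivity-analysis round, capped at 1.0 (a Pearson correlation cannot
#' exceed 1, so eventually every parameter is treated as sensitive and all
#' values become pinned down).
#'
#' @param initial,step,cap schedule parameters.
#' @return Object of class `threshold_schedule` with field `current`.
#' @export
threshold_schedule <- function(initial = 0.84, step = 0.1, cap = 1.0) {
  structure(list(initial = initial, step = step, cap = cap,
                 current = initial),
            class = "threshold_schedule")
}

#' @rdname threshold_schedule
#' @param schedule a `threshold_schedule`.
#' @export
advance_threshold <- function(schedule) {
  schedule$current <- min(schedule$current + schedule$step, schedule$cap)
  schedule
}

#' Partition parameters into sensitive and insensitive sets
#'
#' A parameter is sensitive when its sensitivity value is less than or equal
#' to the threshold (boundary values count as sensitive).
#'
#' @param report an [run_mpsa()] report.
#' @param threshold current sensitivity threshold.
#' @return List with character vectors `sensitive` and `insensitive`
#'   (disjoint, exhaustive parameter labels).
#' @export
select_sensitive <- function(report, threshold) {
  stopifnot(inherits(report, "mpsa_report"))
  tab <- report$table
  sens <- tab$sensitivity <= threshold
  list(sensitive = tab$label[sens], insensitive = tab$label[!sens])
}

#' Sensitivity-derived box constraints
#'
#' Bounds are centred on the best value found so far: sensitive parameters
#' get tight bounds (plus/minus twice a small constant `c_const`, which
#' equals the PSO velocity bound, 0.2 here) and insensitive parameters get
#' loose bounds (plus/minus five times the same constant).
#'
#' @param best named flat parameter vector (the current global best).
#' @param sensitive character vector of sensitive parameter labels.
#' @param c_const the small constant; 0.2 by convention.
#' @return A [bound_set()] with tags `sensitive`/`insensitive`.
#' @examples
#' b <- setNames(c(0.5, 0.5), c("P1", "P2"))
#' make_bounds(b, sensitive = "P1") # P1: (0.1, 0.9); P2: (-0.5, 1.5)
#' @export
make_bounds <- function(best, sensitive, c_const = 0.2) {
  if (c_const <= 0) stop("c_const must be positive")
  labels <- names(best)
  if (is.null(labels)) labels <- paste0("P", seq_along(best))
  is_sens <- labels %in% sensitive
  half <- ifelse(is_sens, 2 * c_const, 5 * c_const)
  bound_set(best - half, best + half,
            tag = ifelse(is_sens, "sensitive", "insensitive"),
            labels = labels)
}

#' Randomly-placed control bounds (experimental setting 3)
#'
#' Same tight/loose widths as [make_bounds()] but interval centres drawn
#' uniformly from each parameter's initial search region instead of the best
#' value found — the control that isolates the value of sensitivity-derived
#' bound placement.
#'
#' @inheritParams make_bounds
#' @param region the initial [search_region()].
#' @return A [bound_set()].
#' @export
make_random_bounds <- function(best, sensitive, region = search_region(),
                               c_const = 0.2) {
  labels <- names(best)
  if (is.null(labels)) labels <- paste0("P", seq_along(best))
  n <- (-1 + sqrt(1 + 2 * length(best))) / 2
  info <- param_info(as.integer(round(n)))
  kin <- info$kind == "kinetic"
  lo <- ifelse(kin, region$kinetic[1], region$rate[1])
  hi <- ifelse(kin, region$kinetic[2], region$rate[2])
  centers <- runif(length(best), lo, hi)
  is_sens <- labels %in% sensitive
  half <- ifelse(is_sens, 2 * c_const, 5 * c_const)
  bound_set(centers - half, centers + half,
            tag = ifelse(is_sens, "sensitive", "insensitive"),
            labels = labels)
}

#' Exploration restart of a population
#'
#' Resamples every parameter of every individual uniformly within the active
#' bounds (injecting diversity after a bound update), re-initializes
#' velocities, and resets personal bests to the new positions. The single
#' global-best individual is preserved so the best-so-far fitness stays
#' monotone.
#'
#' @param state optimizer population state.
#' @param evaluator fitness oracle (the resampled positions are
#'   re-evaluated).
#' @param preserve_best keep the global best in slot 1 (default) or resample
#'   everyone.
#' @return Updated state.
#' @export
explore_population <- function(state, evaluator, preserve_best = TRUE) {
  n <- nrow(state$X); m <- ncol(state$X)
  b <- state$bounds
  X <- matrix(runif(n * m), n, m)
  X <- sweep(sweep(X, 2L, b$high - b$low, "*"), 2L, b$low, "+")
  if (preserve_best) X[1L, ] <- state$best_x
  state$X <- X
  state$V <- matrix(runif(n * m, -0.2, 0.2), n, m)
  state$fit <- evaluate_batch(evaluator, X)
  if (preserve_best) state$fit[1L] <- state$best_f
  state$n_evals <- state$n_evals + (n - as.integer(preserve_best))
  state$pbX <- X
  state$pbF <- state$fit
  update_best(state)
}

#' Infer an S-system gene network by sensitivity-based incremental evolution
#'
#' The package's fitting function. A population optimizer (PSO, hybrid
#' GA-PSO, or DE) minimizes the relative squared-error objective between a
#' candidate S-system's simulated dynamics and the target series. Under
#' settings 2 and 3 the search is wrapped in the incremental-evolution
#' controller: every `sa_interval` generations a full m-MPSA round
#' ([run_mpsa()]) ranks all `2N(N+1)` parameters at the current best
#' solution, parameters at or below the rising threshold join the sensitive
#' list, and new tight/loose box constraints replace the active bounds
#' ([make_bounds()]; setting 3 uses the randomly-placed control bounds of
#' [make_random_bounds()]). Every `explore_interval` generations the
#' population (except the global best) is resampled inside the active
#' bounds. Setting 1 is the plain optimizer over the initial search region.
#'
#' @param target an [ss_series()] of observed expression profiles.
#' @param method `"gapso"` (default), `"pso"` or `"de"`.
#' @param setting experimental setting 1, 2 (default) or 3.
#' @param population,generations optimizer budget (shorthand for the
#'   corresponding `opt_config` fields).
#' @param sa_interval generations between sensitivity-analysis rounds
#'   (500 by convention).
#' @param explore_interval generations between exploration restarts
#'   (1000 by convention).
#' @param region initial [search_region()].
#' @param opt_config an [optimizer_config()]; built from `population` and
#'   `generations` when `NULL`.
#' @param sa_config an [mpsa_config()].
#' @param schedule a [threshold_schedule()].
#' @param c_const bound half-width constant (see [make_bounds()]).
#' @param seed integer seed; the whole run (initialization, optimizer,
#'   sensitivity sampling, exploration) consumes one RNG stream, so a fixed
#'   seed reproduces the run exactly.
#' @param x0,substeps evaluator options passed to [make_evaluator()].
#' @return An object of class `ss_fit`; see [coef.ss_fit()],
#'   [predict.ss_fit()], [plot.ss_fit()]. Fields include the best flat
#'   parameter vector (`best_par`), decoded `model`, `best_fitness`,
#'   best-so-far fitness `history`, the `events` log (one row per SA round /
#'   bound update / exploration, with generation stamps), `sa_snapshots`
#'   (the m-MPSA report, threshold and sensitive set of each SA round) and
#'   `bounds` (the final active bound set).
#' @examples
#' \donttest{
#' spec <- benchmark_spec("toy_2gene")
#' target <- generate_series(spec)
#' fit <- ss_infer(target, population = 40, generations = 60,
#'                 sa_interval = 30, explore_interval = 60, seed = 1,
#'                 sa_config = mpsa_config(n_samples = 50))
#' fit
#' }
#' @export
ss_infer <- function(target, method = c("gapso", "pso", "de"), setting = 2L,
                     population = 200L, generations = 1000L,
                     sa_interval = 500L, explore_interval = 1000L,
                     region = search_region(), opt_config = NULL,
                     sa_config = mpsa_config(), schedule = threshold_schedule(),
                     c_const = 0.2, seed = NULL, x0 = NULL, substeps = 5L) {
  stopifnot(inherits(target, "ss_series"))
  method <- match.arg(method)
  if (!setting %in% 1:3) stop("setting must be 1, 2 or 3")
  n <- nrow(target$values)
  info <- param_info(n)
  evaluator <- make_evaluator(target, x0 = x0, substeps = substeps)
  if (is.null(opt_config))
    opt_config <- optimizer_config(population = population,
                                   generations = generations)
  bounds0 <- bounds_from_region(region, n)

  env <- new.env(parent = emptyenv())
  env$schedule <- schedule
  env$snapshots <- list()
  env$events <- list()
  log_event <- function(gen, event, detail = "") {
    env$events[[length(env$events) + 1L]] <-
      data.frame(generation = gen, event = event, detail = detail,
                 stringsAsFactors = FALSE)
  }
  post <- function(state, gen) {
    if (setting != 1L && sa_interval > 0L && gen %% sa_interval == 0L) {
      best <- setNames(state$best_x, info$label)
      report <- run_mpsa(best, evaluator, region, sa_config,
                         base_fitness = state$best_f)
      thr <- env$schedule$current
      sel <- select_sensitive(report, thr)
      env$schedule <- advance_threshold(env$schedule)
      state$bounds <- if (setting == 2L)
        make_bounds(best, sel$sensitive, c_const)
      else
        make_random_bounds(best, sel$sensitive, region, c_const)
      env$snapshots[[length(env$snapshots) + 1L]] <-
        list(generation = gen, threshold = thr, report = report,
             sensitive = sel$sensitive, bounds = state$bounds)
      log_event(gen, "sa", sprintf("threshold=%.2f sensitive=%d",
                                   thr, length(sel$sensitive)))
      log_event(gen, "bounds",
                if (setting == 2L) "best-centred" else "random-centred")
    }
    if (setting != 1L && explore_interval > 0L &&
        gen %% explore_interval == 0L) {
      state <- explore_population(state, evaluator)
      log_event(gen, "explore", "population resampled within bounds")
    }
    state
  }

  run <- ea_optimize(evaluator, method, bounds0, opt_config, seed = seed,
                     hooks = list(post = post))
  events <- if (length(env$events))
    do.call(rbind, env$events)
  else
    data.frame(generation = integer(0), event = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  best_par <- setNames(run$best, info$label)
  structure(
    list(best_par = best_par, best_fitness = run$best_fitness,
         model = ss_decode(best_par, n, target$gene_names),
         history = run$history, history_mean = run$history_mean,
         events = events, sa_snapshots = env$snapshots,
         bounds = run$state$bounds, target = target,
         method = method, setting = as.integer(setting), seed = seed,
         n_evals = run$n_evals, opt_config = opt_config,
         sa_config = sa_config, region = region, c_const = c_const,
         sa_interval = as.integer(sa_interval),
         explore_interval = as.integer(explore_interval),
         substeps = as.integer(substeps)),
    class = "ss_fit")
}

#' Mean model sensitivity (network robustness score)
#'
#' Runs a full m-MPSA round at a solution and returns the arithmetic mean of
#' all `2N(N+1)` sensitivity values (sentinels included). Lower means the
#' model's behaviour reacts more strongly to parameter variation; the value
#' is used to compare the internal robustness of inferred networks.
#'
#' @param best flat parameter vector (e.g. `coef()` of an [ss_infer()] fit).
#' @param evaluator fitness oracle for the target the model was fitted to.
#' @param region initial [search_region()].
#' @param sa_config an [mpsa_config()].
#' @param seed optional seed for the Monte Carlo draws.
#' @return Mean sensitivity in \[-1, 1\], with the full `mpsa_report` as
#'   attribute `report`.
#' @export
mean_model_sensitivity <- function(best, evaluator, region = search_region(),
                                   sa_config = mpsa_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  report <- run_mpsa(best, evaluator, region, sa_config)
  structure(mean(report$table$sensitivity), report = report)
}
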