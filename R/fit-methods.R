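#' @export
print.ss_fit <- function(x, ...) {
  cat("S-system network inference fit\n")
  cat("  method: ", x$method, " (setting ", x$setting, ")",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  cat("  genes: ", x$model$n_genes, "  parameters: ",
      length(x$best_par), "\n", sep = "")
  cat("  generations: ", length(x$history) - 1L, "  evaluations: ",
      x$n_evals, "\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness, digits = 6), "\n", sep = "")
  if (nrow(x$events))
    cat("  events: ", sum(x$events$event == "sa"), " SA rounds, ",
        sum(x$events$event == "explore"), " explorations\n", sep = "")
  invisible(x)
}

#' @export
summary.ss_fit <- function(object, ...) {
  sens_final <- if (length(object$sa_snapshots)) {
    last <- object$sa_snapshots[[length(object$sa_snapshots)]]
    list(generation = last$generation, threshold = last$threshold,
         n_sensitive = length(last$sensitive))
  }
  structure(list(fit = object, sens_final = sens_final,
                 fitness_decrease = object$history[1] - object$best_fitness),
            class = "summary.ss_fit")
}

#' @export
print.summary.ss_fit <- function(x, ...) {
  print(x$fit)
  cat("  initial best fitness: ", format(x$fit$history[1], digits = 6),
      " (improvement ", format(x$fitness_decrease, digits = 6), ")\n",
      sep = "")
  if (!is.null(x$sens_final))
    cat("  final SA round (gen ", x$sens_final$generation, "): threshold ",
        format(x$sens_final$threshold), ", ", x$sens_final$n_sensitive,
        " sensitive parameters\n", sep = "")
  cat("\nInferred model:\n")
  print(x$fit$model)
  invisible(x)
}

#' Extract the best parameter vector of a fit
#'
#' @param object an [ss_infer()] fit.
#' @param ... unused.
#' @return Named flat parameter vector (labels per [param_info()]).
#' @export
coef.ss_fit <- function(object, ...) object$best_par

#' Simulate the fitted model
#'
#' @param object an [ss_infer()] fit.
#' @param times time grid; defaults to the target's.
#' @param x0 initial condition; defaults to the target's first column.
#' @param substeps RK4 substeps for the prediction (plotting-quality
#'   default).
#' @param ... unused.
#' @return An [ss_series()].
#' @export
predict.ss_fit <- function(object, times = NULL, x0 = NULL, substeps = 40L,
                           ...) {
  if (is.null(times)) times <- object$target$times
  if (is.null(x0)) x0 <- pmax(object$target$values[, 1], 1e-6)
  ss_simulate(object$model, x0, times, substeps = substeps)
}

#' @export
fitted.ss_fit <- function(object, ...) predict(object)$values

#' Residuals of a fit
#'
#' @param object an [ss_infer()] fit.
#' @param type `"raw"` (observed minus fitted) or `"relative"` (raw divided
#'   by the guard-adjusted observed values, the scale the objective is
#'   computed on).
#' @param ... unused.
#' @return `N x T` matrix.
#' @export
residuals.ss_fit <- function(object, type = c("raw", "relative"), ...) {
  type <- match.arg(type)
  r <- object$target$values - fitted(object)
  if (type == "relative") {
    d <- object$target$values
    d[abs(d) < 1e-6] <- 1e-6
    r <- r / d
  }
  r
}

#' Plot a fit
#'
#' `which = "fit"` overlays the target profiles (points) and the fitted
#' model's simulated profiles (lines), one colour per gene;
#' `which = "history"` draws the best-so-far fitness trace on a log scale
#' with sensitivity-analysis and exploration generations marked.
#'
#' @param x an [ss_infer()] fit.
#' @param which `"fit"` or `"history"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ss_fit <- function(x, which = c("fit", "history"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    obs <- x$target
    pred <- predict(x)
    n <- nrow(obs$values)
    graphics::matplot(obs$times, t(obs$values), pch = 1, col = seq_len(n),
                      xlab = "time", ylab = "expression level", ...)
    graphics::matlines(pred$times, t(pred$values), lty = 1,
                       col = seq_len(n))
    graphics::legend("topright", legend = obs$gene_names, col = seq_len(n),
                     lty = 1, pch = 1, cex = 0.8, bty = "n")
  } else {
    gens <- seq_along(x$history) - 1L
    graphics::plot(gens, pmax(x$history, .Machine$double.xmin), type = "l",
                   log = "y", xlab = "generation",
                   ylab = "best fitness (log scale)", ...)
    if (nrow(x$events)) {
      sa <- unique(x$events$generation[x$events$event == "sa"])
      ex <- unique(x$events$generation[x$events$event == "explore"])
      graphics::abline(v = sa, col = "grey70", lty = 3)
      graphics::abline(v = ex, col = "grey40", lty = 2)
    }
  }
  invisible(x)
}
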