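make_fake_report <- function(sens) {
  # minimal mpsa_report carrying given named sensitivities
  n <- length(sens)
  tab <- data.frame(label = names(sens), role = "g", i = 1L, j = 1L,
                    kind = "kinetic", sensitivity = unname(sens),
                    rank = rank(sens, ties.method = "first"),
                    range_low = -1, range_high = 1,
                    n_acceptable = 10L, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ranking = order(sens), n_degenerate = 0L,
                 config = mpsa_config(n_samples = 10, n_bins = 2)),
            class = "mpsa_report")
}

test_that("sensitive selection partitions at the threshold, boundary inclusive", {
  rep <- make_fake_report(c(a = 0.80, b = 0.90))
  sel <- select_sensitive(rep, 0.84)
  expect_identical(sel$sensitive, "a")
  expect_identical(sel$insensitive, "b")
  # exactly at the threshold counts as sensitive
  rep2 <- make_fake_report(c(a = 0.84, b = 0.9))
  expect_identical(select_sensitive(rep2, 0.84)$sensitive, "a")
  rep3 <- make_fake_report(c(a = 0.95, b = 0.99))
  sel3 <- select_sensitive(rep3, 0.84)
  expect_length(sel3$sensitive, 0L)
  expect_setequal(c(sel3$sensitive, sel3$insensitive), c("a", "b"))
})

test_that("the sensitive set grows monotonically as the threshold rises", {
  set.seed(71)
  rep <- make_fake_report(setNames(runif(30, 0.5, 1), paste0("P", 1:30)))
  sched <- threshold_schedule()
  prev <- character(0)
  for (k in 1:5) {
    sel <- select_sensitive(rep, sched$current)
    expect_true(all(prev %in% sel$sensitive))
    prev <- sel$sensitive
    sched <- advance_threshold(sched)
  }
  expect_setequal(select_sensitive(rep, 1)$sensitive, paste0("P", 1:30))
})

test_that("the threshold schedule rises by 0.1 from 0.84 and caps at 1", {
  s <- threshold_schedule()
  expect_equal(s$current, 0.84)
  s <- advance_threshold(s)
  expect_equal(s$current, 0.94)
  s <- advance_threshold(s)
  expect_equal(s$current, 1.0) # capped from 1.04
  s <- advance_threshold(s)
  expect_equal(s$current, 1.0)
})

test_that("tight and loose bounds are centred multiples of the constant", {
  best <- setNames(c(0.5, 0.5, -2), c("P1", "P2", "P3"))
  b <- make_bounds(best, sensitive = "P1", c_const = 0.2)
  expect_equal(unname(unlist(b["P1", c("low", "high")])), c(0.1, 0.9))
  expect_equal(unname(unlist(b["P2", c("low", "high")])), c(-0.5, 1.5))
  expect_identical(b$tag, c("sensitive", "insensitive", "insensitive"))
  # bounds always contain the centre value
  expect_true(all(b$low <= best & best <= b$high))
  # widths: sensitive < insensitive from the same constant
  w <- b$high - b$low
  expect_lt(w[1], w[2])
  expect_error(make_bounds(best, "P1", c_const = 0), "positive")
})

test_that("random control bounds keep the widths but randomize centres", {
  info <- param_info(2)
  best <- setNames(rep(0.3, 12), info$label)
  sens <- info$label[1:4]
  set.seed(72); b1 <- make_random_bounds(best, sens)
  set.seed(72); b2 <- make_random_bounds(best, sens)
  expect_identical(b1, b2)
  ref <- make_bounds(best, sens)
  expect_equal(b1$high - b1$low, ref$high - ref$low)
  # centres drawn from each parameter's initial region
  set.seed(73)
  for (trial in 1:50) {
    b <- make_random_bounds(best, sens)
    centres <- (b$low + b$high) / 2
    kin <- info$kind == "kinetic"
    expect_true(all(centres[kin] >= -3 & centres[kin] <= 3))
    expect_true(all(centres[!kin] >= 0 & centres[!kin] <= 10))
  }
})

test_that("exploration resamples within bounds but preserves the best", {
  ev <- sphere_evaluator()
  cfg <- optimizer_config(population = 15, generations = 1)
  set.seed(74)
  state <- ssie:::init_population(ev, sphere_bounds(4), cfg)
  state$bounds <- bound_set(rep(-0.5, 4), rep(0.5, 4))
  best_before <- state$best_x
  f_before <- state$best_f
  set.seed(75); s1 <- explore_population(state, ev)
  set.seed(75); s2 <- explore_population(state, ev)
  expect_identical(s1$X, s2$X)
  # the incumbent best individual survives the restart untouched, and the
  # best-so-far fitness cannot worsen (it may improve if a resampled
  # individual lands better)
  expect_equal(s1$X[1, ], best_before)
  expect_lte(s1$best_f, f_before)
  expect_true(all(s1$X[-1, ] >= -0.5 & s1$X[-1, ] <= 0.5))
  # personal bests are reset to the new positions
  expect_identical(s1$pbX, s1$X)
})

test_that("the controller fires SA and exploration on the stated schedule", {
  target <- generate_series(benchmark_spec("toy_2gene"))
  fit <- ss_infer(target, setting = 2, population = 20, generations = 20,
                  sa_interval = 5, explore_interval = 10, seed = 76,
                  sa_config = mpsa_config(n_samples = 30))
  sa_gens <- fit$events$generation[fit$events$event == "sa"]
  ex_gens <- fit$events$generation[fit$events$event == "explore"]
  expect_identical(sa_gens, c(5L, 10L, 15L, 20L))
  expect_identical(ex_gens, c(10L, 20L))
  # threshold rises 0.84 -> 0.94 -> 1.0 (capped) across rounds
  thr <- vapply(fit$sa_snapshots, `[[`, numeric(1), "threshold")
  expect_equal(thr, c(0.84, 0.94, 1.0, 1.0))
  # snapshots only at SA generations
  expect_identical(vapply(fit$sa_snapshots, `[[`, integer(1), "generation"),
                   sa_gens)
})

test_that("setting 1 never invokes the SA machinery", {
  target <- generate_series(benchmark_spec("toy_2gene"))
  fit <- ss_infer(target, setting = 1, population = 15, generations = 12,
                  sa_interval = 4, explore_interval = 6, seed = 77)
  expect_identical(nrow(fit$events), 0L)
  expect_length(fit$sa_snapshots, 0L)
  expect_error(ss_infer(target, setting = 4), "setting")
})

test_that("a fixed seed reproduces a full incremental run exactly", {
  target <- generate_series(benchmark_spec("toy_2gene"))
  args <- list(target, setting = 2, population = 15, generations = 12,
               sa_interval = 4, explore_interval = 8, seed = 78,
               sa_config = mpsa_config(n_samples = 25))
  f1 <- do.call(ss_infer, args)
  f2 <- do.call(ss_infer, args)
  expect_identical(f1$best_par, f2$best_par)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$events, f2$events)
  # best-so-far fitness stays monotone despite bound updates and restarts
  expect_true(all(diff(f1$history) <= 0))
  # setting 3 (random control bounds) also reproduces under seed
  args3 <- args; args3$setting <- 3
  f3 <- do.call(ss_infer, args3)
  f4 <- do.call(ss_infer, args3)
  expect_identical(f3$best_par, f4$best_par)
  expect_true(all(diff(f3$history) <= 0))
})

test_that("mean model sensitivity is a bounded mean over all parameters", {
  target <- null_gene3_target()
  ev <- make_evaluator(target)
  base <- ss_encode(null_gene3_model())
  s1 <- mean_model_sensitivity(base, ev,
                               sa_config = mpsa_config(n_samples = 60),
                               seed = 79)
  s2 <- mean_model_sensitivity(base, ev,
                               sa_config = mpsa_config(n_samples = 60),
                               seed = 79)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_gte(as.numeric(s1), -1)
  expect_lte(as.numeric(s1), 1)
  rep <- attr(s1, "report")
  expect_equal(as.numeric(s1), mean(rep$table$sensitivity))
})

test_that("fit methods expose the model in standard R idioms", {
  target <- generate_series(benchmark_spec("toy_2gene"))
  fit <- ss_infer(target, setting = 1, population = 30, generations = 40,
                  seed = 80)
  expect_named(coef(fit), param_info(2)$label)
  pred <- predict(fit)
  expect_s3_class(pred, "ss_series")
  expect_identical(dim(fitted(fit)), dim(target$values))
  r <- residuals(fit)
  expect_equal(r, target$values - fitted(fit))
  rr <- residuals(fit, type = "relative")
  expect_equal(sum(rr^2), as.numeric(ss_fitness(pred, target)),
               tolerance = 1e-10)
  expect_output(print(fit), "best fitness")
  expect_output(print(summary(fit)), "Inferred model")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, which = "history"))
})
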