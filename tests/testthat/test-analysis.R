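test_that("recurrent sensitivity tallies match a brute-force count", {
  # the 15-of-20 convention
  sets <- c(replicate(15, c("P14", "P64"), simplify = FALSE),
            replicate(5, "P64", simplify = FALSE))
  out <- recurrent_sensitive(sets, min_support = 15)
  expect_identical(out$label, c("P64", "P14"))
  expect_identical(out$support, c(20L, 15L))
  # single run, floor 1 -> that run's set
  expect_setequal(recurrent_sensitive(list(c("P3", "P7")), 1)$label,
                  c("P3", "P7"))
  # floor above the number of runs -> empty, not an error
  expect_identical(nrow(recurrent_sensitive(sets, 21)), 0L)
  # independent counting oracle on random run sets
  set.seed(101)
  for (trial in 1:20) {
    labels <- paste0("P", 1:12)
    runs <- replicate(8, sample(labels, sample(3:8, 1)), simplify = FALSE)
    got <- recurrent_sensitive(runs, 3)
    brute <- sapply(labels, function(l)
      sum(vapply(runs, function(r) l %in% r, logical(1))))
    expect_setequal(got$label, labels[brute >= 3])
    expect_identical(setNames(got$support, got$label)[got$label],
                     brute[got$label])
  }
})

test_that("ordering patterns sort labels by descending value", {
  v <- setNames(c(0.8, 2.1, 0.1), c("P14", "P64", "P72"))
  p <- ordering_pattern(v, c("P64", "P14", "P72"))
  expect_identical(p$pattern, "P64 > P14 > P72")
  expect_false(p$tied)
  # exact ties fall back to ascending index and are flagged
  v2 <- setNames(c(1, 1), c("P9", "P2"))
  p2 <- ordering_pattern(v2, c("P9", "P2"))
  expect_identical(p2$pattern, "P2 > P9")
  expect_true(p2$tied)
  # two labels produce one of the two possible orderings
  p3 <- ordering_pattern(setNames(c(1, 2), c("P1", "P2")), c("P1", "P2"))
  expect_identical(p3$labels, c("P2", "P1"))
  expect_error(ordering_pattern(v, "P64"), "two")
  expect_error(ordering_pattern(v, c("P64", "Pxx")), "unknown")
})

test_that("pattern support reproduces the published tally arithmetic", {
  # five runs sharing one pattern, six sharing another, one singleton
  pats <- c(
    setNames(replicate(5, c("P64", "P14", "P72"), simplify = FALSE),
             c(1, 4, 7, 8, 12)),
    setNames(replicate(6, c("P64", "P72", "P14"), simplify = FALSE),
             c(9, 13, 14, 15, 16, 19)),
    setNames(list(c("P14", "P64", "P72")), 3))
  out <- pattern_support(pats, min_support = 5)
  expect_identical(nrow(out), 2L)
  row <- out[out$pattern == "P64 > P14 > P72", ]
  expect_identical(row$support, 5L)
  expect_identical(row$runs, "1, 4, 7, 8, 12")
  expect_identical(out$support[1], 6L) # sorted by support
  # all runs disagree -> every support is 1, all filtered at the floor
  distinct <- list(c("a", "b"), c("b", "a"))
  expect_identical(nrow(pattern_support(distinct, 5)), 0L)
  # supports partition the runs when every run yields a full ordering
  all_supports <- pattern_support(pats, min_support = 1)
  expect_identical(sum(all_supports$support), length(pats))
  # grouping equals a brute-force dictionary tally on random run sets
  set.seed(102)
  for (trial in 1:20) {
    perms <- replicate(10, paste(sample(c("x", "y", "z")), collapse = " > "))
    got <- pattern_support(as.list(perms), min_support = 1)
    brute <- table(perms)
    expect_identical(setNames(got$support, got$pattern)[names(brute)],
                     setNames(as.integer(brute), names(brute)))
  }
})

test_that("scaffold extraction maps kinetic orders to signed edges", {
  genes <- c("lexA", "uvrA", "uvrD", "recA", "umuD", "polB")
  info <- param_info(6)
  h11 <- info$label[info$role == "h" & info$i == 1 & info$j == 1]
  g21 <- info$label[info$role == "g" & info$i == 2 & info$j == 1]
  edges <- infer_structure(c(h11, g21), genes)
  expect_identical(nrow(edges), 2L)
  self <- edges[edges$parameter == h11, ]
  expect_identical(self$source, "lexA")
  expect_identical(self$target, "lexA")
  expect_identical(self$effect, "inhibition") # lexA -| lexA
  act <- edges[edges$parameter == g21, ]
  expect_identical(act$source, "lexA")
  expect_identical(act$target, "uvrA")
  expect_identical(act$effect, "activation") # lexA -> uvrA
  # rate constants contribute no edges; empty input gives an empty list
  a1 <- info$label[info$role == "alpha" & info$i == 1]
  expect_identical(nrow(infer_structure(a1, genes)), 0L)
  expect_identical(nrow(infer_structure(character(0), genes)), 0L)
  expect_error(infer_structure("P9999", genes), "unknown")
})

test_that("signed mode reads the exponent's sign", {
  genes <- c("a", "b")
  info <- param_info(2)
  g12 <- info$label[info$role == "g" & info$i == 1 & info$j == 2]
  h12 <- info$label[info$role == "h" & info$i == 1 & info$j == 2]
  vals <- setNames(rep(0, 12), info$label)
  vals[g12] <- -1.5; vals[h12] <- -0.5
  edges <- infer_structure(c(g12, h12), genes, mode = "signed",
                           values = vals)
  expect_identical(edges$effect[edges$parameter == g12], "inhibition")
  expect_identical(edges$effect[edges$parameter == h12], "activation")
  expect_error(infer_structure(g12, genes, mode = "signed"), "values")
})

test_that("the cross-run pipeline turns fitted runs into a coherent scaffold", {
  # end-to-end mechanics on real (short) fits: per-run sensitive kinetic
  # orders -> recurrence tally -> edge list. Structural interpretation of
  # the edges is qualitative and is discussed in the vignette; here we
  # check the pipeline's invariants on genuine inference output.
  m <- dataset1_model()
  target <- generate_series(benchmark_spec("dataset1"))
  info <- param_info(5)
  tops <- lapply(1:3, function(s) {
    fit <- ss_infer(target, method = "gapso", setting = 2, population = 60,
                    generations = 200, sa_interval = 100,
                    explore_interval = 200, seed = s,
                    sa_config = mpsa_config(n_samples = 150))
    tab <- fit$sa_snapshots[[length(fit$sa_snapshots)]]$report$table
    tab <- tab[tab$kind == "kinetic", ]
    tab$label[order(tab$rank)][1:8]
  })
  rec <- recurrent_sensitive(tops, min_support = 2)
  # recurrence tally agrees with a brute-force count
  for (k in seq_len(nrow(rec)))
    expect_identical(rec$support[k], sum(vapply(tops, function(tt)
      rec$label[k] %in% tt, logical(1))))
  edges <- infer_structure(rec$label, m$gene_names)
  # exactly one edge per sensitive kinetic-order label, none from rates
  expect_identical(nrow(edges), nrow(rec))
  expect_setequal(edges$parameter, rec$label)
  expect_true(all(edges$source %in% m$gene_names))
  expect_true(all(edges$target %in% m$gene_names))
  roles <- info$role[match(edges$parameter, info$label)]
  expect_true(all(roles %in% c("g", "h")))
  expect_identical(edges$effect,
                   ifelse(roles == "g", "activation", "inhibition"))
})
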