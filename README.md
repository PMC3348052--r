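# ssie — Sensitivity-Based Incremental Evolution for S-System Gene Network Inference

`ssie` reverse engineers gene regulatory networks from time-course
expression data. It is written for systems biologists and methods
researchers who model a network of `N` genes as an **S-system**, the
power-law ODE model

    dx_i/dt = alpha_i * prod_j x_j^g_ij  -  beta_i * prod_j x_j^h_ij

where `x_i` is the expression level of gene `i`, the non-negative rate
constants `alpha_i`, `beta_i` set the scale of production and degradation,
and the real kinetic orders `g_ij`, `h_ij` encode the strength and sign of
gene `j`'s influence on gene `i`. Fitting the model means estimating all
`2N(N+1)` parameters at once (220 for ten genes) so that the simulated
dynamics reproduce the data, scored by the relative squared error

    F = sum_i sum_t ( (x_i^a(t) - x_i^d(t)) / x_i^d(t) )^2

between the candidate's trajectory `x^a` and the measured series `x^d`.

The package's contribution is the coupling of two pieces:

1. **m-MPSA**, a modified multi-parameter sensitivity analysis. One
   parameter at a time, 500 Monte Carlo draws are taken from a range
   centred on the current best value (half-width one third of the search
   region's upper bound); each candidate is scored, classified acceptable
   or unacceptable against the threshold `C_r = 3 x` best value, and the
   parameter's sensitivity is the Pearson correlation between the two
   classes' cumulative frequency distributions over ten bins. Low
   correlation = sensitive: acceptability depends strongly on where the
   parameter sits.
2. **Incremental evolution.** A population optimizer (canonical PSO, a
   breeding-swarms GA-PSO hybrid, or DE/rand/1/bin) minimizes `F`. Every
   500 generations an m-MPSA round ranks all parameters; parameters whose
   sensitivity is at or below a rising threshold (0.84, +0.1 per round,
   capped at 1) join the sensitive list and get tight bounds (best value
   +/- 2x0.2), the rest get loose bounds (+/- 5x0.2). Every 1000
   generations an exploration restart resamples the population inside the
   active bounds, preserving the global best. Constraining the most
   influential parameters first yields fits that are both better-fitting
   and more robust to parameter perturbation.

Ground-truth five-gene and ten-gene benchmark networks are built in, along
with decoupled per-gene estimation (for inferring one gene's equation
against measured profiles of the others), and cross-run analyses:
recurrently sensitive parameters, qualitative parameter orderings
(`P64 > P14 > P72`-style patterns), and network-scaffold extraction from
sensitive kinetic orders (sensitive `g_ij` → activation edge `j → i`,
sensitive `h_ij` → inhibition edge `j ⊣ i`).

## Worked example

```r
library(ssie)

spec   <- benchmark_spec("dataset1")     # 5-gene ground-truth network
target <- generate_series(spec)          # 5 x 30 synthetic series
fit    <- ss_infer(target, method = "gapso", setting = 2,
                   population = 200, generations = 2000,
                   sa_interval = 500, explore_interval = 1000, seed = 1)
fit
```

```
S-system network inference fit
  method: gapso (setting 2), seed 1
  genes: 5  parameters: 60
  generations: 2000  evaluations: 400598
  best fitness: 0.000281732
  events: 4 SA rounds, 2 explorations
```

The best fitness is the relative squared error summed over 5 genes x 30
time points; 2.8e-4 means the inferred trajectories overlay the target
(compare setting 1, the plain optimizer, which reaches 8.4e-4 on the
same seed and budget). The four SA rounds are the generations 500, 1000,
1500, 2000 bound updates; `fit$sa_snapshots` holds each round's full
sensitivity ranking. Standard idioms work: `coef(fit)` (named flat
parameter vector), `predict(fit)` / `fitted(fit)` / `residuals(fit)`,
`plot(fit)` (target vs fitted trajectories) and
`plot(fit, which = "history")` (best-fitness trace with SA/exploration
marks), `summary(fit)` (prints the inferred equations).

A sensitivity report on its own:

```r
ev  <- make_evaluator(target)
rep <- run_mpsa(coef(fit), ev)   # 60 parameters x 500 draws
rep                               # ranked table, lowest CF first
mean_model_sensitivity(coef(fit), ev, seed = 1)  # robustness score
```

A shell interface covers the same pipeline
(`benchmark`, `simulate`, `sa`, `infer`, `analyze` subcommands):

```sh
Rscript inst/cli/ssie.R benchmark --id dataset1 --out series.tsv
Rscript inst/cli/ssie.R infer --data series.tsv --setting 2 --seed 7 --out run1/
Rscript inst/cli/ssie.R analyze --runs run1,run2 --min-support 2 --out analysis/
```

## Documentation

The methods vignette (`vignettes/sensitivity-incremental-inference.Rmd`)
describes the model, the m-MPSA algorithm, the optimizers, every tunable
default and the numerical choices (integration step sizes, degenerate-case
sentinels, tie-breaks), what the synthetic benchmarks do and do not show
about real data, and known limitations.
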