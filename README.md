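# hsasca

Swarm-metaheuristic hyperparameter tuning for gradient-boosted-tree models
of daily air quality, built around a **hybrid self-adaptive sine cosine
algorithm (HSA-SCA)**, with the full multi-run comparison protocol,
statistical-significance validation, and Shapley-value model
interpretation. The motivating application is regression of daily
benzo(a)pyrene (B[a]P) concentration — a carcinogenic PAH with strong
cold-season peaks — on co-measured pollutants (PM10, As, Cd, Ni, Pb, SO2,
NO, NO2, NOx) and meteorology; a seeded synthetic generator reproduces
that data structure so every part of the pipeline is testable end to end.

## The method

Hyperparameter selection is cast as minimization of held-out MSE over a
six-dimensional box: learning rate η ∈ [0.1, 0.9], `min_child_weight` ∈
[1, 10], `subsample` ∈ [0.01, 1], `colsample_bytree` ∈ [0.01, 1],
`max_depth` ∈ [3, 10] (integer), split-loss γ ∈ [0, 0.8].

The sine cosine algorithm updates each solution component around the
best-so-far destination P\*:

    x' = x + r1·sin(r2)·|r3·P* − x|   (r4 < 0.5; cosine branch otherwise)

with r1 shrinking linearly from a = 2 and fresh draws of r2 ∈ U(0, 2π),
r3 ∈ U(0, 2), r4 ∈ U(0, 1) per component. The firefly update moves a
solution towards a brighter one with distance-decaying attractiveness
plus a Gaussian walk:

    x' = xᵢ + β0·e^(−γ·r²ᵢⱼ)·(xⱼ − xᵢ) + αₜ·(κ − 0.5)

The hybrid runs pure SCA for the first `vs = ⌈maxIter/5⌉` iterations,
then lets each solution choose per iteration: SCA with probability `sm`
(starting at 0.8 and decaying by a tenth of its value per hybrid
iteration, `sm ← sm − sm/10`), otherwise a firefly move towards P\*.
Early exploration hands over smoothly to late exploitation.

Model quality is reported as MSE, RMSE, MAE, R², Pearson R and Willmott's
index of agreement `IA = 1 − Σ(a−â)² / Σ(|â−ā|+|a−ā|)²` ∈ [0, 1].
Optimizers are compared over paired multi-run experiments (default 20
runs × population 40 × 20 iterations) with a Levene → Shapiro–Wilk →
paired-t significance chain, and the tuned model is interpreted with
TreeSHAP attributions, including per-prediction *relative* shares
`|φ(i,f)| / Σ_g |φ(i,g)|`.

## Worked example

```r
library(hsasca)

d <- generate_dataset(generator_params(), seed = 3)   # 645 daily records
problem <- split_dataset(d, seed = 3)                 # seeded 70/30 split
tuned <- run_hsa_sca(tuning_objective(problem), default_search_space(),
                     n = 10, max_iter = 8, seed = 3)
glance(tuned)
#> # A tibble: 1 × 5
#>   algorithm best_fitness iterations evaluations  seed
#>   <chr>            <dbl>      <int>       <int> <dbl>
#> 1 hsa-sca           2.07          8          90     3
```

The best fitness is the held-out MSE (ng/m³)² of the best hyperparameter
configuration found in 90 model trainings. Decoding and refitting it:

```r
config <- decode_position(tuned$best_position)
config
#> # A tibble: 1 × 6
#>     eta min_child_weight subsample colsample_bytree max_depth gamma
#>   <dbl>            <dbl>     <dbl>            <dbl>     <dbl> <dbl>
#> 1 0.402             5.15     0.365                1         3 0.443
config_metrics(config, problem)
#> # A tibble: 1 × 6
#>     mse  rmse   mae    r2     r    ia
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1  2.07  1.44 0.823 0.763 0.879 0.923
```

The refit MSE reproduces the fitness exactly (training is seeded from the
problem), R² = 0.76 and IA = 0.92 on the 194 held-out days. Interpreting
the tuned model over all observations:

```r
model <- fit_boosted_model(config, problem)
attr <- compute_attributions(model, d[problem$feature_names])
head(mean_abs_importance(attr), 5)
#> # A tibble: 5 × 4
#>   feature mean_abs_shap mean_relative_pct share_of_mean_abs_pct
#>   <chr>           <dbl>             <dbl>                 <dbl>
#> 1 TMPS            0.898             28.7                  28.0
#> 2 As              0.537             16.9                  16.7
#> 3 PM10            0.303              8.79                  9.42
#> 4 T02M            0.165              6.30                  5.15
#> 5 WDSP            0.118              3.63                  3.67
```

Surface temperature dominates (mean |SHAP| 0.90 ng/m³, a 29% mean
relative share), followed by arsenic and PM10 — exactly the effect-size
ordering the generator declared (`ground_truth_importance()`), so the
attribution pipeline recovers the known drivers. `dependence_data(attr,
"TMPS")` exports the per-day (value, SHAP) series behind a dependence
plot; `plot_importance()`, `plot_convergence()` and `autoplot()` draw the
standard figures.

The full comparison protocol is one call:

```r
records <- run_experiment(problem, algorithms = c("hsa-sca", "sca", "fa"),
                          n_runs = 20, population = 40, iterations = 20)
summarize_experiment(records)   # Best/Worst/Mean/Median/Std/Var per algorithm
stat_report(records)            # Levene, Shapiro-Wilk, paired-t vs contenders
export_tables(records, "results/")
```

A thin command-line wrapper (`inst/scripts/hsasca-cli.R`) exposes
`simulate`, `compare` and `explain` subcommands over the same functions.

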