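# methylscore

Methylation risk scores from MWAS summary statistics, with structural
priors and a spike-and-slab Gibbs sampler.

## What this is for

A methylation score (MS) is the methylation analogue of a polygenic risk
score: per-probe weights derived from methylome-wide association (MWAS)
summary statistics are combined with an individual's methylation profile
into a single predictive number, `S = M'B`, where `M` is the probes ×
samples methylation matrix and `B` the per-probe weights. Summary-statistic
PRS samplers need a variant–variant correlation prior; genotypes use
linkage disequilibrium, but methylation has no LD analogue. This package is
for epigenetics researchers who want to build and compare methylation
scores under different structural substitutes for LD:

* **co-methylated regions (CMR)** — proximity + correlation chaining of
  array probes (`corlo`/`maxprbdst`/`corlodst` knobs, lenient defaults
  0.2 / 100 kb / 800 bp);
* **sliding windows** — proximity-only chaining (presets 5 kb – 1 Mb);
* **TAD intervals** — assignment of probes to topologically associating
  domains from a BED scaffold;
* **random clusters** — a size-matched null (counts ~ `Normal(2880, 144)`,
  sizes ~ `LogNormal(log 82, 0.7)`) for judging whether structure matters.

Each prior defines the blocks of a sparse block-diagonal Pearson
correlation matrix `R`. The core fitter is a spike-and-slab (point-normal)
Gibbs sampler over standardized marginal effects
`beta_std = (beta/se)/sqrt(n)`: each effect is zero with probability
`1 - p` or `Normal(0, h2/(M p))` otherwise; each sweep performs block-local
residual updates and then refreshes the hyperparameters from all blocks —
`p ~ Beta(1 + Mc, 1 + M - Mc)` and `h2 = beta' R beta`, clamped below at a
floor (default `1e-5`, which is also the documented override when the
moment-based initialization of `h2` turns out non-positive). Scores are
evaluated by logistic regression with Nagelkerke R², a Wald p-value and
AIC; a clump+threshold baseline is included for comparison. A synthetic
study generator (block-correlated methylation, sparse effects, a
liability-threshold binary phenotype) makes every stage testable without
any data downloads.

## Worked example

Simulate a small study, fit three priors, and compare:

```r
library(methylscore)

st <- generate_study(sim_config(m_probes = 300, n_train = 800,
                                n_test = 400, seed = 7))
report <- run_pipeline(st$summary, st$test$mat, st$annotation,
                       st$test$pheno,
                       priors = c("window:500", "random:1", "baseline-pt"),
                       gibbs = gibbs_config(burn_in = 200, n_iter = 200,
                                            seed = 3))
print(as.data.frame(report), digits = 3)
#>         model  p_value nagelkerke_r2 aic pct_probes_clustered
#> 1  window:500 3.47e-16         0.290 446                  100
#> 2    random:1 3.18e-14         0.239 465                  100
#> 3 baseline-pt 2.97e-14         0.240 465                  100

glance(attr(report, "fits")[["window:500"]])
#> # A tibble: 1 × 7
#>   method h2_mean p_mean m_c_mean h2_init n_iter burn_in
#>   <chr>    <dbl>  <dbl>    <dbl>   <dbl>  <int>   <int>
#> 1 auto     0.274 0.0254     6.57   0.263    200     200
```

The window prior matches the study's true correlation blocks and explains
the most phenotypic variance (Nagelkerke R² 0.29, lowest AIC); the random
null and the clump+threshold baseline trail it. The sampler's hyperparameter
chains recover the simulation truth (`h2` 0.3, polygenicity 0.02) as
posterior means 0.274 and 0.025. `tidy()` on a fit returns per-probe
posterior means and inclusion probabilities; `autoplot()` draws the chain
traces.

A thin command-line wrapper covers the same flow
(`exec/methylscore simulate ...`, `exec/methylscore all ...`).

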