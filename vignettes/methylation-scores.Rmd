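---
title: "Methylation risk scores with structural priors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation risk scores with structural priors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscore)
```

## The problem

A methylation score (MS) condenses an individual's DNA-methylation profile
into a single number predictive of a phenotype, in direct analogy to a
polygenic risk score (PRS): per-probe weights are derived from
methylome-wide association (MWAS) summary statistics on a training cohort,
and the score for a test individual is the weighted sum of their methylation
values, `S = M'B`.

Summary-statistic PRS methods such as spike-and-slab Gibbs samplers need a
variant–variant correlation prior. For genotypes that prior is linkage
disequilibrium (LD) from an external reference. Methylation has no LD
analogue, so a structural substitute must be chosen. This package implements
the adaptation of the summary-statistic sampler to methylation arrays with
four interchangeable structural priors, each a partition of the probe set
into blocks of a sparse block-diagonal Pearson correlation matrix `R`:

* **Co-methylated regions (CMR)** — position-sorted consecutive probes are
  chained when they are close (`maxprbdst`, default 100,000 bp), correlated
  (`corlo`, default 0.2), and, when a reference CpG map is supplied, no gap
  between intervening reference CpGs exceeds `corlodst` (default 800 bp).
  The defaults are deliberately lenient so as many probes as possible
  cluster.
* **Sliding windows** — the proximity-only degeneration of CMR chaining
  (`corlo` vanishing): consecutive probes chain when their gap is at most
  the window size. Documented presets: 5 kb, 10 kb, 20 kb, 100 kb, 500 kb,
  1 Mb.
* **TAD intervals** — probes are assigned to the topologically associating
  domain containing them (BED intervals, 0-based half-open; probe positions
  are 1-based and converted before lookup). Unassigned probes become
  singletons; with overlapping domains the interval with the smallest start
  (then smallest end) wins.
* **Random clusters** — a null model that mimics the TAD cluster-size
  profile without any genomic structure: per set, a cluster count
  `C ~ Normal(2880, 144)` and sizes `P ~ LogNormal(log 82, 0.7)`, probes
  assigned by a random permutation. Ten such sets give a reference
  distribution for judging whether a structured prior adds information
  beyond its size profile.

## The model

Marginal effects are standardized to `beta_std = (beta/se)/sqrt(n)`
(sampling variance about `1/n`). The point-normal (spike-and-slab) model
places each standardized effect at zero with probability `1 - p` and at
`Normal(0, sigma^2)` with `sigma^2 = h2/(M p)` otherwise, where `M` is the
probe count, `h2` the total variance explained and `p` the polygenicity.

Each Gibbs sweep updates every probe in canonical (chromosome, position)
order within its block: the block-local residual
`r_j = beta_std_j - sum_{k != j} R_jk beta_k` feeds a Bernoulli inclusion
draw with probability

```
1 / (1 + (1-p)/p * sqrt(1 + n_j sigma^2) * exp(-r_j^2 n_j^2 sigma^2 / (2 (1 + n_j sigma^2))))
```

and, if included, a Gaussian draw with mean `r_j / (1 + 1/(n_j sigma^2))`
and variance `(1/n_j) / (1 + 1/(n_j sigma^2))`. After each sweep the
hyperparameters refresh from all blocks: `p ~ Beta(1 + Mc, 1 + M - Mc)`
with `Mc` the nonzero count, and `h2 = beta' R beta` computed blockwise —
a deterministic moment update in the spirit of the auto scheme, cheap and
reproducible, clamped below at `h2_floor`. The posterior effect `B` is the
post-burn-in mean. The `p = 1` limit has a closed form per block,
`(R + (M/(n h2)) I) beta = beta_std` (`ldpred_inf()`), which doubles as an
independent oracle for the sampler in the test suite.

### Initialization and the negative-heritability failure mode

`h2` is initialized by an LD-score-style moment estimator:
`M (mean(chi2) - 1) / (mean(n) mean(l))` with `chi2_j = n_j beta_std_j^2`
and `l_j = sum_k R_jk^2`. Under a null, or with ill-conditioned blocks, the
estimate is legitimately non-positive; the sampler then refuses to start
unless an explicit `h2_init` override is given. The documented workaround —
setting the initialization to `1e-5` — is a first-class option, and `1e-5`
is also the default chain floor. `conditioning_report()` surfaces blocks
with minimum eigenvalues below tolerance (default `1e-8`), and
`regularize_blocks()` offers identity shrinkage as an optional mitigation
(off by default; the documented workaround overrides the initialization
instead).

### Numerical and design choices

* **Sampler settings.** Defaults: 500 burn-in and 500 retained sweeps,
  `p_init = 0.1`, mandatory seed. These are package-level choices; chains
  are exported so convergence can be inspected (`autoplot()`).
* **Determinism.** Within-sweep order is the canonical probe order of the
  standardized-effects input; blocks are remapped onto it before sampling,
  so the same seed gives bit-identical results regardless of how the block
  list is ordered.
* **Divergence guard.** If any per-probe effect exceeds `beta_bound`
  (default 5 on the standardized scale, far above any plausible effect) the
  run aborts naming the sweep — the expected symptom of a severely
  ill-conditioned `R`.
* **Correlation predicate.** The CMR rule uses the signed correlation
  (`r >= corlo`): an anti-correlated pair does not form a co-methylated
  region. Consequently the vanishing-threshold degeneration to sliding
  windows is exact only where adjacent sample correlations are positive —
  which is the defining property of co-methylated data, and the regime the
  proximity-only construction presumes. Zero-variance probes have undefined
  correlation and fail the predicate conservatively (they are a hard error
  in correlation-matrix construction, where a block would otherwise be
  undefined).
* **Null identifiability.** When the slab variance is pushed to the floor
  (null data with the `1e-5` override), the inclusion probability tends to
  `p` itself and the `p` chain equilibrates near 0.5 while all effects stay
  at zero: `p` is unidentified when nothing is included. With an
  appreciable slab variance the spike dominates and the `p` chain settles
  near its `Beta(1, 1 + M)` prior. Read `p` chains with this caveat.
* **Random-cluster rounding.** The count draw is rounded to the nearest
  integer and resampled if non-positive; size draws are rounded with a
  floor of 1. If drawn sizes exhaust the probes, later clusters are
  truncated or dropped; leftover probes become singletons. Each set uses
  its own seeded stream (`seed + set index - 1`). Chromosome coherence is
  deliberately not enforced — the null must lack genomic structure.
* **Evaluation.** Scores are evaluated by logistic regression
  `logit Pr(y=1) = a + b S`; reported: the Wald p-value for `b` (a
  likelihood-ratio p is also computed), `AIC = 4 - 2 l1`, and Nagelkerke
  R² `= [1 - exp(2(l0-l1)/n)]/[1 - exp(2 l0/n)]`. Complete separation is
  flagged (R² reported as `1 - 1e-8`), not fatal. Test methylation is used
  as-is: the intended input is residualized methylation, and no covariate
  adjustment is performed.
* **Leakage.** Correlation blocks are built from the same test matrix that
  is later scored, mirroring the analysis this package reproduces;
  `run_pipeline(ref_mat = ...)` accepts an independent reference matrix
  instead.
* **Baseline.** The clump+threshold comparator greedily keeps the
  lowest-p probe per cluster, drops probes with `|r|` above
  `sqrt(r2_prune)` against kept probes, applies `p <= p_thresh`, and scores
  with raw marginal effects.

## What the synthetic generator emulates

`generate_study()` draws a two-cohort study: standardized Gaussian
methylation with block-compound-symmetric correlation (default blocks of
10 probes at rho 0.5), a causal set of `round(p_true m)` probes with
`Normal(0, h2/(m p))` effects, a liability-threshold binary phenotype
(liability = genetic value + `Normal(0, 1 - h2)` noise, thresholded at the
theoretical `1 - prevalence` Gaussian quantile), and training-side marginal
OLS summary statistics. Defaults — 2,000 probes, 5,000 training and 1,000
test samples, `h2 = 0.3`, `p = 0.02`, prevalence 0.4 — define the package's
reference conditions, stand-ins for a real training meta-analysis and
private test cohort at roughly desk scale.

Probes are laid out regularly spaced within correlation blocks with a
ten-fold larger gap between blocks, so a sliding window equal to the probe
spacing recovers the true blocks exactly — letting end-to-end tests
separate sampler behavior from clustering error. Gaussian methylation is
used rather than bounded beta-values because the intended input is
residualized (covariate effects removed), hence effectively unbounded; the
generator does not emulate cell-type composition, batch structure, or the
residualization itself. The marginal scan is linear rather than logistic,
consistent with the standardized-effect bridge. Passing tests on this
generator therefore demonstrate correctness of the machinery under the
model's own assumptions, not performance on real array data.

```{r example, eval = FALSE}
st <- generate_study(sim_config(m_probes = 300, n_train = 800,
                                n_test = 400, seed = 7))
report <- run_pipeline(st$summary, st$test$mat, st$annotation,
                       st$test$pheno,
                       priors = c("window:500", "random:1", "baseline-pt"),
                       gibbs = gibbs_config(burn_in = 200, n_iter = 200,
                                            seed = 3))
report
```

## Problem sizes used in the checks

The shipped checks run at deliberately modest scale: clustering oracles on
instances of up to 100 probes; sampler-versus-closed-form agreement on
blocks of 5–20 probes with 2,000 retained sweeps; parameter recovery on
five studies of 2,000 probes × 5,000 training samples; and the
random-cluster distribution checks on 100,000 size draws and 10,000 count
draws. Monte-Carlo agreement uses batch-means standard errors with a
familywise-calibrated bound (a per-probe 3-SE cut across a 20-probe block
would false-alarm on a correct sampler about 5% of the time).

## Known limitations

* The CMR construction implements the documented three-predicate chaining
  (`corlo`, `maxprbdst`, `corlodst`) on adjacent position-sorted probes; it
  is not a byte-exact reimplementation of CoMeBack's internal CpG-density
  bookkeeping.
* `h2` is updated deterministically as `beta' R beta` rather than sampled;
  per-probe sample sizes are collapsed to their mean in the closed-form
  solver only.
* Evaluation supports a univariate score against a binary phenotype;
  covariate-adjusted or continuous-outcome evaluation is out of scope.
* The grid/validation-set variant of the fitting scheme is not provided —
  only the auto scheme with internal hyperparameter inference.
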