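# omicscreen

Simulation-based evaluation of feature-selection methods for two-group
omics screening studies with small samples and many features (n ≪ p) —
the setting of a typical untargeted metabolomics or gene-expression
screen, where the goal is to pass a reduced candidate list to follow-up
experiments while keeping false negatives low.

The package provides, as tested and reusable components:

* **a synthetic-data generator** — feature means drawn from a gamma(50, 1/50)
  distribution; samples from a multivariate normal with three
  compound-symmetry correlated blocks (ρ within, 0 between, unit variance)
  plus independent noise features; 4 differential features per block with
  group-mean shifts Δ ∈ {0.2, 0.5, 0.8} (Cohen's d scale); a standard
  20-scenario grid crossing p ∈ {205, 2050}, ρ ∈ {0.4, 0.8},
  n ∈ {10, …, 100};
* **a per-feature ANOVA screen** — the two-group one-way F-test
  (F = t² with df (1, n−2)) computed from sums of squares and vectorized
  over features, with Benjamini–Hochberg FDR adjustment and strict
  thresholds at raw 0.05, FDR 0.05 and FDR 0.20;
* **elastic-net penalized logistic regression** — the penalized likelihood

  −(1/n) Σⱼ [yⱼηⱼ − log(1+e^ηⱼ)] + λ[(1−α)/2‖β‖₂² + α‖β‖₁]

  minimized by pathwise coordinate descent inside IRLS (C++), with a
  100-value λ path, warm starts, 10-fold cross-validation on binomial
  deviance and the one-standard-error rule; selection = nonzero
  coefficients, so α = 0 (ridge) selects everything and α = 1 (LASSO)
  selects at most n features;
* **an evaluation and experiment harness** — power per effect size, Type I
  error on the noise features, and the separately-tracked selection rate of
  correlated-but-null features, aggregated over replicates with
  replicate-level Monte-Carlo standard errors, over any scenario grid and
  method roster, fully seeded and resumable. The same roster applies to a
  real feature table (`apply_to_table()`), with per-stratum FDR adjustment
  (e.g. positive/negative ion mode).

## Worked example

```r
library(omicscreen)

res <- run_scenario(
  scenario_spec(n_total = 100),          # p = 205, rho = 0.4
  methods    = c("anova_raw05", "anova_fdr20", "enet:0.5", "enet:1"),
  replicates = 30, base_seed = 1
)
subset(res, metric %in% c("power", "type1") & delta_or_block %in% c(0.8, NA),
       select = c(method, metric, estimate, mc_se))
```

```
        method metric   estimate       mc_se
3  anova_raw05  power 0.97500000 0.013927150
7  anova_raw05  type1 0.04566667 0.003856129
10 anova_fdr20  power 0.86666667 0.035423005
14 anova_fdr20  type1 0.01100000 0.001997124
17    enet:0.5  power 0.89166667 0.028575704
21    enet:0.5  type1 0.09500000 0.013727646
24      enet:1  power 0.70000000 0.042209113
28      enet:1  type1 0.04333333 0.008013399
```

Reading the rows: at n = 100 and p = 205, the unadjusted ANOVA detects the
large effect (Δ = 0.8) in ~98% of replicates while holding its noise-feature
Type I error at the nominal 0.05; FDR adjustment at 0.20 trades a little
power for a Type I error near zero. The elastic net at α = 0.5 has
comparable power but roughly double the nominal false-positive rate on the
noise features at this (small-p, larger-n) configuration, and the LASSO
(α = 1) pays for its sparsity with the lowest power of the roster. Each
estimate is a mean over replicates of per-replicate selection proportions;
`mc_se` is its Monte-Carlo standard error.

Single pieces are usable on their own:

```r
ds  <- simulate_dataset(scenario_spec(20, rho = 0.8, seed = 1))
scr <- anova_screen(ds$values, ds$labels)       # F, p_raw, p_adj, selections
cv  <- cv_enet(ds$values, as.integer(ds$labels == 2),
               enet_config(alpha = 0.5, seed = 1))
sum(selected_set(cv))
```

A thin CLI over the same functions lives at
`inst/scripts/omicscreen-cli.R` (subcommands `simulate`, `run-grid`,
`apply`).

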