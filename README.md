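# kdereg

Kernel-density regulation scoring for tightly coupled two-gene regulatory
pairs.

## The problem

Some cellular processes are controlled by exactly two opposing enzymes. The
canonical example is protein O-GlcNAcylation: a single writer (OGT, the
O-GlcNAc transferase) and a single eraser (OGA, the O-GlcNAcase) jointly
maintain modification homeostasis, and their *joint* expression — not either
gene alone — reflects whether the system is regulated. Direct measurement of
the modification is low-throughput and unstable ex vivo, but transcriptomes
are abundant. `kdereg` infers per-sample dysregulation of such a gene pair
from expression data alone.

Classical cohort statistics (correlation, mutual information, PCA variance,
CV, Jensen–Shannon divergence) summarize a whole cohort, assume a functional
form, or both. `kdereg` instead asks, for each individual sample: *how
densely populated by healthy samples is this point of the joint expression
plane?*

## The model

A bivariate Gaussian product-kernel density estimate is fitted to the `m`
healthy reference samples:

    KDE(x, y) = 1/(m·h₁·h₂) · Σᵢ φ((x − x₁ᵢ)/h₁) · φ((y − x₂ᵢ)/h₂)

with per-gene bandwidths from the interquartile range,

    hⱼ = 2 · IQR(gene j) · m^(−1/3).

A density threshold `KDEt` is set to the median density of the reference
samples themselves, so 50% of the healthy cohort falls in the high-density
region. Each sample's density `KDEᵢ` is then mapped piecewise-linearly to a
regulation score:

    score = 0.5 · (KDEᵢ − min) / (KDEt − min)                 if KDEᵢ ≤ KDEt
    score = 0.5 + 0.5 · (KDEᵢ − KDEt) / (max − KDEt)          if KDEᵢ > KDEt

with `min = 0`, `max` the maximum reference density, and clamping to
`[0, 1]`. The median healthy sample scores 0.5; dysregulated samples drift
toward 0. A covariance-based affine alignment (Cholesky whiten/recolor of
the two-gene mean and covariance) lets a model fitted on one cohort score an
external cohort without refitting.

The package also ships the synthetic benchmark used to validate the score —
four regulatory shapes (linear, exponential, parabolic, multicluster) with
graded cancer-cohort noise inflation (1.0×/1.5×/2.0×) — plus the comparator
metric suite, AUROC / KS / Mann–Whitney testing, and a stratified five-fold
CV harness with fold-internal reference fitting.

## Worked example

```r
library(kdereg)

healthy <- simulate_gene_pair(shape_spec("linear", n_samples = 200, seed = 42),
                              cohort = "healthy")
cancer  <- simulate_gene_pair(shape_spec("linear", noise_multiplier = 2,
                                         n_samples = 150, seed = 43),
                              cohort = "cancer")

fit <- kdereg(healthy)
print(fit)
#> kdereg model: gene1 / gene2, 200 healthy reference samples
#> bandwidths: h1=0.850711 h2=0.949059 (2*IQR*m^(-1/3))
#> density threshold (median reference density): 0.0343672
#> density range for scoring: [0, 0.0515755]

scores_h <- regulation_score(fit, healthy)
scores_c <- regulation_score(fit, cancer)
mean(scores_h)   # 0.517  — healthy cohort calibrated around 0.5
mean(scores_c)   # 0.323  — noisier cancer-like cohort drifts toward 0

ks_two_sample(scores_h, scores_c)
#> KS D = 0.360, p = 4.49e-10  — score distributions clearly separate

cv <- cross_validate(bind_cohorts(healthy, cancer), "regulation_score",
                     k = 5, seed = 1)
print(cv)
#> 5-fold CV, feature 'regulation_score': mean AUROC 0.6922
```

The regulation score is the per-sample output: 0.5 is the calibrated
healthy median, values near 0 indicate joint expression far from any
high-density healthy region. The KS test and the cross-validated AUROC
quantify, respectively, distributional separation and per-sample
discriminative power of the score.

A command-line interface with subcommands `simulate`, `fit`, `score`,
`metrics`, `benchmark`, `classify`, `kstest`, `align` is available through
the installed launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "kdereg.R", package = "kdereg"))')" \
  simulate --shape linear --n 200 --seed 42 --cohort healthy --out healthy.tsv
```

Every run writes a `<out>.run.json` sidecar recording the tool version and
the fully resolved configuration.

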