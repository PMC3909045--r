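---
title: "Structure-immune modelling of iNKT-cell agonists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-immune modelling of iNKT-cell agonists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inktqsar)
```

This vignette is the package's account of its models and of the design
choices made where the methodology left room: what is computed, under which
assumptions, with which defaults, and what the synthetic benchmarks do and
do not demonstrate about real data.

## The data model

A measurement is one raw cytokine value for one compound, in one study, in
one of five test-systems (mice/in vivo, mice and human in vitro with
cell-presented or plate-bound CD1d) for one of four markers (IL-2, IFN-γ,
IL-4, IL-13) — at most 20 response slots per compound. Raw concentrations
are not comparable across studies (different units, assays, animals), so
the working quantity is the *relative response*: the ratio to the α-GalCer
reference measured in the same study, system, marker and condition. Where a
study used several doses or incubation times, the retained condition is the
one at which the reference itself peaks; ties break toward the lowest dose,
then the earliest time (a conservative, deterministic rule). Cells where
the reference response is zero are dropped rather than imputed. Replicates
from different research groups are averaged *unweighted on the ratio scale*
after per-study normalization — the averaging rule is deliberately simple
because per-study variances are rarely reported. When research groups used
different dose grids, selection happens within each study first and
averaging after; the alternative order is not identifiable from published
tables.

## Desirability axes

Each pooled response $Y$ is mapped to a desirability
$d \in [0.1, 0.9]$ linearly between anchors $(Y_{lo}, Y_{hi})$:
$d = 0.1 + 0.8\,(Y - Y_{lo})/(Y_{hi} - Y_{lo})$ for larger-better,
mirrored for smaller-better, clipped at the ends. Defaults:
$Y_{lo} = 0$ and $Y_{hi}$ = the maximum observed pooled response for that
(group, marker) — so anchors are data-derived unless overridden, and
compounds later exceeding the historical maximum clip to 0.9 instead of
erroring. The one-sided linear form is used throughout; the general
Derringer family (power/sigmoid shapes) is out of scope.

Four axes are computed per compound: Th1 and Th2, in vivo and in vitro. A
Th1 axis combines IFN-γ larger-better with IL-4 smaller-better; Th2
reverses both. The overall $D$ is the geometric mean of the components, so
$D \in [0.1, 0.9]$ and a compound with both cytokines extreme scores
$\sqrt{0.1 \times 0.9} = 0.3$ — strong but useless for polarization. The
in-vitro axes pool the human and mice *cell-cell* systems by a simple
per-compound mean before the transform (the two systems correlate strongly
and pooling gains sample size); the marginally-used plate-bound systems are
ingested and summarized but excluded from axes and models by default. IL-2
and IL-13 likewise do not enter the default axes — the axis definitions
name only IFN-γ and IL-4 — but `desirability_config(include_il13 = TRUE)`
adds IL-13 to the Th2-cytokine side for sensitivity analyses.

## Variability statistics

Intra-variability (method precision) is the per-compound relative standard
deviation (sample, $n-1$) of normalized responses across studies, for
compounds with at least two sources. Inter-variability (discriminating
power) is the spread of per-compound means corrected for replication noise:
$100\sqrt{\max(0,\; s^2_{between} - \overline{s^2}_{intra})}/\bar{Y}$,
floored at zero. The correction formula is a declared design choice — the
underlying idea ("corrected for the intrinsic intra-variability") admits
several estimators — and is isolated in `inter_rsd_corrected()` so it can
be swapped. Group comparisons of intra-RSD distributions use
Kruskal–Wallis (tie-corrected, χ² approximation); cross-model agreement
uses Spearman's ρ on complete cases with a two-sided t-approximation
p-value.

## Chemical space

Descriptor matrices are pruned of (near-)constant columns
(variance ≤ 1e-12 by default, robust to numeric noise), then unit-variance
autoscaled — the chemometrics convention — before PCA and clustering
(scaling can be disabled). PCA goes through the singular-value
decomposition of the scaled matrix (numerically stabler than
eigendecomposing the covariance; the test suite uses the eigen route as an
independent oracle) with a deterministic sign convention: the
largest-magnitude loading of each component is positive. Clustering is
agglomerative with average linkage (UPGMA) on Euclidean distances
(squared-Euclidean via config); the distance and scaling defaults are
declared choices, not inferences, since typical HCA reports omit them.

## QSAR models

**Stepwise MLR.** Entry and removal are governed by probability-of-F
thresholds, 0.05 to enter and 0.10 to remove. One subtlety is deliberate:
the forward step scans up to thousands of candidate descriptors, and the
minimum of $m$ null p-values is far below 0.05 with high probability, so a
per-candidate rule would admit noise variables almost every step. Entry is
therefore tested at the *step level*: the best candidate's p-value is
Šidák-adjusted for the number of candidates scanned
($p_{step} = 1-(1-p_{min})^m$), giving an (approximately) 5% chance per
step of admitting anything from pure noise. The classical per-candidate
convention is available via `entry_adjust = "none"`. Removal tests the
included variables' partial-F p-values unadjusted (the included set is
small). Ties break toward the lowest column index; candidates numerically
collinear with the current model (residual variance below tolerance) are
skipped, so duplicated descriptors are never co-selected. Coefficients are
reported on the original descriptor scale, with UV-scaled versions and
scaling metadata stored alongside.

**PLS.** Single-response NIPALS on UV-scaled descriptors and a centered
response; coefficients are back-transformed to the input scale. With as
many components as the predictor rank, PLS reproduces the least-squares
solution (an oracle test). The component count is chosen by seven-fold
cross-validated Q², adding components while Q² improves by at least 0.01 —
the stopping rule is ours (commercial chemometrics suites each have their
own) and both the rule's threshold and a fixed count are configurable.

**Validation.** $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{tot}$ over a seeded
balanced k-fold partition (k = 7 by default), each fold predicted by a
model refit without it; $\mathrm{SS}_{tot}$ is about the full-data mean, so
an intercept-only predictor scores ≈ 0 and permuted responses score ≤ 0.
Classification uses the strict rule: a compound is *strong* when its D
exceeds the reference's D (the reference itself is weak); ROC/AUC uses the
mid-rank Mann–Whitney formulation. Fitted-value ROC is the default
(goodness-of-fit); cross-validated predictions can be substituted where
honest prospective discrimination is the question.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Descriptors come in correlated blocks — one latent factor per
block with loading $\sqrt{\rho}$, default $\rho = 0.5$, reflecting the
strongly family-structured nature of constitutional/topological descriptor
sets while leaving each informative descriptor a detectable unique signal —
plus interspersed constant columns. The informative block carries
coefficients with $|\beta| \sim U(0.8, 1.2) \times$ `coefficient_scale` and
random signs. Responses are multiplicative: cytokine concentrations are
positive and the pipeline works on ratios, so the normalized response of
compound $i$ in cell $(s, m)$ is $\exp(x_i^\top \beta_{s,m})$ times
lognormal noise with the configured CV, and the raw value is that ratio
times a per-study reference baseline with a peaked three-dose
dose–response (so the reference-maximal selection rule is exercised). Noise
applies to the ratio, not independently to numerator and denominator, so
the configured CV is the CV of the quantity the pipeline actually uses.
The reference compound's informative descriptors are zeroed, making its
expected normalized response exactly 1 everywhere. Th1/Th2 polarization is
built in by construction: $\beta$ enters IFN-γ positively and IL-4
negatively (IL-2/IL-13 at half weight), and per-system factors make the
in-vivo effect the most polarized and the human cell-cell system the least
noisy — the directions the variability analysis is expected to recover.
Per-cell measurement probabilities default to the shipped frequency table's
counts divided by 333, reproducing realistic sparsity. Everything is
deterministic given the seed.

What the generator does *not* emulate: real descriptor distributions
(discrete counts, skewness), nonlinear structure–activity relationships,
dose-dependent polarization, inter-study heterogeneity beyond lognormal
noise, and publication bias in which compounds get measured. Passing the
synthetic benchmarks therefore shows the pipeline's statistical machinery
is correct and calibrated — not that real α-GalCer data will yield models
of any particular quality.

## Benchmark problem sizes and numerical choices

The recovery benchmark uses 150 compounds × 50 descriptors with 5
informative and noise set for a log-scale R² of 0.8 (via
`noise_cv_for_r2()`), 50 seeds; null calibration uses 100 pure-noise runs
at n = 100 × 10 descriptors and 2000-point permuted AUCs. The
literature-scale analysis scripts simulate 333 compounds × 100 descriptors
with the frequency-table sparsity. Degenerate inputs are contracts, not
silent behavior: empty models warn, zero-variance responses error,
all-identical Kruskal–Wallis inputs return H = 0 / p = 1, zero rank
variance yields a missing correlation, and the corrected inter-variability
floors at zero. Geometric means are computed on the log scale; UPGMA
heights inherit `hclust`'s deterministic agglomeration.

## Known limitations

D-values compress strongly when a few compounds dominate the observed
maximum (the anchors are data-derived), which weakens linear-model signal
on the D scale relative to the log-response scale; stepwise selection with
step-level type-I control is conservative and may return empty models on
small axes — by design, at the cost of power. The corrected
inter-variability estimator over-subtracts when replicate counts are high
(it removes the full mean intra variance, not its standard-error share).
Cross-model correlations are complete-case and can be biased by which
compounds were measured in both systems.
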