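---
title: "Methods: from canopy spectra to nitrogen-efficiency classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from canopy spectra to nitrogen-efficiency classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nitrospec)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the parameters that matter, and the design
decisions taken where the method left room for choice. The code chunks
are illustrative; the package's tests and `scripts/acceptance.R` are the
executable record of its behaviour.

## The trial structure and what is being estimated

A winter-wheat nitrogen-response trial plants each of 12 candidate
varieties at three nitrogen applications — 0, 225 and 450 kg N/ha,
i.e. low-N stress, the normal local application, and high-N stress — in
two replicate plots. Two reference varieties with known behaviour anchor
the analysis: Jimai 22, known low-N efficient (planted at 0 and
225 kg/ha only), and Shannong 28, known high-N efficient (planted at 225
and 450 kg/ha only). Canopy reflectance is recorded per plot at five
sampling regions (the plot centre and four points one fifth of the way
from each corner to the centre), giving 120 canopy-region spectra per
stress condition for the candidates.

The estimand is a per-variety label — low-N efficient, high-N efficient,
or inefficient — and, downstream, a classifier that predicts it from
reflectance alone.

## Agronomic indices

Replicate phenotypes are averaged per variety and nitrogen level before
any index is computed; the indices then compare a stress level against
the normal level:

* change rates `(stress − control)/control` of yield, above-ground
  nitrogen accumulation, dry matter mass and thousand-grain weight;
* `NUE = (WY_stress − WY_normal)/ΔN` and
  `AENF = (ANA_stress − ANA_normal)/ΔN`, with ΔN the absolute difference
  in applied nitrogen between the two levels (225 kg/ha for both
  contrasts — under the low-N contrast the literal application at the
  stress level is zero, so the applied-nitrogen *difference* is the only
  denominator that keeps the index finite; it is exposed as
  `n_denominator`);
* `NFUE`, a dry-matter ratio statistic. The package defaults to the
  *centred* ratio `WDMM_stress/WDMM_normal − 1`, so that "no change" maps
  to 0 and declines are negative, which is the only reading consistent
  with negative summary values of this index in practice; the literal
  ratio is available via `nfue_mode = "literal"`;
* `NT = WY_stress/WY_normal`, the nitrogen tolerance coefficient.

Summary statistics (`summarize_indices()`) use the sample (n−1) standard
deviation and define CV = SD/|mean|, flagged undefined when the mean is
zero.

## Efficiency labelling

The eight indices are column-standardised (constant columns map to
zeros), embedded with t-SNE, and clustered.

t-SNE is implemented in the package as the exact-gradient algorithm
(Gaussian neighbourhoods calibrated to a target perplexity by bisection,
Student-t low-dimensional kernel, momentum gradient descent with early
exaggeration): with only 12–13 variety points there is nothing to gain
from tree-based approximations, and having the optimiser in-package makes
the seed-to-embedding map fully deterministic. Defaults: 3 output
dimensions (the labelling procedure inspects three-dimensional
embeddings), 1000 iterations, perplexity 3.5. The perplexity must satisfy
`perplexity < (n − 1)/3`; 3.5 is the largest round value valid at n = 12,
and the embedding at this size is insensitive to values between 2 and
3.5. Because a 13-point embedding depends visibly on its random
initialisation, the seed is recorded in every output and a `skip_tsne`
option clusters the standardised indices directly, which is fully
deterministic and, on the synthetic trial, never disagrees with the
consensus of the embedded runs.

Clustering is agglomerative with complete linkage on Euclidean distances,
cut at k = 2 (`stats::hclust`; the test suite checks its merges against a
brute-force rescanning oracle). The cluster containing the reference
variety is labelled *efficient*; the reference itself is excluded from
the reported set. Labels from the two stress conditions combine into
three groups; a variety efficient under both conditions raises an error
rather than being silently resolved, because the grouping is only
meaningful when the two efficient sets are disjoint — on the synthetic
trial such conflicts arise only from unlucky embedding initialisations
(roughly one seed in ten), never from the direct clustering path. Each
group maps to a static fertilization strategy: maintain the standard
application (inefficient), reduce basal nitrogen and supplement P/K
foliar fertilizer (low-N efficient), or increase nitrogen with
top-dressing delayed to heading (high-N efficient).

`reflectance_cluster_baseline()` repeats the embed–cluster–anchor chain
directly on reflectance samples (variety assignment by majority vote over
its samples) and reports agreement with the phenotype-derived labels; it
quantifies how far clustering alone gets without supervised learning.

## Characteristic-band selection

Canopy spectra are smooth: adjacent bands correlate above 0.9, and most
of the 224 bands are redundant for classification.

**Lasso screen.** Bands are standardised, the two-class label is encoded
numerically (0/1 by default; ±1 available), and an L1-penalised linear
model is fitted over a log-spaced penalty grid (default `10^seq(0, -4)`,
60 values) with 5-fold cross-validation. The penalty minimising mean CV
squared error is chosen — the plain CV minimum, not the 1-SE rule, as the
simplest defensible reading of "optimal penalty" — and the bands with
non-zero coefficients survive. If everything is shrunk to zero, the
largest penalty with a non-empty selection is used with a warning.

**CARS refinement.** For runs `i = 1..N` (default N = 50): draw 80% of
the samples without replacement; fit a NIPALS PLS1 regression with A = 5
components (clipped when the retained set is smaller) on the retained
bands; weight each band `w_j = |b_j|/Σ|b_j|`; keep the top `⌈r_i·p⌉`
bands where `r_i = a·e^(−k·i)` with `a, k` fixed by `r_1 = 1` and
`r_N = 2/p` (closed form `a = (p/2)^(1/(N−1))`, `k = ln(p/2)/(N−1)`);
then adaptively resample: draw p bands with replacement proportionally to
weight and retain the union (disable with `ars = FALSE`). Ties in the
weight ranking break by ascending wavelength so reruns are bit-identical.
Each run's retained set is scored by 5-fold RMSECV of a PLS model on all
samples; the run with minimum RMSECV supplies the final subset, and the
full trace (sizes, ratios, RMSECV per run) is kept. PLS1 is implemented
in-package (no PLS package in the dependency set, and the coefficient
magnitudes are the method's importance measure); at full rank it
reproduces ordinary least squares, which the tests exploit as an oracle.

`lasso_cars()` composes the two; a single-band screen passes through
unchanged. Selection runs at the canopy-region sample level (120 samples
per condition) — the granularity at which the spectra exist — rather than
on variety means.

## The serial SVM→XGBoost fusion

Stage one standardises the selected-band features (training statistics
only, asserted by the leakage tests) and fits an RBF SVM (default
C = 10, gamma = scale heuristic; a small grid — C ∈ {0.1, 1, 10, 100},
gamma multipliers {0.1, 1, 10} — is searched by internal 3-fold CV when
`tune = TRUE`). Stage two augments each sample with:

* one decision score per class (pairwise decision values averaged per
  class with orientation, a layout whose width is stable in the class
  count), and
* per class, the maximum and mean RBF-kernel similarity of the sample to
  that class's support vectors — a concrete rendering of "support vector
  information" chosen because it is deterministic, fixed-width and
  kernel-consistent.

A gradient-boosted-tree classifier (depth 3, learning rate 0.1, 150
rounds by default; optional internal CV over depth {2, 3, 4} and rate
{0.05, 0.1, 0.3}) is trained on the augmented matrix after a fresh seeded
shuffle. The augmented features are appended to, not substituted for, the
band features.

One design point deserves emphasis: **training rows are augmented
out-of-fold** (5 inner folds). If the training rows' decision values come
from the very SVM fitted on them, the feature separates the training set
with an optimistically wide margin and the boosted trees put their split
thresholds arbitrarily inside it; held-out samples landing in the gap are
then misclassified, and the fusion's cross-validated accuracy fell well
below the plain SVM's on cleanly separable data. With out-of-fold
augmentation — the standard stacking construction — the feature
distribution the trees see at training time matches prediction time, and
the fusion matches the SVM on easy problems while beating it clearly on
nonlinear ones (the interleaved-spirals fixture in the test suite:
roughly 97% vs 82% mean OA). `oof_folds = 0` restores the in-sample
variant.

Baselines: standalone SVM, random forest (500 trees), XGBoost on the raw
band features, and AdaBoost. AdaBoost is implemented in-package as
multi-class SAMME over shallow CART trees (rpart stumps by default), as
no boosting-by-reweighting package is in the dependency set.

## Evaluation

`stratified_folds()` partitions samples into k = 10 folds, stratifying on
the class label nested within a treatment group, dealing each group×class
cell round-robin so per-fold class counts deviate by at most one sample;
classes with fewer than k members are spread as evenly as possible rather
than erroring, since real trials have small classes. All preprocessing is
fitted inside training folds. Overall accuracy and Cohen's kappa are
computed per fold from the fold's confusion matrix; the headline numbers
are the means over folds (the pooled matrix and its metrics are also
reported). Folds whose training data collapse to a single class are
skipped with a warning and recorded. Comparison tables
(`compare_models()`, `compare_band_inputs()`) reuse one fold assignment
across all rows — the assignment is hashed into the table attributes so
equality is checkable — and the band-input table always carries a
full-spectrum row.

## The synthetic trial: what it does and does not emulate

`generate_spectra()` builds each spectrum from four components: a
piecewise-smooth vegetation template (low visible reflectance with a
green peak near 550 nm, a logistic red edge centred near 715 nm, a
near-infrared plateau with a mild water dip near 970 nm); a deterministic
visible-range chlorophyll response to applied nitrogen; a class- and
level-dependent shift inside the designated signature windows (400–540,
600–660 and 850–900 nm by default); and Gaussian-smoothed noise (kernel
width 30 nm) that reproduces the high adjacent-band collinearity
motivating the band selectors. Reflectance is clipped to [0, 1]. The
class response is: low-N-efficient varieties express their signature
fully under nitrogen deficit and at half strength at normal nitrogen;
high-N-efficient varieties mirror this under excess; inefficient
varieties carry no signature.

Each variety expresses each signature window with its own multiplicative
strength (`signature_expression_sd = 0.5`). This heterogeneity is what
makes the three windows jointly informative: if every window carried an
identical copy of the class signal, the windows would be perfectly
collinear and any selector built to prune redundancy would correctly keep
only one of them — no real canopy behaves that way, because different
spectral regions track different biochemistry (pigments in the visible,
structure and water in the near infrared) with variety-specific
expression.

`generate_phenotypes()` draws the four raw phenotypes per variety × level
× replicate as variety base values times a class-dependent nitrogen
response (low-N-efficient: ×1.04 under deficit; high-N-efficient: ×1.15
under excess; inefficient: ×0.85 and ×0.88 under the two stresses) with
multiplicative noise (CV 0.03). Defaults were fixed once at values giving
index variation comparable in order of magnitude to real trial summaries.

The generator does **not** attempt radiative-transfer realism (no
PROSAIL-style leaf/canopy physics, soil background, illumination
geometry, or atmospheric residuals), sensor artefacts, or spatial
correlation between neighbouring plots. Passing tests on this fixture
therefore demonstrate that the pipeline's logic is correct and that its
statistical machinery recovers planted structure at realistic
signal-to-noise — not that any particular field campaign's accuracies
would be reproduced; real UAV data at field scale carry structure the
generator deliberately omits.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; no function mutates the
  session RNG state. Derived child seeds stay below 2³¹.
* Standardisation maps constant columns to zeros instead of NaN.
* glmnet runs at a tight tolerance (1e-10) so band selection is invariant
  to band column order; remaining ties break by ascending wavelength.
* Kappa returns `NA` with a warning when expected agreement equals N²;
  CV is flagged undefined at zero mean; `change_rate`/`nt`/`nfue` reject
  non-positive controls.
* The raster sampling convention: 0-based pixel coordinates at pixel
  centres; an even window of side w anchors so the rounded point sits at
  the lower-left of the central 2×2 block; the one-fifth offset is
  measured from the vertex toward the centre (`offset_from = "center"`
  gives the alternative reading). Extraction is translation-equivariant,
  and block means of a linear synthetic field match the closed form to
  1e-9.
* Plots with anything other than 4 vertices, degenerate polygons, or
  windows crossing the raster edge are rejected with descriptive errors.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full method at the
trial's own scale — 120 canopy-region samples × 224 bands per stress
condition — for the selection and classification stages; replicated
checks (labelling recovery, window recovery, null-accuracy) use 10–20
seeded repetitions, and the null-accuracy check uses a reduced 48 × 30
fixture per seed, sizes at which the measured properties are already
stable. Oracle comparisons (brute-force clustering, OLS-vs-PLS,
closed-form block means, 1000 random confusion matrices) are exact.

## Known limitations

* With ~13 points, t-SNE embeddings vary with the seed; the dual-path
  design (embedding by default, direct clustering as the deterministic
  fall-back) is a mitigation, not a cure.
* The Lasso target treats a class code as a continuous response; this is
  faithful to the method but means selection optimises squared error, not
  classification loss.
* CARS's minimum-RMSECV rule can return very small subsets when many
  bands are individually sufficient; the trace is retained so users can
  prefer a larger set at near-minimal RMSECV.
* The fusion's advantage over its baselines appears on genuinely
  nonlinear class boundaries; on cleanly separable data all models tie
  and the comparison is uninformative.
* GeoTIFF geo-referencing tags are not interpreted; plot geometries must
  be supplied in pixel coordinates.
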