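---
title: "Predicting longitudinal cognitive decline from baseline hippocampal surface morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting longitudinal cognitive decline from baseline hippocampal surface morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfsgl)
```

## The problem

In progressive dementias such as Alzheimer's disease, a clinically central
question is how a patient's cognition will evolve over the years following a
baseline assessment. This package models the trajectory of the ADAS-Cog
score at five follow-up visits (months 6, 12, 24, 36 and 48 after baseline)
as five *related* regression tasks sharing one weight matrix, fitted jointly
from baseline data only: demographics (sex, age), ApoE-e4 allele copy count,
baseline MMSE, regional MRI features (305 cortical thickness, volume and
surface-area summaries), and — the distinctive ingredient — seven per-vertex
morphometry maps of the hippocampal surface, one of the structures whose
atrophy tracks disease progression most closely.

Two facts shape the estimator. First, later visits have progressively fewer
observations (monotone dropout: in the motivating ADNI-1 cohort of 616
subjects, 606 / 606 / 533 / 364 / 97 scores are available at the five
visits), so the loss must be computed over observed entries only. Second,
with 2409 features and a few hundred subjects, the fit must be sparse, and
the weights a feature receives at adjacent visits should be similar, because
the biology that drives a score at month 24 does not switch off at month 36.

## The estimator

With $X \in \mathbb{R}^{n \times d}$ the baseline design, $Y \in
\mathbb{R}^{n \times t}$ the score panel ($t = 5$), $M$ the observation
mask, and $W \in \mathbb{R}^{d \times t}$ the shared weight matrix, the
convex fused sparse group lasso (cFSGL) estimate minimizes

$$
\| M \odot (XW - Y) \|_F^2
 + \lambda_1 \|W\|_1
 + \lambda_2 \|R W^\top\|_1
 + \lambda_3 \|W\|_{2,1},
$$

where $R$ is the $(t-1) \times t$ first-difference operator
([difference_operator()]), $\|W\|_{2,1} = \sum_i \|w_i\|_2$ sums the row
norms, and $\odot$ is the elementwise product. The three penalties encode,
respectively, elementwise sparsity, temporal smoothness of each feature's
weight profile, and selection of whole features across all visits.

Some published renderings of this objective drop typographical detail (the
square root in the $\ell_{2,1}$ norm, the $-1$ entries of the difference
operator); we use the standard definitions, which are the only ones under
which "group lasso" selects rows and "fused lasso" rewards temporal
smoothness.

### Solver

The objective is convex but nonsmooth. We use a monotone accelerated
proximal-gradient method (FISTA with backtracking line search) on the masked
squared loss, whose gradient is $2 X^\top (M \odot (XW - Y))$. The composite
penalty's proximal operator decomposes row-by-row: for each feature row,
first the exact 1-D fused-lasso signal approximator — a direct taut-string
total-variation solver followed by soft-thresholding, which is the exact
joint minimizer for the TV + $\ell_1$ composition — then group (row-norm)
shrinkage. This sequential decomposition is exact for this penalty nesting;
rather than assuming that, the test suite verifies both the proximal
operator and full fits against an independent convex-programming oracle
(smoothed objective minimized by quasi-Newton descent with
$\varepsilon$-continuation) on randomized instances, to $10^{-4}$ in
objective value.

Monotonicity is enforced: when the accelerated step fails to decrease the
objective (momentum overshoot), the solver takes a plain descent step from
the current iterate and restarts momentum, so the reported objective trace
is non-increasing and the relative-change stopping rule ($10^{-6}$ by
default) is meaningful. The solver itself is deterministic: $W$ starts at
zero and the initial step derives from a power-iteration estimate of
$\|X\|_2^2$.

Two conventions are configuration-exposed because the literature varies:
the loss is *summed* over observed entries by default (`loss_scale =
"sum"`; `"mean"` divides by the observed count), and tuning is by $k$-fold
cross-validation on training subjects minimizing validation nMSE, with ties
broken toward the first grid point.

### Intercept and normalization

Features are z-scored per column with *training-set* statistics (population
standard deviation; constant columns map to zero) and each task's scores are
centered on their observed training mean; held-out subjects are transformed
with the training statistics, so no information leaks. Because the
observation mask differs across tasks, mean-centering alone cannot remove
the per-task constant exactly; [cfsgl_train()] therefore augments the design
with one unpenalized intercept column. Exempting a row from the penalties
preserves the exactness of the proximal operator (every penalty term is
row-separable).

## Surface morphometry

The hippocampal surface is represented as a $50 \times 60$ parameter grid of
3-D vertices ([parametric_surface()]): rows are circumferential rings along
the ~40 mm long axis. Vertex correspondence between the template and each
subject is an input contract — the conformal parameterization and fluid
registration that establish it in a full imaging pipeline are upstream of
this package. Each grid cell is split into two triangles along its
$(i,j) \to (i+1,j+1)$ diagonal; the fixed edge ordering gives every triangle
a deterministic local orthonormal frame (first edge direction, in-plane
perpendicular), shared by construction between template and subject.

For each triangle pair the in-surface $2 \times 2$ Jacobian $J$ maps
template edge coordinates to subject edge coordinates; in these frames $J$
is upper triangular with positive diagonal. From $J$:

* **mTBM components** $(L_{11}, \sqrt{2} L_{12}, L_{22})$ of $L = \log S$,
  $S = (J^\top J)^{1/2}$ the deformation tensor. The $\sqrt 2$ weight makes
  the Euclidean norm of the 3-vector equal $\|L\|_F$, so ordinary statistics
  on the components are log-Euclidean statistics on tensors.
* **Jacobian determinant** $\det S$ — the local area ratio (univariate TBM).
* **Principal stretches** — eigenvalues of $S$ (singular values of $J$),
  descending. The source literature says "Jacobian principal eigenvalues"
  without fixing whether $J$ or $S$ is meant; we use the singular values,
  which are real, positive, and rigid-motion invariant, and note the
  ambiguity here.

Per-triangle log tensors are aggregated to vertices by an area-weighted mean
*in log space* (the log-Euclidean mean, weights = template triangle areas),
which keeps the aggregate positive-definite; determinant and stretches are
recomputed from the aggregated tensor. The seventh map is the **mid-axis
(radial) distance**: each vertex's distance to the centroid of its
iso-parametric ring. The medial-axis construction used in the upstream
surface pipelines is not reproducible from the available description; the
per-ring centroid is the simplest deterministic surrogate consistent with a
radial-distance interpretation, and is documented as such rather than as a
claim about those pipelines.

All seven maps are exactly invariant under rigid motion of either surface,
the identity deformation maps to (mTBM $= 0$, $\det = 1$, stretches $= 1$),
and uniform scaling by $a$ gives (mTBM $= (\log a, 0, \log a)$, $\det =
a^2$, stretches $= (a, a)$) — these closed forms are asserted in the tests.

### Downsampling and assembly

Full-resolution maps are downsampled by bicubic interpolation — separable
cubic-spline interpolation, rows then columns, exact on constants and
bilinear ramps — from $50 \times 60$ to $15 \times 20$, giving $7 \times
300 = 2100$ hippocampal columns. The full grid size is chosen so that
downsampling by a factor of 10 yields exactly 300 points per map. Column
order is fixed and documented: 300 mid-axis, 900 mTBM (vertex-major), 300
determinant, 600 stretches (vertex-major), after the 309 "original" columns
(sex, age, ApoE, baseline MMSE, 305 MRI). The mTBM vertex-major layout is
arbitrary but fixed; predictions are invariant to column order. Where the
source material reports ~350, 305, 309 or 326 baseline features in
different places, the itemized inventory totalling 309 is taken as
authoritative.

## Evaluation protocol

[run_experiment()] repeats a 90/10 holdout 20 times: per split, normalize on
training subjects, select $(\lambda_1, \lambda_2, \lambda_3)$ by $k$-fold CV
on training subjects, fit, predict the held-out subjects, and score:

* `rMSE` per visit: $\sqrt{\sum_{\text{obs}} (y - \hat y)^2 / n_j}$ — in
  score units. The name implies the square root even where rendered
  formulas omit it.
* `nMSE`: $\bigl(\sum_j \|y_j - \hat y_j\|^2 / \mathrm{Var}(y_j)\bigr) /
  \sum_j n_j$ over observed entries.
* `wR`: observation-count-weighted mean of per-visit correlations.

The nMSE and wR definitions follow the multi-task learning framework this
estimator comes from (they are not spelled out in the clinical report and
are flagged here as reconstructed). Splits are stratified by each subject's
last observed visit so every test set contains month-48 subjects — without
stratification a 10% test draw can easily miss all 97 of them. The
with/without-hippocampal comparison shares the split plan and CV seeds
between arms, so it is paired.

## The synthetic cohort

Real ADNI data are access-restricted, so [generate_cohort()] emulates the
study conditions end to end and is itself first-class, tested code. Defaults
are the study conditions: 616 subjects, dropout counts 606/606/533/364/97
(scaled proportionally for other cohort sizes), a $50 \times 60$ grid
downsampled to $15 \times 20$, 305 MRI-like columns.

* **Severity** per subject is uniform on $[0, 1]$.
* **Surfaces**: a deterministic tube-like template at hippocampus scale;
  subjects are deformed by radial contraction inside three fixed Gaussian
  patches with per-subject amplitudes
  $\text{severity} \cdot \max(0, 1 + 0.3 z_b)$, plus 0.02 mm vertex jitter.
  The heterogeneity term makes the hippocampal block carry information
  beyond a single severity axis, as real atrophy patterns do; atrophy is
  monotone in severity by construction.
* **Baseline block**: sex Bernoulli(0.5); age $N(75, 6^2)$; ApoE copies with
  probabilities (0.55, 0.35, 0.10); baseline MMSE $= 27 - 4\,\text{severity}
  + N(0,1)$ clamped to $[10, 30]$; MRI-like columns from a rank-5 latent
  factor model plus noise, with 10% of columns loading on severity.
* **Targets**: $Y = Z W^* + \varepsilon$, with $Z$ the population-
  standardized design and $W^*$ row-sparse (5% of rows by default), row
  magnitudes uniform on $[0.5, 1]$ with random sign, successive differences
  bounded by 25% of the row level (temporal smoothness by construction), and
  60% of signal rows placed in spatially clustered hippocampal patches.
  Noise is $N(0, 4^2)$ by default — chosen so the full-scale cohort lands in
  the performance regime the motivating study reports (per-visit rMSE about
  4–5 score units, wR about 0.85). Generating from the standardized design
  makes the noiseless cohort exactly realizable by the fitted model class
  (affine in the raw features), which the tests exploit.
* **Dropout**: visits 2–5 observe nested random subject sets matching the
  configured counts exactly (monotone attrition); the subjects unobserved
  from month 12 onward are observed at month 6, so everyone is observed at
  least once. Dropout is missing-at-random given the visit — the real
  attrition mechanism is unknown.

All randomness flows from one root seed through per-stage and per-subject
streams, so cohorts are bit-reproducible.

What passing tests on this cohort do *not* show: performance on real ADNI
data. The generator's linear truth matches the estimator's model class
(favoring it), its feature correlations are simpler than FreeSurfer's, and
its dropout is ignorable. Synthetic results support correctness of the
machinery and the *direction* of the with/without-hippocampal comparison,
not the published absolute metric values.

## Problem sizes and numerical choices

The packaged experiments use: the full scale ($n = 616$, $d = 2409$) for
the noiseless interpolation check; $n = 300$, $d = 500$ for support
recovery (F1 with a relative row-norm threshold of 0.1, penalties tuned by
an oracle over a small grid); and a reduced cohort ($n = 200$, $20 \times
24$ grid downsampled to $5 \times 6$, $d = 274$, sparsity 0.10, noise sd 3)
for the 20-split paired comparison, where the raised sparsity fraction and
reduced noise keep the absolute signal comparable to the full-scale regime
at the smaller dimension. Solver tolerances: $10^{-6}$ relative objective
change for final fits (tightened to $10^{-12}$ where tests assert
interpolation), $10^{-5}$ with an iteration cap of a few hundred inside CV.
Degenerate cases are defined errors: triangles with zero area (reported with
their index), subjects observed at no visit, non-finite designs; zero-
variance metric tasks are excluded with a warning. Ties in CV break to the
first grid point; constant columns z-score to zero.

## Known limitations

* Correspondence-establishing registration, segmentation and surface
  extraction are out of scope; garbage correspondence gives garbage maps.
* The mid-axis map is a surrogate for a true medial-axis construction.
* CV tuning inside each split uses the split's training normalization (the
  fold models share it), a common and slightly optimistic shortcut.
* No screening rules or warm-start paths: fits at this scale take seconds,
  so none are needed.
* Stability selection and interpretation of the fitted weight maps are
  deliberately not implemented.
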