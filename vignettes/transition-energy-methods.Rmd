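---
title: "Brain-state transition energies: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state transition energies: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stateTE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, the numerical choices, and the known limitations. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The model

### Brain states by correlation-distance k-means

Regional BOLD frames are treated as points in R^N (N = 86 regions by
default) and clustered with distance d(a, b) = 1 − r(a, b), the Pearson
correlation distance. This metric cares about the *pattern* of regional
activation, not its overall amplitude, which is the right invariance for
demeaned BOLD data: a frame and a scaled copy of it express the same
brain state.

`run_kmeans()` realizes this metric exactly by row-standardizing every
frame to mean 0 and unit norm and running Lloyd iterations in the
standardized space, re-standardizing centroids after every mean update.
For unit-norm, mean-zero rows, 1 − r(a, b) = ‖a − b‖²/2, so nearest-dot-
product assignment is exactly nearest-correlation-distance assignment
while the centroid update stays a closed-form mean. "Best separation of
data" across the 10 random restarts is the minimum total within-cluster
correlation distance — the one scalar objective k-means optimizes. Empty
clusters are repaired deterministically by reseeding from the frame
farthest from its assigned centroid.

Stability is assessed the way large consortium analyses do it: the whole
best-of-10 procedure is repeated 10 times independently and the partition
with the greatest total adjusted mutual information (AMI) against all
others is kept (`select_stable_partition()`). AMI is implemented
in-package (no pre-installed R package provides it) with the
hypergeometric expected-MI correction and arithmetic-mean normalization;
it was verified against `sklearn.metrics.adjusted_mutual_info_score` and
those oracle values are frozen in the tests.

### Choosing k

`choose_k()` automates the explained-variance elbow: explained variance
EV(k) = 1 − SS_within/SS_total is computed in the standardized space
(cluster means vs the grand mean) for k = 2…14, and the selected k* is
the *last* k before the incremental gain EV(k) − EV(k−1) drops below the
1% threshold. With four well-separated planted states the gains at
k = 3, 4 are large and the k = 5 gain is the first below 1%, so k* = 4 —
the reading of "elbow" under which the gain criterion and the elbow
coincide. (The alternative reading — return the first k whose own gain is
sub-threshold — would systematically overshoot the planted k by one; the
package pins the former and the tests assert planted-k recovery.) If no
gain falls below the threshold the maximum of the range is returned with
a warning.

### State naming

Each centroid c is compared by cosine similarity against the nine binary
network indicator vectors, for both c and −c; the best of the 18
candidates names the state (`DMN+`, `VIS−`, …). Because the series are
demeaned, positive centroid values mean activation above the regional
mean, so the anticorrelated pair `DMN+`/`DMN−` is a meta-state: the same
system above and below its mean. Exact ties break to the
lexicographically first network name, with a warning.

### Transition energies

The structural connectome A (symmetric, nonnegative, zero diagonal) is
stabilized as A_norm = A/(λ_max(A) + 1) − I, which places all eigenvalues
in (−2, 0): the uncontrolled system decays to the origin, i.e. to the
mean BOLD pattern. Dynamics are the linear time-invariant model
ẋ = A_norm x + B u with B = I (uniform control: input allowed at every
region).

For horizon T, the finite-horizon controllability Gramian
W(T) = ∫₀ᵀ e^{At} B Bᵀ e^{Aᵀt} dt is computed by the Van Loan
block-matrix-exponential construction (one 2N × 2N `Matrix::expm`), with
a composite-Simpson quadrature route kept as an independent cross-check
(`method = "quadrature"`); the tests additionally compare both against a
discrete-time least-norm oracle. The minimum-energy input is
u*(t) = Bᵀ e^{Aᵀ(T−t)} W⁻¹ δ with δ = x_T − e^{AT} x₀, and the package
defines **regional TE** as ∫₀ᵀ u*_i(t)² dt. The squared integrand is a
deliberate design choice: a signed integral of u would cancel and is not
an energy; the quadratic form is the standard minimum-energy cost whose
total equals δᵀ W⁻¹ δ in closed form. An absolute-value cost
(∫|u_i| dt) is available behind `cost = "abs"` for sensitivity analyses.

Per subject, all k² ordered state pairs are computed, including the
diagonal persistence energies (states are not equilibria of the decaying
dynamics, so staying put costs energy). The TE matrix is generically
asymmetric — the cost of s → t is not the cost of t → s — and the tests
assert that asymmetry rather than accidentally "fixing" it.

### The horizon T

The default T = 1.501 is the canonical value for this analysis family:
the horizon at which pairwise TE is most strongly *anti*-correlated
(Spearman) with the empirical transition probability — transitions the
brain makes often should be the energetically cheap ones.
`select_time_horizon()` re-derives it on any dataset by sweeping a grid
(default 50 log-spaced points on [0.001, 10]) and picking the most
negative correlation. Transition probabilities are pooled consecutive-
frame label counts across subjects, row-normalized, persistence pairs
included (pooling matches the group-level centroid TE; a never-visited
state falls back to a uniform row with a warning).

### Aggregation and outliers

Network TE sums raw regional TEs over each network's regions (no
size/volume weighting); global TE sums over all regions; each mean TE
averages all k² pairwise entries including the diagonal. Sums are exact
linear contractions of the same tensor, so region → network → global
conservation is tested to 1e−9 relative. Subjects whose mean global TE
lies outside [Q1 − 1.5·IQR, Q3 + 1.5·IQR] are excluded before
statistics; quartiles use linear interpolation between order statistics
(R `quantile` type 7), pinned so the rule is bit-reproducible.

### Group statistics

One two-way ANCOVA per TE outcome: sex and FH group (FH+ vs FH− only;
FH+/− subjects — exactly one affected grandparent — carry minimal and
ambiguous genetic load and enter only the continuous FHD analyses) with
the sex × FH interaction as the effect of interest, covariates (age,
race/ethnicity, household income, parental education, parental mental
health, prenatal exposure, scanner model, mean framewise displacement,
pubertal stage) and two further interactions (sex × puberty,
FH × income). Design choices pinned here because no single convention is
universal:

* **Type III sums of squares with sum-to-zero contrasts**, implemented by
  partial-RSS comparisons on the full design matrix; with interactions of
  primary interest and unbalanced groups, Type III is the convention that
  tests each term adjusted for all others. Verified against
  `drop1(..., test = "F")` on unbalanced fixtures.
* **Ordinal covariates (income, education, puberty) enter as numeric
  scores**; their handling is not otherwise determined and linear scores
  are the parsimonious default at 3–5 levels.
* **Pooled-variance t-tests** for the post-hoc FH+ vs FH− contrasts
  within each sex (Welch behind a flag), Cohen's d with pooled SD, sign
  convention first-minus-second (positive = FH+ > FH−).
* **BH-FDR within families**: the global mean is its own family, the 9
  network means one family, the 86 regional means another, pairwise
  entries per level their own — mirroring how the outcomes naturally
  group; configurable.
* **Listwise deletion** with a logged count for missing covariates.

Partial η² = SS_effect/(SS_effect + SS_error) for every term. The
degenerate constant-outcome case returns F = 0 for all terms with a
warning rather than NaN.

## 2. The synthetic cohort: a stated world

The generator emulates the *statistical structure* the analysis assumes,
not the biophysics:

* **Connectome**: weighted stochastic block model — edges kept with
  probability `density`, log-normal weights (sdlog 0.5) doubled within
  modules, connectivity enforced with bounded seeded retries. This
  reproduces the heavy-tailed, community-structured weights of
  streamline-count connectomes without tractography.
* **States**: k = 4 planted centroids in two anticorrelated pairs
  (±amplitude on the DMN regions, ±amplitude on the VIS regions, small
  Gaussian background elsewhere), mimicking the meta-state geometry the
  clustering is expected to find.
* **Series**: a Markov chain over states (default self-transition 0.85,
  remainder uniform — a convention, since within-subject dwell-time
  statistics are not published for this design) emits the subject's
  perturbed centroid plus i.i.d. Gaussian noise (default sd = 0.5 ×
  amplitude), then demeans per region. Subject heterogeneity is an
  additive Gaussian perturbation of the planted centroids (sd 0.1), the
  simplest mechanism that makes individual centroids differ from group
  centroids, which the TE stage requires.
* **Pedigrees and covariates**: FH groups drawn at 23.1% FH+ / 62.3%
  FH− / 14.6% FH+/− (the realistic class imbalance of a large
  developmental cohort), FH classification (≥1 parent or ≥2 grandparents
  affected → FH+; exactly one grandparent → FH+/−; none → FH−) and FHD
  (+1/parent, +0.5/grandparent) computed from the drawn pedigree;
  demographics from documented default distributions (53% female, age
  ≈ 120 ± 7.5 months, sex-dependent puberty, three scanner models,
  log-normal motion).
* **Group effects** scale named networks' centroid entries per
  (sex, FH group) cell *before* series generation, so a unit effect is an
  exact null: series are generated identically in law regardless of the
  covariate draw.

What it does **not** emulate: hemodynamics (no balloon model),
autocorrelated scanner noise, head motion and censoring, site effects
beyond a categorical scanner covariate, genetic correlation between FHD
and covariates. A green test on this world therefore establishes that the
*pipeline* is correct and calibrated — not that any particular biological
effect exists, nor that the method is robust to preprocessing artifacts.

## 3. Numerical choices

* Gramian: Van Loan default; condition number recorded and capped at
  1e12 (error advises a longer horizon — W(T) loses rank as T → 0).
  Solves against W use a Cholesky factorization, never an explicit
  inverse.
* Trajectory discretization: n_steps = 1000 trapezoid intervals;
  exponential-trapezoid state stepping (x_{i+1} = e^{A·dt} x_i +
  dt/2 · (e^{A·dt} B u_i + B u_{i+1})) with endpoint tolerance 1e−4
  relative; totals cross-checked against δᵀW⁻¹δ. At n_steps = 1000 the
  trapezoid total agrees with the closed form to ~1e−6 relative; tests
  that lower n_steps for speed keep ≥ 250 so the endpoint check still
  clears its tolerance.
* Seeds: every stochastic stage derives its own sub-seed from the single
  master seed via a deterministic hash (`derive_seed()`), and all RNG
  use is wrapped so global random state is never touched. Nested
  replicate sets share seeds, making "more replicates never worsens the
  objective" a testable monotonicity.
* Ties: frame assignment and stability selection break ties to the
  lowest index; state naming to the lexicographically first network.
* Degenerate inputs: zero-variance frames are unassignable (NA label,
  excluded from centroid averaging, warned); states a subject never
  visits are imputed from group centroids and recorded in
  `imputed_states`, preserving the k × k TE structure for every subject;
  IQR fences collapse to the common value when IQR = 0.

## 4. Known limitations

* **Statistical power at small planted effects.** The acceptance test
  for the ANCOVA encodes a power target of >80% (and ≥95% joint post-hoc
  direction recovery) for a ±0.3 pooled-SD sex-by-FH crossover at
  n = 400. Under the generator's realistic class imbalance the expected
  cell sizes are ≈ 49/132/43/117, giving an interaction standard error of
  0.245 SD, noncentrality 2.45, and an *analytic* power ceiling of 0.687
  (joint direction probability 0.92) — which the measured rates match.
  Those two assertions are therefore expected to fail: the suite keeps
  the strict thresholds and documents the gap rather than rebalancing
  the generator toward a pass. Null calibration (rejection rate 0.05 ±
  0.02 over 500 seeds) and 0.5-SD direction recovery (≥95%) pass.
* The correlation-distance k-means weights all frames equally when
  subjects have unequal frame counts; no per-subject reweighting is
  applied.
* One connectome per run: cohort-level analyses use a single shared
  (group-average-like) matrix; per-subject connectomes would require
  only looping the system construction but are not exposed.
* TE tensors are exchanged as tidy long TSVs rather than a binary
  container, trading size for inspectability and zero binary
  dependencies.
* The horizon sweep computes group-centroid TE only (closed form), not
  per-subject TE, when ranking horizons; this matches pooled transition
  probabilities but means T* is a group-level choice.
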