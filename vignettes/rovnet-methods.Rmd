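---
title: "Variance mapping, distance-correlation networks and connectome-based prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance mapping, distance-correlation networks and connectome-based prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rovnet)
```

# The scientific problem

Group-level task fMRI analysis deliberately averages away individual
differences. This package implements the complementary analysis: mapping
*where* in a task network subjects differ most from one another, selecting
those loci as regions of variance (ROVs), and asking whether the functional
coupling among them carries information about individual behavioral ability.
The pipeline has five stages, each a module with a small, testable surface:

1. **Variance mapping** — voxelwise between- to within-subject variance
   ratio of a task contrast, and the across-subject SD of grey-matter volume.
2. **ROV extraction** — data-driven thresholding of the variance maps at the
   change point of their sorted values, cluster extraction, and 10-mm spheres
   around cluster peaks.
3. **Connectivity** — per-subject networks over the ROVs from multivariate
   distance correlation on multi-voxel series (task beta-series or resting
   BOLD), after a configurable cleaning chain.
4. **Prediction (CPM)** — connectome-based predictive modeling of behavior
   scores with leave-one-out cross-validation and permutation inference.
5. **Marker correlation** — classical ROV-mean marker versus score
   correlations with outlier handling, covariate control and Bonferroni
   correction.

A seeded synthetic-cohort generator provides ground truth for all of it.

# Models and estimators

## Activity variance maps

For a cohort of subject contrast images `con_i` with residual mean-square
images `ResMS_i` from first-level models with `NScan` scans, the voxelwise
statistics are

$$S_B^2 = \frac{\frac{1}{N-1}\sum_i \left(\mathrm{con}_i - \overline{\mathrm{con}}\right)^2}{2}\, \mathrm{NScan},
\qquad
S_W^2 = \frac{\frac{1}{N}\sum_i \mathrm{ResMS}_i}{\mathrm{NScan}-1},
\qquad
F = S_B^2 / S_W^2 .$$

The `/2 x NScan` rescaling of the between-subject sample variance is
implemented exactly as written; it carries no inferential content (it is a
monotone rescaling shared by all voxels, so thresholding and ranking are
unaffected), and `between_subject_variance(..., scale_by_scans = FALSE)`
drops it for sensitivity analyses. Voxels with `S_W^2 = 0` get an NA
sentinel, never `+Inf`, and are excluded from thresholding. The grey-matter
map uses the across-subject sample SD (denominator `N - 1`, the unbiased
convention; the same convention is used everywhere a SD is taken across
subjects).

The group mask comes from a voxelwise one-sample t test of the contrast
against zero (one-sided, activation tail — the contrast of interest is an
activation contrast), with Bonferroni family-wise error control over the
in-analysis voxels. Bonferroni is deterministic, assumption-light and
conservative; it deliberately diverges from random-field-theory FWE, which
would require smoothness estimation that the package does not model.
Survivors are grouped by 26-connectivity (the SPM cluster convention) and
components below `min_cluster_size` (default 10 voxels) are dropped.

## Change-point thresholding

Variance maps are thresholded at the change point of their sorted values:
the split index `k` minimizing the summed squared error of the two segments
about their means, found by exhaustive search over all `n - 1` splits in
O(n) via prefix sums. The threshold is the first value of the upper segment,
and survival is `value >= threshold`, so the detected high segment itself
survives. Ties take the smallest split index; an all-constant input has no
change point and returns a `+Inf` threshold (nothing survives, and the
pipeline reports no ROVs). This single-split, piecewise-constant-mean, SSE
formulation is the most deterministic reading of generic change-point
detection; no penalty term is needed because exactly one split is fitted.

The change point is fitted on the unmasked in-brain values, then both the
threshold and the group mask are applied. Fitting after masking instead is
available by composing the operations in the other order.

## ROVs

ROVs are spheres of 10 mm radius around cluster peak coordinates; members
are all voxels whose centre lies within the radius (Euclidean, mm). Peak
ties are broken by lowest linear voxel index for determinism. The 13
published peaks (6 functional, 7 structural) ship as a packaged coordinate
table (`published_rovs()`) with a standard 3-mm MNI-like grid geometry
(`mni_geometry()`), so networks can be built on the published geometry
without rerunning extraction. The left angular gyrus appears once per kind
at nearby but distinct peaks; both are kept as separate nodes (13 in total),
disambiguated by a `node` id.

## Series cleaning

Resting series are cleaned in the order: confound regression (24 motion
columns + CSF + WM + global signal, always with an intercept), zero-phase
Butterworth bandpass (order 2 run forwards and backwards, 0.009–0.08 Hz for
rest; the DC component is removed exactly before filtering), truncation to
the first 316 volumes, and per-voxel z-normalization (sample SD). Task
beta-series receive z-normalization only — their nuisance structure is
removed upstream of beta estimation — though every step is switchable.
Rank-deficient confound designs drop the offending columns with a warning
naming them. One honest caveat, also surfaced by the tests: filtering after
regression does not preserve exact orthogonality to the unfiltered
confounds; the injected leakage is strongly reduced, not annihilated. The
filter family and order are recorded on the cleaned object.

## Distance-correlation networks

Dependence between two ROVs is measured on whole multi-voxel patterns: the
T observations (trials or time points) of each ROV give a T x T Euclidean
distance matrix, which is U-centered,

$$\tilde A_{ij} = A_{ij} - \frac{A_{i\cdot}}{T-2} - \frac{A_{\cdot j}}{T-2}
  + \frac{A_{\cdot\cdot}}{(T-1)(T-2)} \quad (i \ne j), \qquad \tilde A_{ii} = 0,$$

and combined into the unbiased distance covariance
$\mathrm{dCov}^2 = \sum_{ij}\tilde A_{ij}\tilde B_{ij} / (T(T-3))$ and the
corresponding distance variances. The unbiased $\mathrm{dCov}^2$ may be
negative; it is clipped at zero before the square root, and a nonpositive
distance variance (a constant pattern) yields a correlation of 0 by
convention. U-centering requires at least 4 observations. Each subject's
network is the symmetric K x K matrix over all K(K-1)/2 unordered ROV pairs
with a zero diagonal; self-edges are never used. Edge-level individual
variability is the across-subject SD per edge, compared between task and
rest with a paired t test across the 78 edges (df = 77 for K = 13).

## Connectome-based predictive modeling

Per leave-one-out fold, every edge is Pearson-correlated with the training
scores; edges with two-sided p <= 0.05 are split by the sign of r into a
positive and a negative mask (two-sided because the sign split already
handles direction). Each model sums the masked edges once per unordered
pair, fits an ordinary least-squares line score ~ sum, and predicts the
held-out subject from its own masked sum. Folds whose mask is empty (or
whose sums are constant) predict the training mean; a model fails outright
only when every fold lacked edges of its sign — mirroring how a
whole-network analysis can report "no behavior-related edges". Model
validity is the Pearson correlation between observed and predicted scores.

The permutation test permutes scores across subjects and re-runs the *full*
pipeline, including per-fold edge selection, for each permutation — the
conservative standard — and uses the add-one estimator
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$ on each model's own
prediction r (significance is assessed on the magnitude of prediction
performance for both models). Permutations in which a model fails
contribute $r_{perm} = -\infty$. The permutation RNG seed is an explicit
argument and is recorded in the result.

Internally the LOOCV engine computes every fold's edge-score correlations by
leave-one-out updates of full-sample sufficient statistics (edge columns are
pre-centred; correlations are shift-invariant, so this changes nothing but
conditioning), and converts the p <= alpha rule to the equivalent
$|r| \ge r_{crit}$ threshold with $r_{crit} = t_c/\sqrt{df + t_c^2}$. A
dedicated test pins the engine's per-fold masks and coefficients to the
plain per-fold `select_edges()`/`fit_models()` operations, and a leakage
test verifies that perturbing a held-out subject's score leaves that fold's
masks and coefficients bit-identical.

The contributing network is the set of edges present in the positive mask of
*every* fold (intersection; a union mode exists), ranked by mean training
correlation.

## Marker correlations

Functional markers are ROV-mean contrast betas; structural markers are
ROV-mean grey-matter volumes. Scores are first checked for normality
(Shapiro–Wilk statistic, reported not enforced) and values more than 3
sample SDs from the mean are replaced by the mean of the remaining values
(the threshold is configurable; runs with more than 20% outliers abort).
Markers are Pearson-correlated with scores — first-order partial correlation
when a brain-size covariate is supplied (structural markers only, following
the convention that anatomical measures scale with head size; functional
markers are left unadjusted) — and p values are Bonferroni-corrected with
family size = markers x scores within each marker kind by default.

# The synthetic cohort

The generator emulates the statistical structure the analyses assume, not
the physics of acquisition: no hemodynamic forward model, no k-space
simulation, no realistic anatomy. Its defaults are the study conditions:

* **Cohort and grid.** 97 subjects; 24^3 voxels at 3 mm (a desk-scale grid
  that still admits 10-mm spheres); NScan = 316; 8 task trials; 316 resting
  volumes at TR = 0.72 s.
* **Contrast maps.** `con_i = mu + N(0, sigma_B(v)^2)` with `mu = 1`,
  baseline `sigma_B = 0.5`, and Gaussian radial bumps (scale = radius/2,
  peak multiplier 4) centred on three designated functional high-variance
  spheres — a radial profile so each sphere has a well-defined peak for
  recovery checks. `ResMS_i = sigma_W^2 chi^2_{NScan-1}/(NScan-1)` with
  `sigma_W = 1`, matching a residual mean-square's sampling distribution, so
  the within-subject averaging in the F map is genuinely exercised.
* **GM maps.** Template 0.5, baseline SD 0.02, multiplier 3 on three
  structural spheres, clipped at 0.
* **ROV series.** A latent-factor model: each ROV has one latent series;
  the K latents are drawn jointly with the subject's coupling matrix as
  their correlation (eigenvalue-clipped to positive definite); each of the
  20 voxels is loading x latent + white noise (loadings U(0.8, 1.2), noise
  SD 0.5). Subject coupling = population target (0.35) + edge noise with SD
  0.03 in task and 0.15 at rest, emulating the empirical finding that
  resting coupling varies far more across individuals than task coupling.
  Resting series receive configured leakage from the global and motion
  confounds so the cleaning stage has structure to remove.
* **Confounds.** 6 motion random walks, their lags and the 12 squares, plus
  CSF/WM/global as low-frequency Gaussian processes.
* **Behavior.** One score coupled to three designated rest-coupling edges
  (`score = 115 + 20 x edge sum + noise`, noise SD set to the signal SD,
  i.e. unit signal-to-noise), one uncoupled score (SD 10), and a brain-size
  covariate (total GM volume). The NIH-toolbox-like scale (mean 115, SD ~10)
  matches the magnitude of standardized language scores.
* **Seeding.** All randomness flows from one seed through per-subject
  sub-streams, so cohorts are byte-identical under a fixed seed and the
  first n subjects are stable when the cohort grows.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: spatial autocorrelation and anatomy of the maps,
hemodynamic spectra (latent series are white; see below), distributional
quirks of real behavioral scores, and site/session structure.

## Two deliberate spectral choices

The resting latents are white noise. Real resting BOLD concentrates power
below ~0.1 Hz, which is why the 0.009–0.08 Hz band retains real
connectivity but discards most of a white latent's variance. We examined
low-frequency latents (moving-average smoothed) and kept white ones: the
estimated-edge versus true-coupling correlation across subjects is ~0.6–0.7
either way (estimation noise dominates at these series lengths), while
smoothed latents inflate the null distance correlation between uncoupled
regions above the generator's calibration property. The practical
consequence, demonstrated in `analysis/04_cpm.R`, is that networks estimated
from the synthetic series are attenuated readouts of the coupling, and
series-route prediction is markedly weaker than prediction from the
ground-truth coupling networks — the same attenuation that caps real-data
prediction at modest correlations.

Relatedly, with only 8 task trials the across-subject SD of *estimated*
task edges is dominated by estimation noise and exceeds the rest-edge SD,
even though the underlying task coupling varies less. The generator's
ground-truth networks show the intended rest > task ordering directly; the
paired-df structure (df = 77) is unaffected.

# Numerical choices and degenerate inputs

* Change-point search: exact prefix-sum SSE, smallest-k tie-break; degenerate
  (all-equal) input yields threshold `+Inf`.
* `S_W^2 = 0` voxels: NA sentinel, excluded from thresholding and clusters.
* Unbiased dCov^2 clipped at 0; dCor clipped into [0, 1]; constant patterns
  give 0.
* Zero-variance edges are excluded from CPM selection; constant edge sums
  make a fold fall back to the training mean.
* Zero-variance voxels are dropped (with a warning) before z-normalization;
  an all-constant ROV is an error.
* Cluster peak ties and all orderings are broken deterministically.

# Problem sizes in the shipped experiments

The test-suite and acceptance-script experiments run at the study's subject
count (97) and node count (13) but with the generator's desk-scale grid and
with permutation counts of 99 for the seeded calibration and recovery
experiments (the analysis scripts use the full 1000). The null-calibration
experiment uses 300 replicate datasets in the test suite (100 in the
acceptance script): the rejection indicator of an exactly calibrated test is
Bernoulli(0.05) per dataset, so the replicate count is chosen to make the
rate estimate's sampling error small relative to the ±0.03 acceptance band
rather than comparable to it.

# Known limitations

* Prediction recovery at unit signal-to-noise is capped by selection
  dilution: with 78 candidate edges and p <= 0.05 screening, each fold
  admits on average ~2 spurious edges alongside the 3 true ones, so the
  expected prediction correlation is roughly
  $\frac{1}{\sqrt 2}\sqrt{3/(3+k)} \approx 0.55$ rather than the
  oracle-mask ceiling of $1/\sqrt 2 \approx 0.71$ — about half of seeds
  fall below r = 0.5. The permutation test still flags the coupling in
  essentially every seed, and the contributing network recovers the true
  edges; it is the point estimate, not the detection, that dilution costs.
* Bonferroni FWE is conservative relative to random-field theory on smooth
  maps; cluster peaks and thresholds are therefore not comparable to
  SPM-style outputs voxel for voxel.
* The paired edge-SD comparison treats the 78 edge SDs as exchangeable
  observations; edges sharing a node are not independent, so its p value is
  descriptive.
* Single change point only: a variance map with more than one regime change
  in its sorted values is still split once.
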