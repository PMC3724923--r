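---
title: "Seed-based two-session connectivity and seed clustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based two-session connectivity and seed clustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedfc)
```

## The analysis problem

seedfc implements a seed-based resting-state functional connectivity
analysis for a two-session within-subject design: every subject is
scanned twice at rest (a "standard" session, then a "criticism" session
preceded by a mild social-evaluative stressor), and the question is how
the connectivity of a fixed set of seed regions differs between the two
states and how that difference co-varies with the subject's neuroticism
score.  Thirteen seeds are used by default: nine 6 mm spheres at
published self-reflection coordinates plus bilateral amygdala and
hippocampus taken from an atlas labelling.

The pipeline has five stages.

1. **Temporal preprocessing** per session: ordinary-least-squares
   regression of nuisance series — six rigid-body motion parameters, the
   global (brain-mean) signal, the first eigenvariates of white-matter
   and CSF masks — together with their backward-difference temporal
   derivatives and an intercept; then band-pass filtering to
   0.008–0.08 Hz.  The order is fixed: regression first, then filter.
2. **Seed extraction**: the first eigenvariate of each seed's voxel time
   series, i.e. the first principal temporal component of the
   column-demeaned `T x n` matrix, standardised to unit variance and
   sign-aligned so its mean covariance with the seed's voxels is
   positive.
3. **First level**: per voxel, OLS of the cleaned series on
   `[intercept, seed]`; the seed coefficient map is the connectivity
   map; the criticism-minus-standard difference of the two sessions'
   maps is the subject's contrast map.
4. **Second level**: per seed, voxelwise OLS of the subject contrast
   maps on `[intercept, gender, neuroticism]`, gender deviation-coded
   (women −1/2, men +1/2) as a factor of no interest and neuroticism
   centred *within* gender (women score higher on average, so global
   centring would alias gender).  Four one-sided contrasts are run:
   criticism>standard, standard>criticism, and ±neuroticism modulation.
   Family-wise error over voxels is controlled at cluster level by
   permutation (below).
5. **Seed clustering**: the group-mean contrast maps are stacked into a
   matrix `D` (rows = seeds, columns = in-mask voxels); the number of
   components is estimated from the eigenvalues of the 13×13 seed
   covariance of `D` over voxels, by the largest scree gap and by the
   maximum two-group profile log-likelihood; fuzzy c-means groups the
   seeds, dual memberships are flagged, and Pearson correlations
   between seed profiles give a weighted seed-similarity graph.

## Inference: permutation cluster-extent FWE

Random-field-theory cluster correction depends on smoothness estimates
that cannot be validated at desk scale, so cluster-level family-wise
error is controlled by permutation instead, which is exact under
exchangeability and directly testable by simulation:

* cluster-forming threshold: the one-sided `t` quantile at
  `voxel_p = 0.001`, with `df = n - rank(design)`;
* clusters: connected components of suprathreshold voxels under
  26-neighbour connectivity (faces, edges, corners); only clusters with
  extent `k > 20` are reported;
* null distribution: maximum cluster extent over sign-flipped
  Freedman–Lane residuals of the reduced model (for the intercept this
  reduces to sign-flipping the subject maps); the FWE p of a cluster is
  the fraction of null maxima at least as large, with the observed map
  counted once;
* reporting: up to three local maxima per cluster, pairwise at least
  8 mm apart, with `t`, the tail-matched `z`
  (`z = Φ⁻¹(P(T_df > t))`, computed on the log scale so large values do
  not saturate), MNI mm coordinates, the cluster FWE p, and a Bonferroni
  flag for the 13 seeds tested (`p < 0.05/13 < 0.003`, strict).

The type-I behaviour of the permutation procedure is checked by
simulation in the test suite: over 200 pure-noise cohorts at a scaled
operating point where rejections are attainable at all (a liberal
cluster-forming threshold and small extent rule on a small grid), the
empirical family-wise rejection rate at nominal 0.05 must stay below
0.07.  At the pipeline defaults (`p < 0.001`, `k > 20`) the null
rejection rate on a desk-scale grid is essentially zero — the extent
rule alone removes the tiny suprathreshold components that noise
produces.

## Model order and fuzzy c-means

Two rules estimate the number of seed networks from the descending
eigenvalues λ₁ ≥ … ≥ λ₁₃ of the seed-by-seed covariance of `D`:

* **scree gap** — Cattell's visual elbow operationalised as
  `argmax_q (λ_q − λ_{q+1})`, smallest `q` on ties;
* **profile log-likelihood** — for each split `q` the eigenvalues are
  modelled as two Gaussian groups with separate means and one pooled
  maximum-likelihood variance; the split with the highest summed
  log-likelihood wins.  A perfect two-group fit (zero pooled variance)
  dominates, and an all-equal spectrum returns 1 with a warning.

Fuzzy c-means uses the standard alternating updates with fuzzifier
`m = 2` (the field default; the original choice is unpublished, so it is
exposed in the configuration), convergence when the objective
`J_m = Σ u^m d²` changes by less than 1e-6, and 20 random restarts with
the lowest objective kept — FCM is sensitive to initialisation, and
seeded restarts make the result reproducible.  A seed exactly coincident
with a centroid receives membership 1 (the `m → 1` limit rule), so no
division by zero can occur.  Each seed is assigned to its argmax
cluster and additionally to the runner-up when the top-two membership
gap is below `dual_gap = 0.15`; the gap was chosen so that clearly mixed
(≈50/50) profiles flag dual while dominant ones (top membership above
~0.6) do not, and it is exposed in the configuration.

## The synthetic cohort: what it emulates and what it idealises

No scan data accompany the analysis, so a synthetic module generates
cohorts with the statistical structure the pipeline assumes, at
configurable scale, with a JSON truth manifest of every planted
quantity.  The default profile is desk-scale: 12 subjects (8 women,
4 men, the 2:1 ratio of the emulated cohort), two 150-volume sessions at
TR 2 s on a 24×28×24 grid at 2 mm — a full pipeline run takes seconds
on one CPU.  Neuroticism scores are drawn with the published
gender-specific moments (women 144.4 ± 17.7, men 127.4 ± 21.6,
NEO-PI-R-like) and rounded to integers.

Each voxel time series is a loading-weighted sum of four network time
courses plus nuisance structure (linear and quadratic drift, a shared
low-frequency global fluctuation, a motion-correlated component built
from the session's six random-walk motion parameters, WM/CSF-specific
signals) plus white noise (sd 0.5 in BOLD units against planted signal
amplitudes near 2).  The coupling gain of network *j* for subject *i*
is

```
gain = base + (session_effect_j + covariate_slope_j * neuro_centered_i) * is_criticism
```

with `base = 1.8`.  Thirteen seeds carry the four networks in the
default grouping — a prefrontal pair, a fronto-temporal triple, an
occipito-parietal pair, a subcortical quadruple, and two seeds (ACC,
SFG_BA10) with mixed 50/50 loading on the first two networks.

Three generator design choices deserve emphasis, because they are
idealisations that real data do not share:

* **Zero-sum spatial loadings.** Each network also has an
  anticorrelated "target" region whose negative loading exactly balances
  the network's seed loadings, so the planted signal sums to zero over
  the brain.  Global-signal regression is therefore transparent to the
  planted structure.  In real data the global signal contains neural
  signal and its regression biases connectivity; the generator removes
  that bias by construction rather than modelling it.
* **Nuisance-orthogonal, mutually orthogonal network series.** The
  network time courses are drawn from the 0.03–0.07 Hz Fourier subspace
  *orthogonal to the session's nuisance design* (motion, derivatives,
  global, WM/CSF signals, drift shapes) and to each other.  Two reasons.
  First, at 150 volumes the pass-band holds only ~26 real degrees of
  freedom, so independently drawn band-limited series would carry
  spurious cross-network correlations of order 0.2 — planted
  "orthogonal networks" would not actually be orthogonal.  Second,
  regression of ~19 nuisance columns removes a random in-band direction
  from every voxel; signal planted inside the removed span would be
  destroyed asymmetrically between sessions.  Whatever survives the
  preprocessing projections is all a seed GLM can ever recover, and the
  generator plants its signal exactly there, making preprocessing
  provably transparent to the truth (the noiseless pipeline reproduces
  `session_effect × loading` to numerical precision, a property the
  test suite asserts).  The planted band sits above the motion
  random-walk spectrum (≈1/f²), mirroring the physical fact that head
  drift is slow, and inside the 0.008–0.08 Hz analysis band.
* **Balanced network variance shares.** The default per-network session
  effects (0.8, 0.8, −0.8, 0.6) and target sizes (one 6.5 mm sphere /
  two 6 mm spheres / one 4 mm sphere / one 6 mm sphere) were chosen on
  the noiseless analytic profile matrix so that the four components
  contribute comparable eigenvalue shares despite the unequal seed
  counts, and so that the two mixed seeds sit symmetrically between the
  first two clusters.  This emulates the reported situation in which
  both model-order rules agree on a four-component solution and the two
  mixed seeds load on two clusters; with arbitrary effect sizes the
  eigenvalue spectrum of a 13-seed matrix is easily dominated by one
  network and neither property holds.  Networks 1 and 2 share equal
  effects and equal profile norms because the eigenvariate of a mixed
  seed normalises by the session's total variance: unequal gains would
  push the mixed seeds asymmetrically toward the stronger network.

Consequently, a green test suite shows that the pipeline correctly
recovers structure *of the kind it assumes*: band-limited,
nuisance-orthogonal, linearly mixed network signal with planted
session and covariate modulation.  It does not show robustness to
global-signal contamination, motion-correlated signal of interest,
non-stationarity, or physiological noise inside the pass-band — all of
which real resting-state data contain.

## Numerical choices and degenerate inputs

* The band-pass filter is a linear detrend followed by an orthogonal
  projection onto the in-band Fourier subspace — an ideal filter, which
  makes the pass/stop contracts exact (in-band sinusoids keep ≥95% of
  their amplitude, out-of-band ones ≤5%).
* Sphere ROIs use the inclusive voxel-centre rule (centre distance
  ≤ radius), which reproduces the canonical 123-voxel / 984 mm³ count
  for r = 6 mm on the 2 mm grid; a sphere that would be clipped by the
  grid is an error reporting the clipped voxel count.  Seed tables with
  overlapping spheres (the published coordinates contain one such pair
  7.2 mm apart) produce a warning, not an error.
* Eigenvariate extraction solves the smaller-side symmetric
  eigenproblem; an all-zero ROI is an error.  Zero-variance seed
  regressors and rank-deficient nuisance designs (after dropping exact
  duplicate columns) are errors naming the offending columns.
* `t`→`z` uses log-scale tail probabilities, so `t = 60` maps to a
  finite `z` instead of `Inf`.
* Voxels with numerically zero residual variance at second level get
  `NA` and are excluded from clustering.
* Standard sessions acquired longer than the criticism session are
  truncated to the first `n_keep` volumes (150 by convention) before
  any processing.
* All randomness (cohort generation, FCM restarts, permutations) is
  seeded and scoped: the caller's RNG stream is restored afterwards,
  and regenerating a cohort with the same seed reproduces every array
  bit for bit.

## Known limitations

* The session-gain recovery has a small multiplicative bias (the seed
  eigenvariate is an estimate, so betas are attenuated by its
  reliability); the validation suite therefore recovers gains from the
  *ratio* of session betas, which cancels the session-symmetric part.
  The network with the weakest session gain retains a ~1–2% slope
  bias from gain-dependent attenuation.
* Cluster-extent inference is one-sided per contrast; two-sided maps
  require running both directional contrasts, as the driver does.
* The driver runs permutations per seed and per contrast independently;
  across-seed multiplicity is handled only by the Bonferroni flag.
* Dynamic (time-varying) connectivity, scrubbing, ICA denoising and
  physiological-recording regression are out of scope.

## Problem sizes used in the validation suite

Stochastic validation uses the default desk-scale cohort: 50 seeded
replicates for the model-order and partition-recovery checks, 200
pure-noise cohorts (12 subjects on a 12×12×10 grid, 199 permutations)
for the type-I calibration, and one default cohort for parameter
recovery.  These sizes keep the complete suite in the tens of minutes
on one CPU while leaving the Monte-Carlo error of every rate estimate
well below the margin it is compared against.
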