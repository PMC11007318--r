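---
title: "Models and methods: carry-over adaptation designs, tuning-curve BOLD simulation, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adaptmap)
```

This vignette is the package's account of its science: the generative
model behind the synthetic BOLD data, the statistical machinery of the
analysis path, the parameters that matter (with units and defaults), and
the places where the design was genuinely open and a choice had to be
made.

## The task and the carry-over design

The simulated experiment is a location-identification task on a virtual
linear track. Four test locations sit at 4, 8, 12 and 16 m, evenly spaced
at 4 m; an arrow set at 0 m anchors path integration and a tree beyond
the far end (20 m) anchors landmark navigation. On each trial the
participant is transported passively from a start position drawn from
U[−18, −4] m at a speed drawn from U[2, 5] m/s, then occupies the test
location for exactly 4 s — the phase all fMRI analyses target — before
responding. Trials run back to back; the phases are start (0.7 s),
movement (path length / speed), arrival (2 s), occupation (4 s), response
(2 s) and feedback (1 s). The arrival, response and feedback durations
are generator choices (the occupation and start durations, the kinematic
ranges, and the 4 m spacing define the conditions; the remaining phase
durations only set the pacing). Null events are 4 s fixations, matching
the occupation duration — another choice where no value was dictated.

Adaptation can only be estimated if every location precedes every other
a balanced number of times. `generate_debruijn()` produces a second-order
counterbalanced sequence over five event types (four locations plus
null): length k² = 25, five occurrences per type, and — read cyclically —
every ordered pair of types exactly once. Internally this is a uniform
random Eulerian circuit (Hierholzer's algorithm with randomized edge
choice) on the complete transition multigraph. The published
"path-guided" construction additionally biases sequence selection toward
high detection power with unspecified thresholds; we replace that bias by
generate-and-screen: `relative_detection_power()` scores a realized
design's GLM efficiency for a named contrast, `e = 1 / (cᵀ(XᵀX)⁻¹c)`,
as a percentile against freshly generated candidate sequences. The final
sequence event is duplicated and prepended (26 presented events) so the
hemodynamic response is in steady state when the cyclic sequence begins;
the duplicate is modeled but excluded from the 20 effective trials.

Sessions are planned as 2 blocks × 4 runs, each block a random
permutation of the four cue × environment combinations with no
combination repeated across consecutive runs — the Latin-square flavor of
the original counterbalancing without its (unstated) exact squares.

## The generative voxel model

Each voxel *v* carries, per cue (and optionally per environment), a
Gaussian tuning curve over track position with center `c_v`, width
`σ_cue`, gain `g_v`, and suppression strength `s_v ∈ [0, 1]`. The
occupation-phase neural amplitude is

```
A_v(t) = g_v · T_v(x_t) · (1 − s_v · Ω_v(x_t, x_{t−1})),
T_v(x)  = exp(−(x − c_v)² / 2σ²),
Ω_v(x, x′) = exp(−(x − x′)² / 2σ²),
```

with no suppression term on trials without an adaptable predecessor
(after a null event, or the duplicated first trial). This is the
simplest mechanism realizing the tuning-curve account of the two coding
formats: at σ = 0.5 m (the landmark default) the overlap at the 4 m
spacing is below 10⁻¹⁴, so suppression occurs only on exact repeats —
identity coding; at σ = 6 m (the self-motion default) overlap declines
smoothly over 0/4/8/12 m — distance-graded coding.

Tuning centers are drawn uniformly over the 0–20 m span for broad
populations. For sharp populations a uniform draw would leave ~90% of
voxels silent at every test location, so the default
(`center_mode = "locations"`) places centers at a random test location
plus N(0, σ) jitter — the natural reading of identity coding as units
tuned to the discrete, familiar locations. Both modes are exposed.

Gains are U[0.5, 1.5] and suppression strengths U[0.25, 0.75]; the
across-voxel heterogeneity of `s_v` and `g_v` is what gives each cue a
*spatial pattern* of adaptation for the similarity analysis. The
`cue_specific` flag controls whether the two cues draw independent
parameter maps (the default) or share one; `env_specific` does the same
per environment and defaults to environment-shared landmark maps and
environment-specific self-motion maps, mirroring the two regimes the
pattern analysis is designed to distinguish.

BOLD synthesis convolves the neural boxcars (plus a cue-constant
movement-phase response of height `0.5 · g_v`, so the GLM's movement
regressors have a real signal to absorb) with the canonical double-gamma
HRF (response peak 6 s, undershoot 16 s, ratio 6) at 0.1 s microtime,
samples at TR = 2 s, and adds: polynomial drift (order 2, random
amplitudes of SD 0.5 per basis), AR(1)+white noise (φ = 0.3, marginal SD
1), and motion-correlated nuisance (six random-walk series with
N(0, 0.1) voxel loadings). The HRF kernel is normalized so a 4 s unit
boxcar peaks at 1.0, putting gains on the scale of peak occupation
response; with marginal noise SD 1 the typical single-trial CNR is ≈ 0.5,
an ordinary event-related regime. Identical seeds give bitwise-identical
output; all per-participant/run/stage seeds derive from one master seed
by counter-based splitting.

Behavioral responses are Bernoulli with accuracy linear in location
index: rising toward the tree for landmarks (0.90 → 0.975) and falling
away from the arrows for self-motion (0.90 → 0.63), a crossover matching
the anchor-distance logic of the two strategies; the chance floor 0.25
is enforced by clipping. Wrong responses favor neighboring locations
(weights halving per index step).

What the generator does *not* emulate: spatial autocorrelation between
voxels, physiological noise, motion that actually displaces voxels,
scanner drift nonstationarity, and between-day map drift. Passing tests
therefore show that the analysis machinery is correct and calibrated
under a known generative model — not that real data would show these
effects at these sizes.

## First-level GLMs

`build_design()` constructs, per run: an adaptable-occupation boxcar, a
separate non-adaptable-occupation boxcar (post-null and duplicated
trials), a movement regressor (movement phase only by default; the
entire pre-occupation navigation stage under
`movement_model = "phases123"`; or none), all convolved with the
canonical HRF at 0.1 s microtime with onsets not locked to the TR grid,
plus a temporal derivative per event regressor, per-run motion and
polynomial-drift nuisance columns, and the parametric modulators.

Modulators are mean-centered within run and attached to the adaptable
occupation events — *without* serial orthogonalization. In
joint-modulator designs (distance + identity; location + path length;
location + response; location + temporal distance) the unique
contribution of each variable is read directly from its OLS partial
coefficient; orthogonalization order would silently privilege one
variable, which is exactly what the unique-contribution logic must not
do. The sign convention is: positive modulator beta = activation rising
with distance/identity = adaptation present.

Fitting is plain OLS via QR (`fit_glm()`), with the column-correlation
matrix reported for collinearity diagnostics; an optional prewhitening
stage was considered and dropped — at these run lengths and noise levels
OLS betas are unbiased and the group-level tests operate on
per-participant summaries, so AR(1) correction would change nothing the
pipeline tests. Rank-deficient designs and all-zero modeled columns are
errors that name the offending columns. On generated designs the
movement regressor correlates with the adaptation modulators at
|r| < 0.05 and the distance and temporal-distance modulators at
|r| < 0.1 pooled over a session — the decorrelation the carry-over
design exists to buy.

The visualization variant (`build_binned_design(run, "distance")`)
replaces the modulator with one occupation regressor per inter-location
distance; derivatives are kept for symmetry with the main model. The
same machinery with `bins = "pair"` yields one regressor per
(previous, current) location pair — each pair occurs exactly once per
run by the carry-over property — and is the input to the reconstruction
analysis. The success-contrast model (`success_design()`) concatenates
all 16 runs (some runs have no errors), with exactly four cue ×
correctness occupation regressors, per-run mean, movement, motion and
drift columns; a participant with an empty cue × correctness cell is
rejected with instructions to drop them.

## Group statistics

ROI summaries are winsorized by the boxplot rule — values outside
[Q1 − 3·IQR, Q3 + 3·IQR] move to the nearest inlier — with quartiles by
linear interpolation (R type 7); the quartile convention is a stated
choice (Tukey hinges differ slightly and no convention was dictated).

Directional one-sample *t* tests carry a JZS Bayes factor with Cauchy
prior scale r = 0.707, computed by adaptive quadrature of the
noncentral-*t* marginal likelihood. For one-sided tests the prior is
*truncated* to positive effects: the package's test suite verifies this
choice numerically against printed (t, n, BF₁₀) benchmark triples at
n = 20, which the truncated prior reproduces to under 1% while a
symmetric prior is off by a factor of ~2.

Familywise error across a family of ROI × cue tests is controlled by
sign-flip maximum-statistic permutation (`max_stat_correction()`): all
2ⁿ sign patterns when n ≤ 14, else random flips with the identity
pattern always included, so corrected p ≥ 1/n_perm. Voxel-wise inference
(`voxelwise_group_map()`) uses the same flips for a max-t null and a
max-cluster-size null with cluster-forming threshold T > 3 and
26-connectivity — both thresholds are stated defaults, the connectivity
choice being conventional for volumetric data.

The repeated-measures ANOVA (`rm_anova()`) implements the balanced
fully-within decomposition directly — each effect tested against its own
effect × subject stratum, partial η² = SS/(SS + SS_err) — cross-checked
in the tests against `stats::aov` error strata and the F = t² paired
equivalence. No sphericity correction is applied by default (none was
dictated; the 4-level factor is the only candidate). Linear trend
contrasts use normalized weights (−3, −1, 1, 3) against the trend's own
error stratum, giving the (a−1)(n−1) degrees of freedom convention.

## Adaptation-pattern distinction

Per run and cue an adaptation vector holds the signed voxel-wise
modulator betas (identity for landmarks, distance for self-motion — each
cue's dominant format). The environment factor is averaged out
voxel-by-voxel within each (cue, day, block) pair of adjacent runs from
different environments: 8 vectors per cue become 4. All C(8,2) = 28
cross-run pairs are Pearson-correlated, Fisher-transformed *before* any
averaging, and labeled by cue relation × day relation (the 2 × 2 = 4
pairing categories; 12 within-cue, 16 between-cue pairs). Because no
pair shares a source run, pure noise has zero expected correlation — the
cross-validation property that makes a positive within-cue similarity
evidence of a stable pattern rather than shared noise. The distinction
score is mean within-cue z minus mean between-cue z, per day-relation
stratum; group inference is the directional one-sample *t* test.
Jackknife portion contributions recompute the within-day score with each
of the 10 voxel portions left out; the portion effect is then a
one-factor repeated-measures ANOVA.

At the default conditions a single 20-participant cohort tests the
distinction score at t ≈ 2 — deliberately in the regime such designs
actually occupy rather than a caricature with unbounded power; the
acceptance battery pools three cohorts for a reliable decision.

## Neural-space reconstruction

The location × location matrix of mean ROI activation for current
location j preceded by i is symmetrized, D = (M + Mᵀ)/2, and min-max
normalized to [0, 1] (a z-normalization variant is exposed; the original
normalization is not public, so the choice is flagged and isolated).
Higher activation = less suppression = larger neural distance; the
same-location cells supply the baseline minimum. Classical (Torgerson)
MDS with the diagonal treated as zero embeds the four locations on one
dimension; `procrustes_test()` aligns the embedding to the physical
coordinates {0, 4, 8, 12} m by optimal translation and positive scaling
and reports the normalized residual d = 1 − r², with significance
one-tailed on small d over the exhaustive 24 label permutations
(identity included, so the minimum p is 1/24 ≈ 0.042).

Two interlocking choices deserve care. A distance matrix cannot
distinguish a configuration from its mirror image, so the MDS axis sign
is fixed by convention — non-negative correlation with the label axis —
before the permutation step. And reflection is *not* allowed in the
alignment by default: if it were, every labeling would tie with its
mirror (reversing the labels only flips the sign of r, and d = 1 − r²
ignores the sign), capping the attainable one-sided p at 2/24 ≈ 0.083
and making the test useless at n = 4. The cost of this construction is
mild anti-conservativeness: under a perfectly flat (identity-coding)
matrix the chance of reaching p = 1/24 by noise is about 1/12 rather
than 1/24, because the orientation convention hands the observed
labeling an |r| rather than a signed r. We accept this: the test is used
to *compare* regimes (graded codes reconstruct, identity codes almost
never do), not to calibrate a 5% error rate, and the reflection-allowed
variant remains available via `allow_reflection = TRUE`.

## Gradient segmentation

`fingerprints()` correlates each ROI voxel's time series (GLM residuals
standing in for resting-state data) with the top SVD components of a
reference region (rank 20 by default; the ROI itself may serve as its
own reference), then correlates fingerprints between voxels.
`dominant_gradient()` clips negative similarities to zero, forms the
symmetric normalized graph Laplacian, and takes the first nontrivial
eigenvector mapped through D^(−1/2) (the random-walk eigenvector, which
is monotone along a chain graph — the property the tests pin down);
disconnected similarity graphs are an error rather than a silently
multi-modal gradient. `partition_gradient()` rank-orders voxels (ties
broken by index) into 10 portions whose sizes differ by at most one.
This is a minimal re-implementation of the connectopic-mapping idea:
only the gradient ordering and the balanced split are consumed
downstream, so multiple connectopies, spatial statistics and
surface-based variants are out of scope.

## Problem sizes and numerical choices

The desk-scale study is 20 participants × 2 sessions × 8 runs × 200 ROI
voxels — the full experimental structure at a reduced voxel grid, chosen
so the complete pipeline runs in tens of seconds per cohort and the
whole test battery in minutes. Microtime is 0.1 s; convolution is FFT
per column with trial-factored synthesis (the neural signal is an outer
product of trial boxcars and voxel amplitudes, so only trial columns are
convolved). OLS uses QR; residual orthogonality to the design holds to
1e−8 and noiseless round trips recover injected amplitudes to better
than 1e−6 relative error. Degenerate inputs fail loudly: empty
(previous, current) cells, all-zero distance matrices, non-positive
leading eigenvalues, zero-variance vectors (pairs skipped with one
warning), constant time series, disconnected graphs, empty masks, and
all-equal values in the winsorizer (returned unchanged).

## Known limitations

Voxels are statistically independent given their parameters; there is no
spatial smoothness, so cluster-level inference is exercised on
block-signal constructions rather than realistic smooth fields. OLS
without prewhitening slightly misstates single-run standard errors
(harmless here because inference is at the group level). The behavioral
model has no lapse/bias decomposition. The reconstruction's permutation
test is exact but coarse (24 permutations) and mildly anti-conservative
under flat matrices, as discussed. Between-day pattern drift is not
modeled, so within-day and between-day distinction scores have the same
expectation in simulation even though real data may dissociate them.
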