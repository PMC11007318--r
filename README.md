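# adaptmap

Simulation and analysis of carry-over fMRI adaptation (repetition
suppression) studies of spatial coding on a virtual linear track.

## The scientific problem

When a navigator occupies a location that is the same as — or near — the
previously occupied one, the BOLD response of a region coding position is
reduced; the size of this *repetition suppression* indexes how much the
two locations overlap in the neural code. Studies of landmark-based
navigation versus path integration use this to ask three questions:

1. **Is position coded at all?** A parametric modulator on the location
   occupation regressor — inter-location distance `|x_t − x_{t−1}|`
   (values 0/4/8/12 m) or location identity (0 = same, 1 = different) —
   should earn a positive group-level beta.
2. **What is the format of the code?** Sharp tuning curves produce
   *identity* coding (suppression only on exact repeats); broad tuning
   produces *distance-graded* coding. Graded codes, and only graded
   codes, let one reconstruct the physical track by classical MDS +
   Procrustes alignment from the location × location "neural distance"
   matrix.
3. **Is the code cue-specific?** The *adaptation pattern distinction
   score* — mean within-cue minus between-cue Fisher-z correlation of
   voxel-wise adaptation maps across runs — is positive when landmark and
   self-motion navigation recruit distinct voxel populations.

`adaptmap` implements the full computational path: second-order
counterbalanced (de Bruijn) event sequences whose cyclic ordered pairs
each occur exactly once (so carry-over effects are estimable without
bias), trial-timing realization, a synthetic BOLD generator whose voxels
implement tuning-curve-based suppression
(`amplitude = gain · T(x_t) · (1 − s · Ω(x_t, x_{t−1}))`, with Gaussian
tuning `T` and normalized overlap `Ω`), first-level GLMs with parametric
modulators, group statistics (boxplot-rule winsorization, directional
one-sample *t* tests with JZS Bayes factors at Cauchy scale *r* = 0.707,
sign-flip maximum-statistic permutation correction, balanced
repeated-measures ANOVA with trend contrasts), the pattern-distinction
analysis with jackknife portion contributions, 1-D neural-space
reconstruction, and a simplified connectopic-gradient segmentation.

## Worked example

Simulate the default cohort — 20 participants × 2 sessions × 8 runs
(26 presented events each, 20 effective trials) × 200 ROI voxels, sharp
landmark tuning (σ = 0.5 m) versus broad self-motion tuning (σ = 6 m) —
and run the whole pipeline:

```r
library(adaptmap)
res <- run_study(study_config(master_seed = 101))
print(res)
#> <study_result>
#>   univariate landmark     mean 0.0837, t(19) = 20.537, p[1-tailed] = 9.833e-15, BF10 = 558764279877.848
#>   univariate self_motion  mean 0.0204, t(19) = 51.181, p[1-tailed] = 4.004e-22, BF10 = 5340422158013039616.000
#>   within-day pattern distinction: mean 0.0024, t(19) = 0.267, p[1-tailed] = 0.3963, BF10 = 0.287
#>   reconstruction landmark     <reconstruction> d = 0.3093, p_perm = 0.1250 (24 permutations)
#>   reconstruction self_motion  <reconstruction> d = 0.0364, p_perm = 0.0417 (24 permutations)
```

Reading the output: both cues show strongly positive mean adaptation
betas (position is coded). The joint distance+identity model
(`res$joint`) dissociates the formats — for landmarks the unique identity
contribution is significant while the unique distance contribution is
null, and vice versa for self-motion. Only the broad-tuning (self-motion)
regime reconstructs physical space: `d` is the normalized Procrustes
residual in [0, 1] and `p_perm` the one-sided exhaustive 24-permutation
p value, whose minimum 1/24 ≈ 0.042 the self-motion regime attains. The
single-cohort distinction score is positive in expectation but tests at
roughly unit power here (t ≈ 2 across seeds, comparable to the effect
sizes such designs yield); pooled cohorts in the test suite recover it
reliably. A `2.940 → 11.77` check of the Bayes factor:

```r
bf_jzs(2.940, n = 20, r = 0.707)   # directional JZS
#> [1] 11.77437
```

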