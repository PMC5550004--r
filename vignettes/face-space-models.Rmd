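---
title: "Encoding models and measurement effects in simulated face spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models and measurement effects in simulated face spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a norm-based face space, individual faces are points in a
high-dimensional space whose origin is the average ("norm") face:
direction from the norm carries identity, radial distance (eccentricity)
carries distinctiveness. Functional imaging studies compare such spaces to
the brain by predicting a representational dissimilarity matrix (RDM) —
the matrix of pairwise distances between the response patterns evoked by
each stimulus — and correlating it with RDMs estimated from cortical
activity or perceptual judgments. The catch is that an fMRI voxel does not
record single neurons: it averages many differently tuned neurons in a
small neighborhood, non-negatively. `facersa` implements a family of
neurally plausible encoding models together with an explicit model of that
measurement step, and the full inferential machinery needed to adjudicate
between them on (here, simulated) data.

## Stimulus geometry

`sample_slice(D)` draws a uniformly random orthonormal 2-frame in `D`
dimensions (two standard-normal vectors, Gram–Schmidt). Each simulated
participant receives their own slice: physically distinct stimuli with an
identical underlying similarity structure, because `build_polar_grid(r,
basis)` always lays out the same 12 faces — all combinations of three
eccentricity levels (30%, 100%, 170% of the mean eccentricity `r`) and
four directions at 60° separation spanning a half-circle. The half-circle
(rather than full-circle) layout decorrelates eccentricity coding from
adaptation-style accounts, and the polar arrangement gives a much higher
variance of pairwise dissimilarities than random sampling in high
dimensions (`analysis/01_reference_space.R` quantifies this: about 0.47 vs
0.02 for isotropic Gaussian draws). Each face appears at two viewpoints
(left/right); both share one face-space coordinate, so coordinate-input
models are view-tolerant by construction and all view-specificity enters
at the image/measurement level. `r` defaults to 1 and every model
parameter with face-space units is expressed relative to it. `D` defaults
to 50; the reference RDM is invariant to both the slice seed and `D`
(isometric embedding), which the test suite asserts.

## Encoding models

**Sigmoidal ramp** (`ramp_model(o, s, p)`): 1000 units, each preferring a
random direction in the slice and responding to the signed projection `x`
of the stimulus on that direction as

$$y_{raw} = \frac{1}{1 + e^{(-x + o)/s}}$$

with offset `o` (0 centers the sigmoid midpoint on the norm; positive
values shift it away from the norm) and saturation `s` (around 4 is
near-linear over the stimulus domain; near 0 approaches a step). A useful
consequence of random directions: with `o = 0` the population-mean
activation profile is exactly flat in expectation (opposite-direction
units cancel, since `sigmoid(x) + sigmoid(-x) = 1`), whereas any `o > 0`
yields a genuinely increasing profile with eccentricity. The phenomenon
checks therefore use an offset ramp.

**Exemplar** (`exemplar_model(w, d, p, inverted)`): 1000 units preferring
Cartesian coordinates drawn from an isotropic Gaussian around the norm,
responding through an isotropic Gaussian with full width at half maximum
`w` (response 1 at the preferred point, 0.5 at radius `w/2`). The center
spread `d` is anchored so the Z = 2.32 point of the center-distance
distribution sits at `d` times the caricature eccentricity. We read
"Z = 2.32" as the standard-normal probability level (Φ(2.32) ≈ 0.9898)
applied to the *radial* distance distribution, which for an isotropic 2D
Gaussian is Rayleigh, so the per-axis scale has the closed form
`d · ecc_car / sqrt(-2 log(1 - Φ(2.32)))`; a `reading = "marginal"` switch
anchors the 1D marginal at `2.32 σ` instead. The inverted variant maps
each radial distance `t` to `T - t` (with `T` the Z = 2.32 point) and
truncates negatives to zero; by construction the truncated fraction is
`1 - Φ(2.32)` ≈ 1.02%, matching the quoted "1% of exemplars".

**Measurement-level population averaging** (`population_average(resp,
p)`): each unit's response is translated toward the per-stimulus
population mean,

$$y_{final} = (y_{raw} - \bar{y})(1 - p) + \bar{y},$$

so `p = 0` is a faithful readout and `p = 1` reduces every unit to the
population mean. The operation preserves each stimulus's mean exactly and
scales the across-unit spread by `1 - p`; consequently activation
profiles (per-condition means over units) are independent of `p`, while
RDMs are reshaped — distances that modulate the population mean are
over-represented. This is the package's model of voxel-level pooling,
and its two signature phenomena are asserted in the tests: the
radial/tangential distance ratio of the ramp model is non-decreasing in
`p`, and the Gabor model's mirror-pair distances collapse as global
pooling approaches 1.

**Gabor filter model** (`build_filter_bank()`, `gabor_rdm()`): an
image-input control with 5 spatial-frequency banks × 8 orientations × 2
phases on square grids of centers, coarser for lower frequencies. The
paper family this follows does not fix the geometry, so the defaults are
declared, not inferred: 96 px images, octave-spaced wavelengths
{32, 16, 8, 4, 2} px, grid spacing of one wavelength, envelope
σ = wavelength/2. Filters are built as truncated (±3σ) patches, clipped at
the image border, and zero-meaned and unit-normed per filter *after*
clipping, so "DC-free, unit-norm" holds exactly for every filter —
asserted over all 49k phase rows. Quadrature pairs collapse to contrast
energy `sqrt(a² + b²)`; energies are bank-weighted (5 weights), then
pooled in two mean-preserving stages: hemifield-specific (features split
by filter-center side of the vertical midline; exact-midline centers go
left, though the default geometry avoids them) and global. Mirror
tolerance is emergent, not built in: the orientation set is closed under
left–right reflection, so a mirrored image permutes the feature vector,
leaving the mean intact — with no pooling mirror pairs are about as
distant as unrelated pairs, with full global pooling they collapse.

**Pixelwise correlation** (`pixelwise_correlation_rdm()`): the
zero-parameter control, one minus the Pearson correlation of intensity
vectors.

## Crossnobis distances

`cv_rdm()` estimates pattern discriminability from run-wise condition
pattern estimates: per leave-one-run-out fold, discriminant weights are
the training-mean contrast multiplied by the inverse noise covariance
(estimated from the training runs' residual time courses), unit-length
normalized per fold, and projected on the test run's contrast; fold
estimates are averaged. The estimator is unbiased under the null — it can
go negative — which licenses ordinary group T tests against zero. With
the full covariance estimator, no cross-validation and no normalization,
the statistic reduces to the squared Mahalanobis distance; the tests
assert this against `stats::mahalanobis()` to 1e-8, and a 1000-dataset
null simulation (V = 40, 16 runs) checks centering on zero.

The "sparse prior" covariance is implemented as analytic shrinkage of the
sample covariance toward its diagonal (Schäfer–Strimmer-style intensity),
which guarantees invertibility even with fewer timepoints than voxels; no
installed package provides this estimator, so it is written in-package
and pluggable. The mean-removal control first sets every condition
pattern to spatial mean zero (removing additive offsets), then projects
the pair-mean pattern out of each contrast (removing multiplicative
scaling of a shared pattern); both steps run in train and test. Pairs
whose training contrast is exactly zero arise in noiseless simulations
(the two viewpoints of an identity have identical patterns); the RDM path
reports the continuous limit 0, while an explicit single-pair
`cv_distance()` query raises a degenerate-pair error.

## Regression RSA, ceilings, fitting, inference

`build_rsa_predictors()` partitions the squared reference distances: for
a pair with eccentricities `(e_i, e_j)` the eccentricity predictor is
`(e_i - e_j)²` (the minimum squared distance in the pair's eccentricity
group — no direction change) and the direction predictor is the
remainder. The partition is complete: regressing the squared reference
matrix on its own predictors returns eccentricity 1, direction 1,
constant 0 with zero residual. That identity is asserted at 1e-10 on the
OLS coefficients (where it holds to ~1e-15); the sign-preserving
square-root back-transform maps coefficient noise ε to √ε, so the
back-transformed constant is asserted at 1e-6 — a property of the printed
transform, not of the fit. Data RDMs are squared with sign preserved
(cross-validated estimates keep their negativity), fitted by OLS, and
estimates are square-root transformed back with sign.

`noise_ceiling()` bounds the Fisher-Z performance achievable by the true
model: lower bound by leave-one-participant-out prediction from the
others' mean, upper bound in-sample from the grand mean; averaging is on
the Z scale and only reporting reverses the transform. `grid_search_fit()`
computes the participant-by-cell Fisher-Z matrix once — each cell's RDM
predicted from that participant's *own* stimuli, so left-out evaluation
stimuli are new by construction — then every leave-one-participant-out
split selects the cell with the best training mean (ties: first cell in
row-major order, for determinism) and scores it on the left-out
participant. Correlations at machine ±1 (noise-free fits) are clipped at
|r| = 1 − 1e-12 before `atanh`, with a warning. Group inference uses
one-sample and paired T tests on Fisher-Z values, with the degenerate
zero-spread case handled explicitly (p = 1 when all values equal the
null), and the 2×2 metric-by-viewpoint ANOVA is implemented as paired
contrasts — the exact repeated-measures decomposition, verified against
`stats::aov` in the tests.

## The synthetic generator: what it emulates, and what it does not

`generate_participant(seed)` is a pure function of its seed: slice, grid,
24 stimulus images, and sub-seeds for unit sampling and run simulation.
Images are synthetic stand-ins for rendered face stimuli: a participant-
specific very smooth "norm" field plus D band-limited random fields
(sinusoids with 4–20 cycles per image, inside the Gabor banks' passband)
weighted linearly by the embedded face-space coordinates, under a
feathered oval aperture, with the right viewpoint an exact horizontal
mirror and all 24 images normalized to identical mean and RMS contrast.
Two properties carry the scientific load: pixel content varies smoothly with
face-space position (pixelwise-correlation RDMs correlate with the
reference RDM), and identity content is band-limited while the norm is
not, so band-pass (Gabor) contrast grows with eccentricity at fixed RMS —
the image-level analogue of the increasing activation profile. These are
*design choices*, not derived facts about faces: passing tests show the
pipeline behaves correctly on stimuli with these properties, not that
real face photographs have them.

`simulate_runs()` makes voxels non-negative uniform mixtures of unit
responses, adds Gaussian noise with mild spatial correlation
(`rho^|i-j|`, ρ = 0.3, V = 100 by default — the real noise spectrum and
voxel count are unreported, so these are declared parameters), and draws
matching residual series for covariance estimation. True patterns are
rescaled to unit mean across-condition standard deviation so `noise_sd`
is directly a noise-to-signal ratio; 1 is the package's "moderate noise"
condition. Note that non-negative mixing itself adds measurement-level
averaging on top of the generating model's `p` — the very premise of the
measurement model — so parameter recovery is expected to land at or above
the generating `p` (with the default FFA-like truth, one grid step
above). Region defaults mirror the study's winning accounts: "FFA-like" =
ramp with strong averaging (`p ≈ 0.9`), "EVC-like" = Gabor with hemifield
and strong global pooling (`gabor_model_spec()`).

`simulate_pair_of_pairs()` enumerates all 2145 pairings of the 66 face
pairs and chooses by a logistic link on the distance difference with
noise `tau` — the simplest link consistent with a percent-choice matrix.
At `tau = 0` ties are split exactly 50/50 (expected counts, not coin
flips), making the deterministic limit a true monotone transform of the
generating distances. The bounded percent scale mildly compresses large
distances, so eccentricity/direction balance is recovered approximately
(ratio within ~20–30% of 1), clearly separated from genuinely warped
generating spaces. `generate_trial_sequence()` builds the first-order
counterbalanced run order as a seeded Eulerian circuit (Hierholzer) over
the complete transition multigraph with one extra self-loop per face —
156 trials, every ordered pair once, every repetition twice — and
`randomize_viewpoints()` rejection-samples viewpoint assignments until
all 24-condition off-diagonal transfers are 0 or 1.

## Fold-dependence calibration

Leave-one-participant-out splits share training participants, so T tests
over splits could be anticonservative. `simulate_fold_dependence()`
measures this directly: two arbitrary model RDMs per simulated dataset,
a small nuisance grid per family (the model mixed with a family-specific
distractor) selected on training data, and the study's T tests on the
resulting split estimates. The dependence is real but its size is
controlled by how *diverse* the candidate set is: with candidates as
correlated as a real grid neighborhood (default mixing 0–0.2) the null
difference-test rejection stays at the nominal 5% (0.045–0.058 across
1000-simulation runs), while an independent distractor mixed at full
strength inflates it to ~0.14. `analysis/05_calibration.R` reports the
sweep; the default emulates the fitting procedure, where selection
concentrates among near-equivalent top cells.

## Problem sizes and runtimes

The package's own checks run at deliberately modest scale, chosen to keep
the full suite under a minute while leaving every assertion
comfortably powered: 1000 model units (the study's size), 10 simulated
participants for recovery, 16 runs × 100 voxels per dataset, 1000
simulations for the null-centering and calibration checks, 10⁶ draws for
the truncation percentage, and one shared 96 px filter bank. The analysis
scripts use 6 participants per region and finish in about a minute
altogether.

## Known limitations

- The reference space is treated as isotropic; real shape/texture
  principal components are not.
- Synthetic images share only the two properties listed above with real
  face renders; image-model conclusions transfer to real stimuli only to
  the extent those properties do.
- No hemodynamic convolution: run-wise pattern estimates are the
  simulation's entry point, and trial sequences — though constructed
  exactly — are not pushed through a GLM.
- The exemplar center anchor has two defensible readings (radial vs
  marginal); both are implemented, radial is the default, and the ~1%
  truncation anchor holds under the radial reading.
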