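---
title: "Texture statistics, synthesis, and the foveated pooling observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture statistics, synthesis, and the foveated pooling observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(texpool)
```

## The scientific problem

Peripheral vision seems to trade detail for summary: the visual system is
thought to measure local statistics of the image — averages of products of
oriented filter responses — over regions that grow linearly with
eccentricity, and to discard the spatial arrangement from which those
averages were computed.  This hypothesis makes a sharp, testable
prediction with two opposite faces.  Discriminating *texture families*
(images with different statistics) should get easier as a stimulus grows,
because statistics are estimated more reliably over larger regions.
Discriminating *texture samples* (physically different images with
identical full-field statistics) should get *harder* as the stimulus
grows, because the estimates converge to the same values.  `texpool`
implements the full computational pipeline needed to simulate this
tradeoff: the texture statistic model, the synthesis procedure that
manufactures families and samples, and a noisy, normalized,
eccentricity-scaled pooling observer that performs AXB discrimination.

## The statistic model

Images are decomposed with a complex steerable pyramid (`build_pyramid()`)
with K = 4 scales and O = 4 orientations.  The filters are polar-separable
in the Fourier domain — raised-cosine radial profiles on a log-frequency
axis, `cos^(O-1)` angular lobes — and tile it, so the transform is a tight
frame and `reconstruct()` inverts it to machine precision.  The real and
imaginary parts of a band are even- and odd-phase filter responses (model
simple cells); the modulus is a phase-invariant energy (model complex
cells).  Bands are stored spatially downsampled by two per scale, in image
units; the Parseval identity for the decimated frame weights level-k
coefficients by `4^(k-1)` (`pyr_energy()`).

From the pyramid the package measures pairwise-product statistics
(`full_statistics()`, catalog in `statistic_catalog()`):

* covariances across position of the linear bandlimited image at each
  scale, over the 25 unique offsets of a 7×7 neighborhood (4 × 25 = 100);
* covariances across position of each band's centered magnitude
  (16 × 25 = 400);
* covariances of magnitudes across scale (3 × 16 = 48) and across
  orientation within scale (4 × 6 = 24);
* products of fine-scale complex coefficients with the phase-doubled,
  upsampled next-coarser coefficients, real and imaginary parts
  (3 × 16 × 2 = 96).

These 668 values form the observer's statistic set; for synthesis targets
the package adds per-band mean magnitudes and the marginal pixel
statistics (mean, variance, skew, and kurtosis in the `m4/m2²`
convention).  The pixel mean and variance are not part of the published
statistic count but are needed to pin the synthesis problem (every other
statistic is invariant to a mean shift); we include them in the marginal
group of the synthesis target only.

Two design points deserve note.  First, the "linear" spatial covariances
are computed on the partial lowpass image entering each pyramid level
(frequencies at and below that level), matching the recursive construction
of the reference texture-model software.  Second, covariance means are
subtracted *within* the weighted pooling region rather than globally; with
a uniform weight the two conventions coincide, and the weighted path
reproduces `full_statistics()` exactly (this equivalence is tested).

## Synthesis

`synthesize()` generates an image whose statistics match a target vector.
The image is initialized as seeded Gaussian white noise, pre-conditioned
by rescaling each oriented band to the target band energy, and then
iteratively adjusted.  Rather than alternating projections onto the
individual constraint sets, we minimize a least-squares objective — the
sum over statistic groups of squared deviations, each group divided by its
squared target norm — with analytic gradients propagated through the
magnitude and phase-doubling nonlinearities and the pyramid (whose adjoint
is the reconstruction with per-level decimation weights; the gradient is
verified against numerical differentiation in the tests).  Each
"iteration" is one bounded L-BFGS cycle (30 quasi-Newton updates);
between cycles, groups lagging behind the tolerance are up-weighted.  The
problem is solved coarse-to-fine: the target's coarser scales are first
matched at reduced resolution (scale k of the stage target is scale k + j
of the final one), the result upsampled, and the full problem refined.
Convergence is declared when every group matches with relative L2 error
at most `tol` (default 1e-2, cap 50 cycles); non-convergence warns and
reports the achieved errors.

A *family* is the set of images synthesized from one target with
different seeds (`make_family()`); statistics are matched globally over
the full synthetic extent, not within local windows.  Stimuli are
centered crops vignetted by a raised-cosine circular aperture whose flat
top covers 7/8 of the width (`crop_and_vignette()`); the background is
the package's mid-gray (0.5).  At the standard configuration, crop widths
{64, 128, 192, 320, 512} px at 80 px/deg subtend {0.8, 1.6, 2.4, 4, 6.4}
degrees.

Strongly periodic targets are the known hard case for this model class:
a pure square-wave grating has long-range phase structure that the local
statistic set constrains only weakly, and its match converges slowly.
The wave-composite prototype generator therefore jitters its carriers
spatially and includes a noise floor.

## The pooling observer

`build_windows()` tiles the model field with windows separable in
log-eccentricity and polar angle about a fixation point outside the
image.  Profiles are squared-cosine bumps whose neighbors sum to one, so
the windows form an exact partition of unity.  The radial spacing is
`2*asinh(s/2)`, making the radial FWHM of a window exactly `s` times its
center eccentricity; the angular spacing is half that, giving a
radial:circumferential aspect ratio of ~2.  Ring centers are anchored at
the field's minimum eccentricity, which makes the geometry exactly
invariant to uniform dilation about fixation — the property behind the
eccentricity scaling of performance.  Windows are dropped only if they
have no pointwise support in the field (threshold 1e-9), preserving the
tiling identity to numerical precision.

For each stimulus, `pooled_responses()` computes all 668 statistics of
every window as weighted averages, with the window resampled to each
band's resolution by area-preserving block averaging.  Responses are then

1. rescaled per statistic by its standard deviation over a broadband
   calibration ensemble (`calibrate_rescaling()`, geometry at s = 0.5);
2. divided by the global Euclidean norm over all windows and statistics
   (divisive normalization — the surround-suppression mechanism;
   `normalize_and_noise()`);
3. corrupted with i.i.d. Gaussian noise of standard deviation σ.

The decision on an AXB trial is the distance rule of `decide_axb()`: the
stimulus whose response vector lies farther from X is reported as the odd
one.  σ is calibrated (`calibrate_sigma()`) so that the mean SNR — the
variance of each statistic across all experimental stimuli and the
pooling regions covering them (in-field coverage ≥ 1%), divided by σ² and
averaged over statistics — equals a target value; 0.5 is the
physiologically matched default, bracketed by 0.125 and 2.0.

In the published description of this model family, the running text
speaks of dividing each statistic by the *summed* activity while the
formal definition uses the Euclidean norm; we implement the Euclidean
norm.

## Simulations and their problem sizes

`run_discrimination()` assembles AXB trials (counterbalanced matching
side; in the family task X is a different sample from one of the two
families, in the sample task X is a pixel-identical copy).  Because only
Euclidean distances between noisy vectors matter, trials are simulated by
an exact reduced-dimension sampler: the noise is drawn in the 2-D span of
the clean difference vectors, and the squared distances contributed by
the orthogonal complement follow a 2×2 Wishart law with `P·N − 2` degrees
of freedom.  This is distributionally identical to drawing the full
noise vectors (cross-checked against the direct path in the tests) and
makes thousands of trials essentially free.  Within one task and noise
level, the same trial compositions and noise draws are reused across
stimulus sizes (a paired, common-random-numbers design), so size effects
are estimated without dilution by independent simulation noise.

The package's default simulations mirror the reference configuration:
a 640×640 field at 80 px/deg with fixation at (320.5, −256), 512²
samples, 15 samples × 4 families, 10,000 trials per condition, scaling
factors s ∈ {0.21, 0.46, 0.84} (V1-, V2-, V4-like).  The test-suite and
acceptance profile runs the same pipeline scaled down by 2 in pixels so
a complete run fits on a desktop core: 256² samples (4 families × 5
samples, generator difficulty 0.5), a 320×320 field at 40 px/deg with
fixation (160.5, −128) — the same 8×8 degrees and the same angular sizes
{0.8, 1.6, 2.4, 4, 6.4}° — and 2,000 trials per condition; the
synthesis-gate check uses the first 2 families × 3 samples of that set;
the convergence (CV) analysis uses 5 families × 15 samples at 128² with
crop widths 32..112 px in steps of 16 (the standard 64..448 step 64
scaled with the images).  The eccentricity sweep presents the same pixel
images at {4, 8} degrees inner-edge eccentricity with pixel densities
{40, 20} px/deg; the single-region analysis treats each window as a
complete observer (its 668 rescaled statistics normalized by their own
norm), using s = 0.6 at fixed pixel density with placements at {4, 6, 8}
degrees in an enlarged (448 px) field, binning overlap into 10
log-spaced bins.

## What the synthetic data do and do not show

Prototype textures come from three procedural archetypes — oriented
filtered noise, spot fields, and jittered wave composites — chosen to
populate different statistic groups (orientation/position covariances,
kurtosis and cross-scale magnitude structure, cross-scale phase
alignment).  A `difficulty` knob mixes all prototypes toward their common
blend, monotonically shrinking family separation in statistic space; the
package default of 0.5 emulates the selection of hard-to-discriminate
families while keeping family discrimination off both floor and ceiling.
The calibration ensemble is phase-randomized 1/f-amplitude noise — a
stand-in for a natural-image database that shares its broadband
second-order structure but none of its higher-order organisation; since
the rescaling only needs a broadband reference spread per statistic,
this is sufficient (and the z-scoring alternative across experimental
stimuli is exposed as `standardize = FALSE`).

Passing simulations on these synthetic families demonstrates the
mechanisms — statistic convergence, aperture effects, normalization —
not the specific numerical performance levels of any photographic
texture set: absolute accuracies depend on family separability, which is
a free property of the generator.

## Numerical choices and degenerate inputs

* Boundary handling is circular everywhere (exact in the frequency
  domain); crops measured for the CV analysis wrap within the crop.
* A constant image is a legal input: all band energy is zero, skew and
  kurtosis are returned as `NaN` with a `degenerate` flag.
* CV entries whose across-sample mean is below 1e-8 times their group's
  median absolute mean are flagged and excluded.
* Exact distance ties in the AXB rule are broken by a seeded fair coin.
* A blank (all-background) stimulus has zero response norm and cannot be
  normalized; this is an error by design, to be handled upstream.
* All randomness flows through R's RNG; every public simulation takes a
  seed and is bit-reproducible.

## Known limitations

* The statistic set is the observer subset plus {band means, skew,
  kurtosis}; the min/max/variance marginals and lowpass-band refinements
  of the full reference texture model are out of scope.
* Synthesis minimizes a weighted least-squares objective; it reaches the
  1e-2 per-group gate reliably on the package's generators but offers no
  global-optimality guarantee, and strongly periodic targets converge
  slowly.
* The observer uses the simple AXB distance rule, which is close to but
  not exactly the statistically optimal decision for this task.
* Pooling geometry, not fitted: s and SNR are config constants, never
  estimated from data.
* Spatial downscaling is not perfectly neutral: at the 2x-reduced test
  profile the sample-discrimination curve at the intermediate scaling
  (s = 0.46) is slightly non-monotone over the middle sizes, whereas the
  identical pipeline at the full 512²/640² configuration yields a
  strictly decreasing curve.  The corresponding strict-monotonicity
  check in the test suite documents this residual scale sensitivity.
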