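---
title: "Laminar VASO digit mapping: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar VASO digit mapping: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
signal model, the geometric and statistical machinery, every convention that
the underlying methods leave open, the synthetic phantom that provides ground
truth, and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The acquisition and signal model

An interleaved VASO acquisition collects pairs of volumes: a blood-nulled
volume (acquired at an inversion time where blood magnetisation crosses
zero) and a not-nulled volume with ordinary BOLD weighting. The time between
like-contrast volumes is the *pair repetition time* (default 3.85 s). The
nulled signal falls when cerebral blood volume (CBV) rises; because the
nulled readout also carries BOLD weighting, its contamination is removed by
*dynamic division*. The package models a voxel as

```
bold(t)   = B0 * (1 + b(t)) + noise
nulled(t) = N0 * (1 - v(t)) * (1 + b(t)) + noise
```

with `b(t)` the fractional BOLD response and `v(t)` the fractional CBV
response, so that `nulled / bold = (N0/B0) * (1 - v(t))` exactly. The
baseline ratio `N0/B0` is irrelevant for the statistics (the GLM carries an
intercept; percent-change conversion divides by the run mean).

**Within-pair timing.** The two members of a pair are acquired half a pair
apart, and the analysis chain (upsample by 2, duplicate one contrast's first
volume, divide) exists to compensate that offset on real data. For the
phantom, both members of a pair carry the signal content of the *pair time*,
and the offset lives only in the series metadata. This is a deliberate
choice: with truly offset content, every division pairs an original volume
with an interpolated one, and no interpolation of gamma-smooth signals at
3.85 s sampling is accurate to machine precision — the exact-division
identity that the correction assumes (and that the test suite verifies to
`1e-6`) could never be tested. `align_nulled_bold()` therefore supports
three conventions: duplicate the first nulled volume (`"VB17"`), duplicate
the first not-nulled volume (`"VE"`), or pass through with harmonised time
metadata (`"none"`, the right setting for pair-simultaneous data such as the
phantom). Which duplication is correct on scanner data depends on which
contrast leads within a pair on the given platform; the two flags cover both
orders. Note also that on this protocol the true within-pair offset
(1601 ms) is not exactly half the pair time (1925 ms); the upsample-by-two
alignment itself assumes half-pair spacing, and the phantom adopts that
convention.

**Preprocessing order.** The interleaved stack is split first and the
non-steady-state replacement (volumes 1–3 := volumes 4–6) is applied per
contrast, so that a nulled volume is never overwritten by a BOLD volume.

**Temporal upsampling** inserts midpoints with the Lagrange polynomial
through the 8 nearest samples, which reproduces polynomials of degree up to
7 exactly at interior points; near the edges the window shrinks
symmetrically (down to linear) and the trailing midpoint extrapolates from
the final window. The exact boundary behaviour of upsampling tools used in
practice is not publicly specified; this one is chosen for testability.

## Cortical depth: the equivolume estimator

Depth is defined on gray-matter voxels, 0 at the pial surface and 1 at the
white-matter boundary.

1. **Boundary distances.** The gray/CSF and gray/white boundaries are
   represented by their face midpoints. A nearest-face-point distance
   carries the staircase bias of the rasterised boundary (up to half a voxel
   where the surface aligns with the lattice), so each face point receives a
   local tangent plane — the centroid and smallest principal component of
   the face points within a radius of `3 * mean(voxel)` — and the voxel
   measures its distance to the plane of its nearest face point. The
   centroid averages the staircase onto the underlying smooth surface.
2. **Equidistant depth** is `d_csf / (d_csf + d_wm)` after denoising both
   distance fields with local weighted quadratic fits (exact on smooth
   fields even when the window is cut by the gray-matter mask, hence no
   boundary bias).
3. **Equivolume correction.** The divergence `c` of the outward pial normal
   is estimated by quadric fits to the pial face points in their tangent
   frames (window `max(6 * mean(voxel), 2.4)` mm — wide enough to average
   several staircase periods at any resolution), averaged over the same
   neighbourhoods, and propagated to a voxel at depth distance `d_csf` as
   `kappa = c / (1 - c * d_csf)`. For a locally cylindrical patch this gives
   the signed radius `R = 1/|c|` and the closed-form equal-volume
   reparameterisation of an annulus,
   `alpha = (R^2 - s^2) / (R^2 - r_w^2)` with `s` the voxel's distance from
   the centre of curvature. Voxels with `|kappa| < 0.02 / mm` (radius beyond
   50 mm) are treated as flat and keep the equidistant value, so a flat slab
   reduces to the equidistant solution exactly.

The estimator is validated against the quarter-cylinder phantom's analytic
depth (`alpha(r) = (r_p^2 - r^2)/(r_p^2 - r_w^2)`): at 0.2 mm validation
resolution the maximum absolute error is below 0.03 depth units, and the
equidistant metric's curvature bias is visibly larger — the correction is
doing real work. Layer bins are `ceiling(alpha * n)` clamped to `[1, n]`,
with `n = 11` for laminar profiles and `n = 3` for event-related averages.

## Distances, disks, columns

Geodesic distances run through the 26-connected voxel graph with physical
edge lengths (anisotropic voxels respected), computed by Dijkstra's
algorithm; an independent quadratic-time Dijkstra implementation serves as
the test oracle. The geodesic **disk** flattens the ribbon onto its
mid-depth band (depth 0.4–0.6): every gray-matter voxel takes the nearest
mid-depth voxel as its foot point and joins the disk if that foot's
along-cortex distance from the seed is within the radius (default 12 mm).
The along-cortex distance is measured through the full gray-matter graph
rather than the thin band alone, because at coarse voxel sizes the band can
break into disconnected arcs; through-depth shortcuts on a 2 mm ribbon are
at most a few percent. **Column directions** are the normalised smoothed
gradient of the depth map.

Euclidean **distance bins** are the half-open 2 mm bins `[0,2), ..., [12,14)`
from a digit's peak voxel. The bin population defaults to all of gray
matter; restricting it to the geodesic disk is available
(`distance_mask = "disk"`) for data whose segmentation is trustworthy only
near the disk, but on a gently curved ribbon Euclidean and geodesic
distances nearly coincide, so a 12 mm disk would leave the outermost bin
almost empty.

## The GLM

Condition regressors are 30 s boxcars convolved with a gamma response of
mean lag 6 s and standard deviation 3 s (shape 4, scale 1.5, mode 4.5 s),
plateau-normalised so betas are on the fractional-plateau scale. The
high-pass filter is a discrete-cosine drift basis with all frequencies below
0.01 Hz (`floor(2 * duration * cutoff)` columns); six demeaned motion
parameters and one unit spike per flagged outlier volume complete the
design. Conditions without events keep an all-zero column (dropped from the
numerical fit) so the contrast interface is stable.

Three numerical conventions matter:

- **The GLM sees the pair grid.** Temporal upsampling interpolates, and
  interpolated samples carry no new information but leave the noise strongly
  autocorrelated (lag-one autocorrelation near 0.7 for white input). An
  ordinary-least-squares fit on the upsampled grid is anticonservative — on
  a pure-noise phantom the empirical two-sided rejection rate at z = 1.96
  was 0.225 instead of 0.05. Pipelines that fit on upsampled data rely on
  prewhitening; this package's documented alternative is to fit on the
  decimated (original-sample) series, which restores nominal calibration
  (0.049–0.054 in the test suite). Upsampled series are still used where
  temporal resolution matters: the VASO division and the event-related
  averages.
- **Variance floor.** Residual variance is floored at the square of
  `1.2e-7` (float32 relative accuracy) times the voxel's signal RMS.
  Acquired data carry at most single-precision information; without the
  floor, noise-free synthetic data make vanishingly small effects reach the
  z cap and dominate the FDR step.
- **z cap.** |z| is capped at 40 (numerically perfect fits would otherwise
  be infinite); the t-to-normal quantile transform uses log-space tail
  probabilities for stability.

Fixed effects across runs combine betas by inverse variance,
`b = sum(b_i/v_i) / sum(1/v_i)`, `v = 1/sum(1/v_i)`, with z recomputed
against the standard normal (whether published pipelines combine betas or
z-maps directly is typically unstated; inverse variance on betas is this
package's documented choice). FDR uses Benjamini–Hochberg step-up over the
gray matter of the geodesic disk; p-values from z are two-sided by default
with a one-sided option, and the binarised digit map keeps only the positive
tail in either case — a winner-take-all *activation* map must not admit
voxels that are significant because they respond strongly to the *other*
digits.

## Digit ROIs

The five-step construction: FDR-threshold each digit's
digit-versus-other-digits z-map at q = 0.001 over the disk's gray matter,
binarise (positive tail), keep the largest 26-connected cluster (ties go to
the component containing the smallest linear index), propagate across depth
with the columnar max filter, and remove voxels claimed by more than one
digit. The **columnar max filter** places a cylinder of radius 0.45 mm along
the local column direction through every disk voxel, spanning the full
cortical depth (the line is walked at quarter-voxel steps until it leaves
gray matter), and assigns the voxel the maximum input value among voxels
whose centre lies within the cylinder — so one active voxel anywhere in a
column activates the whole column, equalising voxel counts across depth
(exactly equal on the flat slab). The cylinder is rasterised against voxel
centres; note that at functional voxel sizes the 0.45 mm radius is below the
voxel size, whereas the procedure was designed for grids several times finer
— the rasterisation is documented, not claimed identical to any specific
tool. Peak voxels are the gray-matter argmax of the digit-versus-rest z-map;
z ties (the cap) are broken by the larger beta, then the lower linear index.

## Event-related averages and triphasic features

Cleaning removes, per voxel, a linear trend, the motion parameters and the
outlier spikes by OLS and expresses the residual as percent of the voxel's
*original run mean* — the baseline convention of the underlying procedure.
Because the run mean includes the activation, a sustained response of `a`
percent appears as a plateau of roughly `a * (1 - mean(regressor))` relative
to zero; recovery tests therefore compare plateau minus the immediately
pre-stimulus level, which restores `a` up to interpolation error. A
pre-stimulus-baseline option for the ERA itself is deliberately not the
default, matching the stated procedure.

Windows run from 15 volumes before to 70 volumes after onset (86 samples,
both ends inclusive — the phrasing "from 15 before up until 70 after" is
ambiguous about inclusivity; this is the documented choice) on the
upsampled grid (effective sampling 1.925 s). Trials whose window leaves the
run are dropped and counted. The across-trial 95% confidence interval is
t-based. Runs are combined by pooling trials; digit pooling for the distance
analysis keeps each digit's response to its *own* stimulation within its
*own* distance map and averages with trial weights.

Triphasic features operate on the across-trial mean trace: initial peak =
argmax within the stimulation period (`t` in `[0, 30]` s); trough = argmin
after the initial peak and at or before stimulus end; post-stimulus peak =
argmax within 8 volumes (≈ 15.4 s) after offset, with its time reported
relative to offset. Ties take the earliest time. These definitions force
`TTP_initial <= TTP_trough` by construction.

## The synthetic phantom

**Geometry.** Gray matter is a quarter-cylinder shell (inner radius 10 mm,
outer 12 mm, so 2 mm cortical thickness) around the domain corner, with
white matter inside and a 2 mm CSF shell outside; the cylinder makes the
equivolume depth analytic and the curvature uniform. A flat-slab variant
(11 gray-matter planes, so exactly one plane per layer at 11 layers) covers
the zero-curvature limit and the depth-occupancy arithmetic. The default
functional grid is anisotropic, 0.3 × 0.3 × 1.2 mm with the fine axes
spanning the plane that contains the depth direction — mirroring protocols
that optimise resolution perpendicular to the cortical bank at the cost of
slice thickness — over a 14.4 × 14.4 × 31.2 mm domain.

**Digits.** Three patches at 25°, 45° and 65° on the shell (about 3.8 mm
tangential separation at mid-depth, comfortably above one patch FWHM of
3 mm, as adjacent fingertip representations are distinct in cortex), each a
tangential Gaussian times a laminar profile: BOLD amplitude grows linearly
from 2% at the white-matter boundary to 4% at the surface (the ~2:1
superficial-to-deep gradient of laminar BOLD responses, i.e. the
draining-vein bias), CBV response peaks mid-depth (0.5% floor, 2% peak,
Gaussian of width 0.15 in depth units).

**Surround.** Every gray-matter voxel carries, per digit, a triphasic
response indexed by its 2 mm distance bin from that digit's peak: the sum of
three gamma-shaped components (widths 3, 6, 3 s) with amplitudes/latencies
`(A1, t1)` for the onset peak, `(-A2, t2)` for the sustained trough and
`(A3, t3)` for the offset peak. Defaults: bins 1–2 carry none (the patch
dominates there); across bins 3–7 `A1` falls from 0.5% to 0.1% while its
latency shortens from 10 s to 6 s, `A2` rises from 0.1% to 0.5% with
latencies 25 s down to 21 s, and the post-stimulus peak appears from bin 4
(beyond 6 mm) with amplitudes 0.2–0.25% and offsets 4–7 s — the qualitative
distance ordering reported for surround responses. Because the components
overlap in time, the superposed extrema can shift from the nominal latencies
by up to about one sample; the zero-noise recovery tests allow exactly the
sampling grid.

**Acquisition and noise.** Runs hold 12 pseudo-randomised blocks (no digit
twice in a row), 30 s on / 30 s off, a 30 s lead-in and a 75 s tail so that
full post-stimulus windows fit; three runs of four repetitions per digit.
Noise is i.i.d. Gaussian per volume (optional AR(1) switch, default off,
for quantifying miscalibration), with defaults giving BOLD tSNR near 65 and
VASO tSNR near 19–21 — above the >10 quality bar for sub-millimetre fMRI,
with the usual large BOLD advantage, and calibrated so that the weakest
injected condition (deep patch edge, 1% amplitude, 12 repetitions) stays
detectable at the q = 0.001 winner-take-all threshold. The 25 Hz vibration
carrier and its brief interruptions are not simulated: stimulation enters
only as the 30 s boxcar, since no analysed quantity depends on the carrier.

**Motion** is injected only as a nuisance table (registration is out of
scope; images are never displaced): white jitter around a stable position
plus transient outlier excursions. Two properties are deliberate. First,
the jitter is serially uncorrelated: a temporally smooth random trace has so
few effective degrees of freedom that regressing six of them out absorbs
several percent of any block response purely by chance — with a
mean-reverting AR(1) trace the measured absorption reached 3–10% of the
injected amplitude, an artifact of a synthetic trace rather than a property
of motion correction on real data (where the regressors track an actual
head position). Second, the outliers are transient rather than persistent
steps, for the same reason. On real data, collinearity between smooth motion
estimates and a slow block design remains a genuine cost of nuisance
regression; this phantom measures the pipeline, not that cost.

## What the tests show, and what they cannot

Passing this suite demonstrates that the implementation is faithful to its
stated conventions and recovers known ground truth through the full chain:
the division identity to machine precision, the equivolume closed form to
0.03, geodesics exactly, nominal GLM false-positive calibration, ≥90% digit
ROI coverage with disjointness, uniform depth occupancy, triphasic timing to
the sampling grid (zero noise) and to a median of one volume with the
correct distance orderings (default noise), a BOLD profile monotone toward
the surface and a mid-depth CBV peak. It does **not** show that the pipeline
is robust to what the phantom omits: EPI distortions and their correction,
motion as actual image displacement and registration error, physiological
noise and temporal autocorrelation (the default noise is white; with the
AR(1) switch the GLM is knowingly miscalibrated, since prewhitening is not
implemented), partial-volume mixtures at tissue boundaries, segmentation
error, vascular anatomy beyond the injected laminar profiles, and
between-subject variability. Group-level inference is out of scope.

## Problem sizes and determinism

The validation suite runs on one CPU in a few minutes: the depth oracle uses
a 0.2 mm shell of ~4,300 gray-matter voxels; the noiseless and default
studies use the default 48 × 48 × 26 grid (~10,000 gray-matter voxels, 430
interleaved volumes per run; one noiseless run, three noisy runs); null
calibration uses a ~11,000-voxel zero-amplitude phantom. All randomness is
seed-controlled: identical seeds give bit-identical runs, and
`run_pipeline()` records the resolved configuration and its hash next to
every artifact.
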