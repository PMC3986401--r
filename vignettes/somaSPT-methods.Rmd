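---
title: "somaSPT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somaSPT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaSPT)
```

# The measurement problem

Quantum-dot (QD) probes conjugated to a ligand let a microscope follow
single ligand-receptor complexes — for example BDNF bound to its TrkB
receptor — for minutes inside the soma of a live neuron. The raw data are
EMCCD movies at 9 or 18 frames/s with 127 nm pixels (live imaging at a
fixed focal plane) and two-channel z-stacks with a 300 nm step (fixed
cells; one channel images the QDs, the other a fluorescent membrane label
such as WGA). Four quantitative tasks stand between those images and
biology:

* find and localize each QD to well below the pixel size;
* decide, in 3D, whether a QD sits on the plasma membrane or inside the
  cell;
* connect per-frame localizations into trajectories despite QD blinking;
* summarize each trajectory's motion: diffusion coefficients, transport
  speeds, confinement, and motion phases.

This vignette documents the models behind each stage, the tunable
parameters, and the choices made where the method leaves room.

# Image formation model and calibration

All fitting assumes the camera mapping `ADU = gain × photons + offset`
with Poisson-distributed photons. `calibrateFrame()` inverts it
elementwise. Read noise is supported in the simulator (`readNoiseSD`) but
off by default, because the maximum-likelihood fitter models pure Poisson
counts; with modern EMCCDs at high gain the excess noise is
well-approximated by the Poisson branch.

The PSF is an integrated 2D Gaussian: the expected count in pixel *k* is

$$\mu_k = b + N \int_{\text{pixel } k} G(x - x_0, y - y_0;\ \sigma)\,dA .$$

**Coordinate convention.** Pixels are indexed 0-based; the center of pixel
(row *r*, col *c*) is at ((c + 0.5)·p, (r + 0.5)·p) with *p* the pixel
size; all user-facing positions are in micrometres.

# Detection and localization

`findCandidates()` band-passes each calibrated frame with a difference of
Gaussians (defaults σ = 1.0 / 2.0 px) and takes strict local maxima above
a threshold (default 4 × the robust MAD of the filtered frame — a
data-driven floor that adapts to background level). Candidates closer than
one ROI width keep only the brighter member, ties broken by lower row then
column.

`fitSpotMLE()` maximizes the Poisson log-likelihood
$\sum_k d_k \ln \mu_k - \mu_k$ over $(x_0, y_0, N, b)$ by coordinate-wise
Newton ascent on a 7×7 px ROI, capped at 30 iterations, declaring
convergence when the position update falls below 1e−4 px. The PSF width is
fixed (default 1.2 px) with a free-σ variant available
(`fitSigma = TRUE`). The localization uncertainty is the Cramér-Rao lower
bound from the Fisher information of the same model; Monte-Carlo tests in
the suite confirm the empirical spread of the estimator tracks the CRLB
within 20% at the default SNR.

Fit quality is tested by the log-likelihood ratio against the saturated
model, $\Lambda = 2(\mathrm{LL}_{sat} - \mathrm{LL}_{fit})$, compared to
χ² with (n_pixels − 4) degrees of freedom. A fit is accepted when its
photon count reaches `intensityMin` (default 100) *and* the χ² upper-tail
p-value is ≥ `llrPvalueMax` (default 1e−3); two overlapping spots fit as
one produce a large Λ and are rejected.

`localizeRadialSymmetry()` implements the gradient-line least-squares
center: intensity gradients are computed on the half-pixel grid by
diagonal differences, smoothed 3×3, and the center is the point minimizing
the gradient-magnitude-weighted perpendicular distance to the line through
each grid point along its gradient. It is non-iterative, fit-free, and
reaches ~8 nm RMSE at the reference SNR — comfortably below the 50 nm
target resolution. It is the localizer used in z-stack analysis, where
thousands of per-plane fits are needed.

# Membrane segmentation and 3D classification

`segmentMembrane()` computes, per z-plane, a phase congruency map from a
log-Gabor filter bank (3 scales, 6 orientations, minimum wavelength 4 px,
bandwidth σ_onf = 0.55, Rayleigh noise compensation with k = 2). Phase
congruency marks loci where Fourier components agree in phase and is
normalized by local amplitude, so the segmentation is invariant to affine
rescaling of staining intensity — verified in the suite to < 0.1 px
contour shift under doubling. The PC map is binarized by Otsu's threshold,
intersected with an intensity mask, the largest connected component is
closed (EBImage hole filling) and its boundary traced; each boundary
vertex is then refined along the local normal to the crest of the
(smoothed, locally background-subtracted) intensity ridge, in two passes
with light along-chain smoothing. The crest refinement uses the intensity
ridge rather than the PC map because the PC response is slightly
asymmetric around curved ridges, which would bias a centroid refinement;
the intensity profile of a thin membrane is symmetric about its crest.
A contrast-normalized gradient-magnitude fallback
(`method = "gradient_ridge"`) is provided and recorded in the output.

`linkZ()` groups per-plane localizations that fall on the same XY pixel
across planes. Because sub-pixel jitter straddles pixel edges, the default
accepts localizations within 1 px of the group's running mean pixel; the
literal same-pixel rule is kept as `tolerance = "strict"`. Planes need not
be contiguous (blinking), but a QD must be supported by ≥ 3 planes; its z
is the mean member-plane z, its xy the mean of member localizations.

`classifyLocation()` computes the signed Euclidean distance from each QD
to the nearest contour segment of the nearest z-plane (negative inside,
even-odd rule): membrane if |d| ≤ `dMem`, else internal/external.
`dMem` defaults to 0.25 µm (~2 px) — about the combined localization +
contour uncertainty; the method itself does not fix this value. Distances
use the single nearest plane rather than an interpolated 3D surface: with
a 300 nm z-step and near-vertical somatic membranes the difference is well
below `dMem`, and 3D surface rendering is visualization, not measurement.

# Trajectory linking

`linkTrajectories()` is a two-stage cost-matrix scheme. Stage 1 solves,
per consecutive frame pair, an exact rectangular assignment (augmented to
square with birth/death alternatives) with link cost = squared
displacement, links beyond `maxDisp` forbidden, and alternative cost
(1.05·`maxDisp`)². Stage 2 joins segment ends to later segment starts
across gaps of 1..`maxGap` frames, again by exact assignment, with the
displacement allowance growing linearly with the bridged interval.
Bridged frames are kept in the trajectory with linearly interpolated
positions and `gap = TRUE`; they carry no localization and are excluded
from MSD pairs. The assignment solver is a Jonker-Volgenant shortest
augmenting path implementation, exact rather than greedy; the suite checks
it against exhaustive enumeration.

`maxDisp` defaults to 0.64 µm/frame (5 px), sized for the fastest reported
transport (2.5 µm/s at 9 frames/s) with margin. For *free diffusion* at
D ≈ 0.3 µm²/s and 9 frames/s, ~4% of Brownian steps exceed 0.64 µm;
analyses of highly mobile membrane QDs should raise `maxDisp` to ~1 µm, as
the README example does. `maxGap` defaults to 5 frames, covering the large
majority of off-state excursions at typical QD duty cycles.

Correct linking is verified against simulator ground truth (trajectory
purity ≥ 0.98 with ≥ 2 µm spacing), replacing manual visual inspection of
trajectories with an automated check.

Two-channel registration (`alignChannels()`) maximizes the normalized
cross-correlation of sum projections with parabolic sub-pixel peak
interpolation, returning the rigid shift to apply to one channel.

# Dynamics

`computeMSD()` averages |r(i+k) − r(i)|² over all valid frame pairs, lags
up to ¼ of the trajectory length; the suite pins it to a brute-force O(N²)
oracle exactly. `fitMSD()` fits

* free diffusion: MSD = 4DΔt + c, weighted least squares, weights ∝
  number of pairs per lag;
* corralled diffusion: MSD = (L²/3)(1 − exp(−12DΔt/L²)) + c, bounded
  Levenberg-Marquardt (`minpack.lm`), where L is the corral side and the
  initial slope is 4D;

over the first min(10, N/4) lags, selecting by AIC with c ≥ 0, D ≥ 0,
L > 0 enforced. A ballistic alternative (v²Δt² + c) is scored as a
diagnostic only: when it clearly wins, the fit is flagged, guarding
against reading a diffusion coefficient off directed motion. A
non-convergent corral fit falls back to the free model with
`corralConverged = FALSE`.

`fitSmoothPath()` fits x(t) and y(t) by a second-order polynomial or a
cubic regression spline; the number of spline segments grows until the
residual RMS falls below twice the median localization uncertainty — a
smooth fit that does not truncate features. `pathPosition()` projects each
observation onto the densely sampled path (exact segment projection;
equidistant ties resolved toward the smaller arc length), and
`estimateSpeeds()` takes first-order-polynomial slopes of s(t) over
sections (default 2 s): positive speed is motion away from the path start.

`segmentPhases()` classifies rolling windows (default 2 s window, 0.5 s
step): *immobile* when the window's net displacement is below 3× the
localization σ; *directed* when the windowed speed ≥ `vMin` (default
0.2 µm/s, the slowest reported transport) and straightness (net / path
length) ≥ 0.8; otherwise *diffusive*. Straightness is computed on a
5-point coarse polyline over positions smoothed by a ~window/4 moving
average — otherwise localization noise dominates the step sum and slow
transport is misread as diffusion. Windows vote on the frames they cover;
contiguous same-kind runs become segments. These thresholds are this
package's own operational definitions; the phenomena they name are
otherwise described qualitatively.

`intensityTrace()` sums calibrated counts in a 6×6 px (~760 nm) window
around the (rounded) particle position, holding the last known position
through bridged gaps. `classifySingleQD()` thresholds the trace at the
midpoint of its two dominant modes (Otsu) and inspects the level
structure: a *single* QD shows clean two-level blinking (mode separation
≥ 4 within-state SDs) with at least one complete off excursion; *multiple*
co-located QDs betray themselves by a well-occupied intermediate level,
detected by re-splitting the sub- and supra-threshold populations
(recursive Otsu with a separation criterion). A Gaussian-mixture/BIC
approach was tried and rejected: with Poisson noise the level variances
grow with intensity, and BIC absorbs the rarely-visited all-off level into
a wide component, missing two-QD traces. A constant trace, having no off
excursion, is *indeterminate*.

# The synthetic-data generator

The simulator is a first-class, tested module, not a fixture. It emulates
exactly the statistical structure the analysis assumes:

* **motion**: Brownian steps with per-axis variance 2DΔt; directed motion
  advancing vΔt in arc length along a (possibly curved) path; confined
  Brownian motion reflected at a square corral of side L centred at the
  phase entry point; and immobility — composable into multi-phase
  trajectories with per-frame ground-truth labels. Motion is lateral
  (x, y) with z held fixed, matching fixed-focal-plane acquisition.
* **emission**: two-state Markov blinking (defaults pOff = 0.1,
  pOn = 0.5, i.e. a 5/6 duty cycle and mean off runs of 2 frames);
* **imaging**: integrated-Gaussian PSF (default σ = 1.2 px ≈ 152 nm,
  diffraction-limited for a red-emitting QD at NA 1.4), 800 signal
  photons/frame over 10 background photons/px — a budget at which the
  50 nm localization target is comfortably attainable — Poisson shot
  noise, camera gain/offset, optional Gaussian read noise;
* **cell geometry**: per-plane closed membrane contours (default a
  circular cylinder, radius 7-8 µm, 300 nm z-step), QDs placed either
  ≥ 0.5 µm inside the contour or within 0.1 µm of it, rendered across 5
  consecutive planes with a triangular axial intensity profile (no axial
  PSF model is claimed; 3-5 plane support with falloff is what the ≥ 3
  plane linking rule needs to be exercised), and a membrane channel
  rendering the contour as a Gaussian-profile ridge. QDs are placed with
  a minimum lateral separation (default 0.8 µm) since single-QD analysis
  presumes optically resolvable puncta.

What it does **not** emulate: realistic neuron morphology, spectral
crosstalk, chromatic aberration beyond a rigid shift, axial astigmatism,
EMCCD excess noise, z-drift, or QD spectral fluctuations. Passing tests
therefore demonstrate correctness of the *algorithms* under the stated
noise model, not robustness to every artifact of real acquisitions.

# Numerical choices and problem sizes

* Seeds: every stochastic operation accepts a seed; the pipeline derives
  per-stage child seeds from the run seed, and identical config + seed
  yields byte-identical outputs (tested).
* The MLE Newton steps are clamped to 1 px per iteration; non-converged
  fits are retained but flagged.
* The LLR χ² null uses dof = n_pixels − 4 (position, photons, background
  consume 4 of the 49 ROI degrees of freedom).
* Corral-fit starting values: L from the MSD plateau (L² ≈ 3·max MSD), D
  from the free-fit slope.
* Test and acceptance problem sizes were chosen to give stable statistics
  at interactive runtimes: 500 spots for localization RMSE, 20 × 1000
  frames for diffusion recovery, 35 s × 18 frames/s for the curvilinear
  run, 50 QDs per synthetic cell. Confined-motion recovery is exercised
  at micro-diffusion D = 0.05 µm²/s inside L = 0.5 µm so that the MSD
  rise is resolvable at 9 frames/s; at the membrane diffusion rate the
  curve saturates within a single lag and only the plateau is
  informative.

# Known limitations

* The detector assumes isolated emitters; overlapping QDs are rejected by
  the LLR filter rather than multi-emitter fit.
* Phase congruency segmentation expects one dominant closed cell section
  per plane (the largest component); touching cells are not separated.
* The corral model's D and L are strongly correlated when the corral is
  large relative to the observation window; interpret L only when the
  corralled model is selected and the plateau is sampled.
* Internalization fractions near 0 or 1 are granular with small QD
  counts (1/50 = 2 percentage points per QD).
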