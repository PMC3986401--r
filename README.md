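# somaSPT

Single-particle tracking (SPT) of quantum-dot (QD) labelled ligand-receptor
complexes in the cell body of live neurons. Bright, photostable QD probes
conjugated to a growth factor (e.g. BDNF binding its TrkB receptor) make it
possible to follow *individual* ligand-receptor complexes for minutes as
they diffuse on the plasma membrane, internalize, and are trafficked
through the soma. Extracting biology from such movies requires a chain of
quantitative steps — each implemented and tested here:

1. **Photon calibration** — EMCCD frames are converted to Poisson-scale
   counts, `counts = (ADU − offset) / gain`.
2. **Detection and sub-pixel localization** — difference-of-Gaussian
   candidate detection; each candidate ROI is fit by maximizing the Poisson
   likelihood of an integrated-Gaussian PSF model,
   `μ_k = bg + N · ∫_pixel G(x − x₀, y − y₀; σ)`,
   with the theoretical precision from the Cramér-Rao lower bound (Fisher
   information of the same model) and a χ² log-likelihood-ratio test that
   rejects fits not shaped like a single PSF. A radial-symmetry localizer
   (gradient-line least squares) provides fast, fit-free sub-pixel centers
   for z-stack work; both reach < 10 nm RMSE at typical QD photon budgets
   (800 signal photons over 10 background photons/px on 127 nm pixels).
3. **Membrane vs intracellular classification (3D)** — the membrane-label
   channel is segmented per z-plane by phase congruency (a log-Gabor filter
   bank edge measure that is invariant to staining intensity), refined to a
   sub-pixel contour; QD localizations are linked across z-planes (a QD
   must appear in ≥ 3 planes, tolerating blinking) and classified
   membrane / internal / external by signed distance to the contour.
4. **Trajectory linking** — frame-to-frame linking is solved as an exact
   linear assignment problem with squared-displacement costs and
   birth/death alternatives, followed by a second assignment that closes
   blinking gaps (up to `max_gap` frames).
5. **Dynamics** — per-trajectory mean square displacement,
   `MSD(Δt) = 4DΔt + c` (free diffusion) vs
   `MSD(Δt) = L²/3 · (1 − e^{−12DΔt/L²}) + c` (corralled diffusion),
   selected by AIC; smooth-path (spline) fits with arc-length positions
   `s(t)` and first-order-polynomial section speeds; rolling-window motion
   phase segmentation (directed / diffusive / immobile); QD blinking trace
   classification (single vs multiple emitters) from the on/off level
   structure of 6×6-px intensity traces.

A **synthetic-microscopy simulator** (Brownian / directed / confined /
stationary motion phases, two-state Markov blinking, integrated-Gaussian
PSF rendering with Poisson shot noise and camera gain/offset, and a
two-channel cell z-stack generator with ground truth) makes every stage
testable without experimental data.

## Worked example

Simulate a single blinking QD diffusing inside a corral at the
membrane-typical rate, then run detection, linking, and MSD analysis:

```r
library(somaSPT)
tr  <- simulateTrajectory(motionPhase("confined", 30, D = 0.29, L = 3),
                          dt = 1/9, origin = c(4, 4, 0), seed = 2)
sim <- renderMovie(tr, cameraModel(), psfModel(), blinkModel(),
                   imageShape = c(64, 64), seed = 2)
loc <- detectSpots(sim$movie)
trs <- linkTrajectories(loc, dt = 1/9, maxDisp = 1.0)
fitMSD(computeMSD(trs[[1]]))
evaluateAgainstTruth(list(localizations = loc, trajectories = trs), sim$truth)
```

Output:

```
MSDCurve: 66 lags (dt 0.1111 s), msd[1] = 0.1239 um^2
  fit: free model, D = 0.3268 um^2/s, offset 0 um^2
EvaluationReport
  detection: precision 1.000, recall 1.000
  localization RMSE: 7.4 nm
  trajectory purity: 1.000
```

All 237 on-state localizations (the QD is off ~1/6 of the time) are found
with no false positives, localized to 7.4 nm, and linked into one
trajectory across 30 bridged blinking gaps; the fitted diffusion
coefficient recovers the simulated mobility (a 3 µm corral barely curves
the first MSD lags, so the free model is selected).

The full pipeline — simulate → detect → track → analyze → evaluate, with
TIFF/CSV/JSON outputs — runs from a single YAML-configurable call:

```r
res <- runPipeline(runConfig(seed = 3, out_dir = "out"))       # live movie
res <- runPipeline(runConfig(seed = 5, out_dir = "out_z",
                             mode = "zstack"))                 # fixed cell
```

A thin command-line wrapper is provided in
`inst/scripts/run-pipeline.R`.

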