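---
title: "Mapping the hemodynamic landscape: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the hemodynamic landscape: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscape)
```

`hemoscape` analyzes co-registered 2D image time-series of microvascular
oxygen saturation (Hb_sat, %), blood volume (BV) and blood flow (BF),
acquired at roughly one frame per variable every 30 s over 30–60 minutes at
micrometer-scale pixels. This vignette is the package's own account of the
science: the models each module implements, the parameters that matter and
their defaults, the numerical conventions, what the synthetic scenes do and
do not emulate, and the design choices made where the design was open.

## The pre-processing chain

Every module consumes the same chain:

1. **Resampling** (`resample_to_common_grid()`): frames are averaged within
   per-minute bins `[t, t + 1)` so all variables share one regular base.
   Empty bins are treated as acquisition gaps and raise an error rather
   than being interpolated.
2. **Temporal running mean** (`temporal_mean_filter()`): a 5-minute boxcar
   stepped by 1 minute. Only fully covered windows are emitted — the
   arithmetic that turns a 60-minute series into exactly 56 points and a
   30-minute perturbation session into a 26-point series. We interpret the
   filter in "valid" mode (no zero padding) because that count is the only
   one consistent with a 56-point FFT on an hour of data. Output timestamps
   sit at window centers so that event timing (e.g. gas onset) is unbiased.
3. **Spatial block mean** (`block_average()`): non-overlapping
   50 × 50-pixel tiles (trailing partial tiles discarded), giving
   sub-region series resilient to the microscopic tissue motion typical of
   soft tissue beds. The tiling (rather than sliding) interpretation
   matches the discrete sub-region grid the analyses are defined on. Blocks
   with under 50% finite pixels are marked missing throughout.

Both filters are plain means, so they commute to floating-point tolerance;
the pipeline applies blocks first purely for economy. Coordinates follow
the image convention: origin at the top-left, `(row, col)` order, 1-based
indices as idiomatic in R.

Vasomotion for the cluster module is quantified as the fractional blood
volume change ΔBV/BV, computed as a forward difference
`(v[t+1] − v[t]) / v[t]` on the filtered per-minute base. The forward
(causal) difference is a convention choice — the ratio itself does not
dictate a differencing scheme — and is configurable.

## Module models and parameters

### Propagation

The hypoxic region at each filtered minute is the set of pixels with
Hb_sat strictly below the threshold (default **30%**). The tracked region
is the 4-connected component containing the user-chosen origin *O* (or the
component nearest *O* within `capture_radius_px`, default 25 px, when *O*
itself is transiently normoxic); its contour is the set of component pixels
with at least one 4-neighbor outside. The expansion profile along a
direction *O → A* reports, per minute, the farthest contour crossing of the
ray (so fingering fronts report their leading edge), converted to μm via
the pixel size (nominally 5 μm/px); speed is the forward difference in
μm/min. Two conventions matter:

* **Censoring at the field-of-view edge**: a ray crossing that lands on the
  image border measures the border, not the front, so that minute's
  distance is reported missing rather than biasing the speed toward zero.
* **Retreat is allowed**: negative speeds are reported, not clipped.

Sub-regions are zoned by their center pixel against the first and last
contours — CHRONIC inside the first, ACUTE newly engulfed, NORMOXIC outside
the last — and the −ΔBF / −ΔBV scatter uses windowed reductions
(early-window mean minus late-window mean, positive = decline), with the
first and last 5 filtered minutes as default windows since the averaging
windows behind this comparison are a free choice.

### Clustering

Niches are found per time window (default: the two halves of the run,
mirroring a 0–30 / 30–60 min split) from the ΔBV/BV series. The master
correlation matrix holds all pairwise Pearson correlations between
sub-regions. SVD of that matrix seeds the search: the retained rank K is
the smallest capturing 80% of squared singular-value energy (capped at 10),
each cell joins its largest-|loading| component, and components are split
by loading sign so vasodilating and vasoconstricting dynamics never start
in one group. Refinement then alternates: recompute centroids as
member-mean series; reassign each cell to its best centroid if r > 0.7
(ties to the lowest niche id, for determinism) else unassign it; dissolve
niches below ⌈5% of cells⌉; merge centroid pairs with r > 0.7. A final
enforcement sweep guarantees the returned labeling satisfies both printed
rules exactly — member-to-centroid r > 0.7 and the 5% size floor — with
centroids computed from the final membership. The correlation threshold
and size floor are the two noise controls; both live in `run_config()`.

### Coupling

Coupling is the Pearson correlation between BF and BV series per
sub-region, in two successive windows. Classification is strict:
r exactly at the threshold does not exceed it, so TIGHT requires r > 0.7
in both windows, POOR r < 0.7 in both, INTERMITTENT otherwise; cells with
a constant series in any window are MISSING. One shared threshold serves
both windows (it is user-selectable). Area fractions are reported over
non-missing cells and sum to 100%.

### Perturbation

The stimulus reference is the 0/1 inhalation boxcar sampled at the
acquisition cadence and passed through *the same* `temporal_mean_filter()`
call as the data — one code path, so the reference and data bases match by
construction. Responsiveness is strict and one-sided (r > 0.7; an
anti-correlated cell is not "responsive"). The response magnitude is
**stimulus minus baseline** — the sign convention under which a
carbogen-driven Hb_sat increase is positive, matching how such responses
are displayed — and samples within half a kernel of a state transition are
excluded from both means by default because the filtered boxcar has not
reached steady state there (configurable to use all samples).

### Fourier

Each sub-region series is normalized to fractional fluctuation about its
temporal mean, `y = x/mean(x) − 1`, before the FFT; 0 dB therefore means
fluctuation power equal to the squared mean level. This realization of
"dB relative to the mean level" (rather than referencing the DC bin of the
unnormalized transform) is a documented convention; the two are numerically
similar but not identical. One-sided powers are `P_k = 2|Y_k|²/N²`
(Nyquist bin not doubled), so a pure modulation of depth c carries
`c²/2` (−16.99 dB at c = 0.2) and the powers sum to var(y) (Parseval).
Band edges map periods to bins by `T_k = N·Δt/k` with inclusive bounds: at
N = 56, Δt = 1 min the low-frequency band (10–56 min) is bins 1–5 and the
high-frequency band (2–10 min) bins 6–28 — disjoint and jointly covering
all analyzable bins. Periods ≤ 1 min need no special handling: the
filtered Nyquist period is 2 min. No taper is applied by default (none is
part of the method); band powers at or below the noise floor (−60 dB
default) are omitted, and the H_f/L_f ratio is computed on linear powers.

## The synthetic scenes

`generate_scene()` builds ground-truth-bearing trials in the acquisition's
nominal geometry (5 μm pixels, 30-s cadence, 50 × 50 px blocks; the full
5 × 7 mm² field is 1000 × 1400 px, with smaller sizes used routinely for
speed). Planted structure per kind: a constant-speed expanding sub-30%
Hb_sat disc with co-localized BF/BV declines (WAVEFRONT, default
15 μm/min); three horizontal niche bands whose sinusoidal vasomotion
phases slide smoothly into one common profile at the merge time (NICHES,
default merge at 30 min, 10% modulation of a 100-unit baseline);
sub-region thirds with shared-latent, independent-latent, or
half-session-spliced BF/BV dynamics (COUPLING); boxcar responders under
the 10/10/10 paradigm (PERTURBATION, planted Δ at pixel signal-to-noise 3);
and per-sub-region sinusoids at chosen periods (SPECTRAL, modulation depth
0.2 at 28 and 4 min).

Two noise placements are used, and the distinction matters:

* **Pixel noise** (all scenes): independent Gaussian per pixel per frame.
  The wavefront analysis runs at pixel resolution and the perturbation
  scene states its SNR per pixel, so this is where their stated noise
  lives. Under 50 × 50 aggregation it attenuates ~50-fold.
* **Sub-region noise** (NICHES at 25% of signal SD, COUPLING at 20%):
  block-constant per frame, emulating the spatially correlated
  disturbances (motion, perfusion fluctuations) that survive block
  averaging. Stating these fractions at the sub-region scale keeps the
  clustering and coupling validations meaningful; purely per-pixel noise
  would make them vacuous.

For COUPLING, a planted category must be true of the realized series, not
merely of the drawing scheme — two independently drawn smooth signals can
correlate by chance over a 27-point window — so draws are rejected until
each cell's raw half-session correlations respect its label with margin
(coupled halves r ≥ 0.8, uncoupled |r| ≤ 0.4) around the 0.7 rule.

What the scenes do **not** emulate: vascular anatomy, oxygen transport
physics, spatially correlated noise beyond the block scale, motion
artifacts, registration error, or the conversion from raw optical frames
to hemodynamic maps (out of scope throughout). Passing recoveries
demonstrate that the pipelines measure what they claim under the stated
noise; they do not certify performance on real tissue.

## Numerical choices and degenerate inputs

* Pearson correlations with a zero-variance side are missing, never 0;
  a constant seed or reference raises a warning or error as appropriate.
* ΔBV/BV steps with nonpositive denominators are flagged missing, not
  thrown.
* Cluster tie-breaks (equal centroid correlation) go to the lowest niche
  id; refinement is capped at 100 iterations and the enforcement sweep at
  50 (all fixtures converge in a handful).
* Maps written as TIFF are float32 scaled to [0, 1] with the range in a
  JSON sidecar (the storage format's constraint); CSVs carry exact values.
* All randomness is seed-controlled; identical spec + seed reproduce
  bit-identical stacks and outputs.

## Validation problem sizes

The test-suite and acceptance runs validate at: 200 × 200 px over 60 min
(wavefront, 10 seeds), 300 × 500 px / 60 sub-regions (niches, coupling
across 10 seeds, spectral), and 200 × 200 px over 30 min (perturbation,
50 seeds) — sizes chosen to exercise full pipelines with comfortable
statistics while keeping a complete run in the low minutes on one CPU.

## Known limitations

* Contours are pixel-resolution (no sub-pixel interpolation) and
  propagation is strictly 2D.
* No lagged cross-correlation or transfer-function modeling of BF–BV
  coupling; no response-latency estimation or deconvolution in the
  perturbation module; no multitaper/wavelet spectral estimation.
* The cluster module's refinement loop is the package's concrete
  realization of SVD-seeded correlation clustering; alternative backends
  (k-means, ICA, spectral clustering) are deliberate non-goals of the core.
* With very small fields of view the 5% size floor can drop to one or two
  cells, at which point noise pairs can satisfy the membership rule;
  meaningful niche detection presumes a field of ~100 sub-regions or an
  accordingly raised `min_cluster_frac`.
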