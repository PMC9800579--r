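---
title: "Quantifying annexin-driven membrane-patch rolling"
author: "patchRoll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying annexin-driven membrane-patch rolling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchRoll)
```

## The system

Annexins are Ca^2+^-dependent phospholipid-binding proteins whose convex,
disc-shaped core domain bends a membrane on binding. When they bind one face
of a supported membrane patch with free edges — a secondary bilayer fragment
resting on a primary supported membrane — the asymmetric binding imposes a
spontaneous curvature $c_0$, and the patch rolls up from its free edges into
a tight spiral. Crosslinking annexins (A1, A2, A6) oppose rolling by gluing
the patch to the membrane underneath, which enters the energy balance as an
adhesion energy density $w_{ad}$. The competition between curvature
relaxation and adhesion decides whether a patch rolls completely, stalls
("incomplete rolling"), or — once maximally rolled — can unroll again.

patchRoll implements the four quantitative strands of this analysis:

1. **Rolling energetics** — a Helfrich spiral model for the equilibrium
   rolled length $L^*$ and its dependence on $w_{ad}$ and $c_0$.
2. **Rolling kinetics** — frame-differencing of time-lapse dye-channel
   stacks, logistic fits for the rolling time constant $\tau$ and onset
   time, relative-area traces of unrolling patches, edge line profiles,
   and Welch's $t$ comparisons between conditions.
3. **AFM lattice and domain analysis** — 2D-FFT period of the close-packed
   trimer crystals annexins form on supported bilayers, and area fractions
   of the two height domains a GFP label creates.
4. **Curvature mapping** — membrane midplane surfaces fitted to
   lipid-particle coordinates and their Monge-gauge mean curvature, averaged
   under a protein footprint.

A synthetic-data module generates every input modality with a ground-truth
record, so each stage is validated end to end without external data.

## The rolling-length model

The rolled patch is modelled as an Archimedean spiral
$r(\theta) = r_0 + \tfrac{b}{2\pi}\theta$ with pitch $b$ (the spacing
between successive membrane wraps) and inner radius $r_0$. Measuring the
rolled length $L$ as arclength from the inner end, the energy difference per
unit roll width between the rolled and flat states is

$$\Delta E(L) \;=\; \int_0^L \left[\; \frac{k_c}{2}\!\left(\Big(\frac{1}{r(s)} - c_0\Big)^{\!2} - c_0^2\right) \;+\; w_{ad} \right]\, \mathrm{d}s .$$

The first term is the Helfrich bending energy of membrane curved at
$c(s) = 1/r(s)$ relative to the flat state, which is frustrated at energy
density $(k_c/2)c_0^2$; the second is the adhesion energy the membrane
forfeits by detaching from the support. Because $1/r(s)$ decreases
monotonically along the spiral, the integrand crosses zero at most once from
below, so the energy-minimizing length is given by the marginal condition

$$\frac{k_c}{2}\left(c_0^2 - \Big(\frac{1}{r^*} - c_0\Big)^{\!2}\right) = w_{ad},$$

i.e. rolling stops at $1/r^* = c_0 - \sqrt{c_0^2 - 2 w_{ad}/k_c}$, and never
starts when $w_{ad} \ge (k_c/2)c_0^2$. `rolledLength()` evaluates this in
closed form; `energyProfile()` exposes the full $\Delta E(L)$ by quadrature,
and the test suite checks that the closed form coincides with brute-force
grid minimization of the profile across randomized parameter sets.

### Parameterization

```{r}
rollModelParams()
```

* $c_0 = 3.33\times 10^7\,\mathrm{m^{-1}}$ — the spontaneous curvature of an
  annexin-covered leaflet (spontaneous radius $1/c_0 \approx 30$ nm).
* $b = 2.1$ nm — the roll pitch, i.e. roughly a bilayer plus bound-protein
  spacing. `b` is interpreted as pitch per turn.
* $k_c$ — two values of the bending modulus are in circulation for this
  system; both ship as named presets, `"results"`
  ($1.0\times10^{-19}$ J, the default) and `"methods"`
  ($4.0\times10^{-20}$ J). Sweep landmarks below are reported for both.
* $w_{ad} = 1.0\times10^{-5}\,\mathrm{J/m^2}$ — the reference adhesion.
  Note that rolling requires $w_{ad} < (k_c/2)c_0^2 \approx
  5.5\times10^{-5}\,\mathrm{J/m^2}$; quoted adhesion values of order
  $10^{5}\,\mathrm{J/m^2}$ exceed every molecular bond-energy scale and
  would forbid rolling outright, so the package treats them as sign-typo
  artifacts and defaults to the $10^{-5}$ scale. The field is plainly
  configurable for users who disagree.
* $r_0 = 1/c_0$ by default: the innermost turn sits at the spontaneous
  radius, where its local curvature frustration vanishes. For the $c_0$
  sweep the convention `"follow_c0"` re-anchors $r_0$ to the reduced
  curvature; a fixed-$r_0$ convention is selectable.

The spiral arclength uses the exact closed form
$s(r) = \big[r\sqrt{r^2+a^2} + a^2\,\mathrm{asinh}(r/a)\big]/(2a)\big|_{r_0}^{r}$
with $a = b/2\pi$; the familiar thin-pitch approximation
$L \approx \pi(r^2 - r_0^2)/b$ is retained as a documented fast path and
agrees with the exact mapping to well below 1% at $b = 2.1$ nm.

### Sweeps and critical factors

Crosslinking by a second annexin is modelled as a multiplicative increase of
$w_{ad}$; displacement of the curvature-inducing annexin as a multiplicative
reduction of $c_0$. A rolled length at or below the optical resolution limit
(1 µm by default) reads out as "no rolling":

```{r}
sw <- sweepAdhesion(rollModelParams(), factors = seq(1, 10, by = 0.25))
criticalFactor(sw)
swc <- sweepSpontaneousCurvature(rollModelParams(),
                                 fractions = seq(0.25, 1, by = 0.01))
100 * (1 - criticalFactor(swc))   # percent reduction of c0
```

With the `"results"` preset the critical adhesion factor is ≈ 5.2 and the
critical $c_0$ reduction ≈ 57%; with `"methods"`, ≈ 2.1 and ≈ 32%. The
model form here is a reconstruction — the spiral geometry, the stopping
condition and the two parameter presets are the package's own normative
choices, with brute-force energy minimization as the oracle — so landmark
comparisons against published sweep figures should be read at factor-level
precision, not percent-level.

`criticalFactor` is refined by bisection between the two sweep points that
bracket the crossing, so the sweep grid only needs to straddle it.

## Rolling kinetics from image stacks

Rolling consumes patch area, so rolled membrane appears as intensity *loss*
in the membrane-dye channel. `incrementalRolledArea()` binarizes each frame
at a cutoff (Otsu's threshold of the first frame by default), median-filters
the binary patch masks, and counts the pixels lost between consecutive
frames; `fitLogistic()` fits

$$A \,/\, \big(1 + e^{-(t - t_0)/\tau}\big)$$

to the cumulative trace by Levenberg–Marquardt least squares, initialized
from trace quantiles ($A$ from the maximum, $t_0$ from the half-maximum
crossing, $\tau$ from the 20–80% rise time over 2.2).

Numerical choices worth knowing:

* **Binarize frames, then subtract.** Differencing noisy grayscale frames
  and thresholding the difference is fragile when the rolling front advances
  less than a pixel per frame: the per-frame loss is a fragmented, one-pixel
  arc that no spatial filter can separate from shot noise. Binarizing patch
  presence first concentrates the noise handling where it is safe — the
  patch mask is a large contiguous blob, so a 3×3 median removes isolated
  flickers without eroding anything — and leaves the thin mask difference
  exact.
* **Monotone masks.** Rolling is irreversible, so by default a pixel that
  leaves the patch mask stays out (`monotone = TRUE`); this prevents noise
  at the front from re-counting pixels and makes the cumulative trace an
  unbiased estimate of consumed area.
* **Onset time** is defined as the first time the cumulative area exceeds
  5% of the fitted amplitude (configurable), linearly interpolated between
  frames.
* **Fit failures are loud.** A flat trace or a non-convergent fit raises a
  `patchRoll_fitFailure` condition carrying diagnostics, never a silent
  default.
* A truncation bias is inherent to fitting a logistic to a record that
  starts near the onset: with the movie starting $\sim\!2\tau$ before
  $t_0$, the fitted $\tau$ sits about 2% low. Recovery tests therefore
  place the onset at $\ge 2\tau$ after the movie start, which is also the
  physically common regime.

`relativeAreaIncrease()` handles the unrolling assay (area relative to the
maximally rolled state over an 80 s window), `extractLineProfile()` the
edge-localization cross-sections (per-channel min–max normalization; a
channel whose maximum does not exceed twice its profile median is reported
as having *no* isolated peak — the signature of a protein that does not
enrich at the patch edge), and `welchT()` the unequal-variance comparisons
(a thin wrapper over `stats::t.test`, cross-checked in the tests against an
independently coded Welch–Satterthwaite formula).

## AFM lattice period and height domains

`latticePeriod()` plane-flattens the scan (per-scanline polynomial,
`planeFlatten()`), applies a Hann window, and locates the first-order
Bragg-like peak ring of the 2D power spectrum. The period is $2\pi/|q|$
averaged over all discrete first-order peaks — for a hexagonal trimer
packing this is the row (d-) spacing, with the lattice constant
$a = 2d/\sqrt{3}$ reported alongside. Peak acceptance is deliberately
strict: a peak must exceed the radially averaged background by 5 local MADs
*and* by a factor of 20 in power, because the spectral power of an
uncorrelated rough surface is exponentially distributed and its upper tail
alone defeats any pure-sigma criterion. Four discrete peaks set the
crystallinity flag; fewer than two leave the period `NA`. The search is
restricted to periods of 3–30 nm, the annexin-trimer scale. Peak positions
are refined by a power-weighted centroid, which keeps the period estimate
within one radial frequency bin across lattice rotations and tilted
backgrounds (tested at spacings of 6–12 nm and pixel sizes of 0.25–1 nm).

`segmentHeightDomains()` requires a bimodal height histogram — two kernel
density modes whose valley dips below 80% of the lower mode — and
thresholds at the midpoint of a two-component Gaussian fit (Otsu fallback).
Percent area fractions are reported over the analyzed (optionally masked)
pixels and sum to 100 exactly. Unimodal input raises a
`patchRoll_segmentationFailure` carrying the histogram.

## Midplane curvature from particle coordinates

`fitMidplane()` bins lipid particles into an x–y grid (periodic in x, y)
and takes each cell's midplane height as the midpoint of the two leaflet
means; empty cells are filled by periodic neighbour interpolation and
flagged, and a leaflet empty in more than 20% of cells is a resolution
error. `meanCurvatureField()` computes the Monge-gauge mean curvature

$$H = \frac{(1+z_x^2)\,z_{yy} - 2 z_x z_y z_{xy} + (1+z_y^2)\,z_{xx}}{2\,(1+z_x^2+z_y^2)^{3/2}}$$

with periodic central differences. The sign convention takes the normal
along $+z$ (the protein-bound side), so a membrane dimpling away from the
protein has $H < 0$. A periodic Gaussian smooth of one grid cell is applied
before differentiation by default — binning noise under a second-derivative
operator is severe — but is switched off in every validation against
analytic surfaces. `footprintMeanCurvature()` averages $H$ (signed; the
same aggregation of $|H|$ is also emitted) over an explicit footprint
region per frame and reports mean and SD across frames or replicas. The
region is supplied by the caller: inferring protein contacts from
coordinates is out of scope.

Desk-scale validation replaces trajectory-scale statistics: sphere caps
reproduce $|H| = 1/R$ within 2% for $R$ of 50–200 nm, a Gaussian dimple
matches its closed-form Monge curvature within 1% with smoothing off, and
replica aggregation is checked as exact arithmetic. Published per-protein
curvature numbers from microsecond trajectories cannot be regenerated at
this scale and are treated as context only.

## What the generators emulate — and what they do not

* `genRollingMovie()` renders a circular patch whose cumulative consumed
  area follows the logistic schedule, with fronts advancing inward as
  circular-arc erosions from edge seed points, a bright 2 px rim leading
  each front, and Gaussian noise (`noiseSigma` is the inverse SNR). $t_0$
  is placed so the 5%-of-$A$ crossing equals the requested onset. Defaults
  mirror a typical epifluorescence setting (0.32 µm/px, 10 fps, 512 px
  field; the tests use 128 px crops and coarser frame intervals to keep
  runtimes in seconds). Edge puckering and corrugation are not modelled —
  only areas and times carry information here.
* `genUnrollingMovie()` grows a disc linearly in area
  (`growth = 0` models a fully crosslinked, non-unrolling patch).
* `genAfmImage()` draws Gaussian bumps on a hexagonal lattice of the
  requested row spacing, raises a smoothed-noise domain by a height step
  (default 2.7 nm, the GFP differential scale) with randomized texture in
  place of the lattice, and adds roughness and an optional background tilt.
* `genMembraneFrame()` samples flat, spherical-cap or Gaussian-dimple
  midplanes with uniform x–y particles, leaflet offsets of ± thickness/2
  and optional z-noise at the lipid-protrusion scale (0.2 nm).

All randomness flows from the single `seed` argument through an isolated
RNG stream; identical calls are bit-identical and the global RNG state is
untouched. Every generator returns a `SyntheticTruth` record sufficient to
regenerate its dataset.

Passing the closed-loop tests shows that each analysis stage recovers the
parameters of data generated under its own assumptions — sharp patch edges,
static fields of view, ideal logistic schedules, Gaussian noise, perfectly
hexagonal crystals, Monge-sampleable membranes. It does not certify
performance on drifting stages, photobleaching, non-sigmoid rolling,
multi-patch fields, tip-convolved AFM scans or steep membrane folds; the
drift check, ROI support and explicit failure conditions are the designed
escape hatches for such data.

## Problem sizes and runtimes

The test-suite and acceptance workloads are sized for interactive use: 50
recovery movies at 128² px with ~70–90 frames each (~20 s total), 256² px
AFM scans, 20–40 k particles per leaflet for curvature pipelines, and 10^4
to 10^6-point energy grids for the rolling model. All tolerances quoted
above are asserted by the test suite at exactly these sizes.
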