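# patchRoll

Quantitative analysis of annexin-driven rolling of supported membrane
patches, for membrane biophysicists working with non-vesicular patch assays,
AFM of annexin crystals on supported bilayers, and coarse curvature analysis
of simulated membranes.

Annexins binding one face of a membrane patch with free edges impose a
spontaneous curvature c0 that makes the patch roll up from its edges;
crosslinking annexins oppose this by binding the patch to the membrane
underneath (adhesion energy density w_ad). patchRoll implements:

* **Rolling energetics.** The patch rolls into an Archimedean spiral
  r(θ) = r0 + (b/2π)θ. Per unit roll width, rolling a length L changes the
  energy by

  ΔE(L) = ∫₀ᴸ [ (k_c/2)((1/r(s) − c0)² − c0²) + w_ad ] ds,

  a Helfrich bending term (relaxation of the c0-frustrated flat state)
  against the adhesion forfeited by detaching. The equilibrium rolled
  length L\* follows from the marginal condition
  (k_c/2)(c0² − (1/r\* − c0)²) = w_ad; sweeps in w_ad and c0 locate the
  critical crosslinking factor / curvature reduction at which L\* falls to
  the ~1 µm optical resolution limit ("no rolling").
* **Rolling kinetics.** Incremental and cumulative rolled area from
  time-lapse dye-channel stacks by binarized frame differencing; the time
  constant τ from a logistic fit A/(1 + exp(−(t − t0)/τ)); onset times,
  relative-area unrolling traces, edge line profiles, Welch's t tests.
* **AFM analysis.** Lattice period of close-packed annexin-trimer crystals
  from the 2D power spectrum (first-order ring, period 2π/|q|), and
  low/high height-domain area fractions from bimodal height histograms.
* **Curvature mapping.** Membrane midplane surfaces fitted to
  lipid-particle coordinates; Monge-gauge mean curvature H; footprint
  averages across frames or replicas.
* **Synthetic data.** Generators for rolling/unrolling movies, AFM scans
  and curved-membrane particle frames, each returning a ground-truth
  record — the package's principal test surface.

## Worked example

```r
library(patchRoll)

## Energetics: how much extra adhesion stops rolling?
p <- rollModelParams()        # kc 1e-19 J, c0 3.33e7 1/m, wad 1e-5 J/m^2
rolledLength(p)               # 0.0001492 m: a ~150 um roll
sw <- sweepAdhesion(p, factors = seq(1, 10, by = 0.25))
criticalFactor(sw)            # 5.219: w_ad x 5.2 pins L* to 1 um

## Kinetics: recover tau from a synthetic rolling movie
g <- genRollingMovie(patchRadius = 15, tau = 12, onset = 24,
                     noiseSigma = 0.1, pixelSize = 0.32,
                     frameInterval = 1.5, dim = 128L, seed = 42)
fit <- fitLogistic(incrementalRolledArea(g$stack))
fit
#> LogisticFit: A / (1 + exp(-(t - t0)/tau))
#>   tau = 11.75 s, t0 = 57.71 s, A = 707.3 um^2
#>   onset = 23.95 s, RMS residual = 2.1 um^2

## AFM: lattice period and domain fractions of a two-phase scan
a <- genAfmImage(spacing = 9.08, domainFractionHigh = 30, seed = 7)
latticePeriod(a$map)
#> LatticeResult: period 9.12 nm (lattice constant 10.5 nm, 6 peaks, crystalline)
segmentHeightDomains(a$map)$fractions
#> DomainFractions: low 70% / high 30% (threshold 1.29 nm)
```

The movie's true τ was 12 s and its patch area 708 µm²; the fit recovers
11.75 s and 707 µm² (the small τ deficit is the documented truncation bias
of fitting a logistic to a record that starts near onset). The AFM scan was
generated with a 9.08 nm row spacing and a 30% raised domain.

See the `membrane-rolling-analysis` vignette for the models, parameter
conventions, numerical choices and limitations, and `inst/cli/patchroll.R`
for a command-line wrapper over the same functions.

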