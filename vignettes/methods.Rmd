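---
title: "Methods: spot calling, staging, and scaling statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot calling, staging, and scaling statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotglass)
```

# Overview

`spotglass` quantifies single-molecule FISH images and single-cell
fluorescence data for questions about expression–volume scaling in budding
yeast. This vignette documents the models behind each module, the tunable
parameters and their defaults, the numerical decisions, and what the
synthetic-data generators do and do not emulate.

# The spot-calling model

An smFISH z-stack is a 3D intensity array `[z, y, x]` with physical voxel
sizes (default 0.240 µm axial step, 0.103 µm lateral pixel). Single mRNAs
are diffraction-limited: their image is the microscope's PSF, so two true
molecules cannot produce two intensity peaks closer than the optical
resolution. The caller exploits this in five steps.

1. **Prefilter.** A separable 3D Gaussian, isotropic in voxel units
   (`prefilter_sigma`, default 0.75 voxel). The sigma is deliberately small:
   it suppresses single-voxel shot noise without broadening
   diffraction-limited peaks into each other. Border handling is reflection
   padding. `sigma = 0` is the identity.

2. **Thresholding.** A single global threshold on the filtered stack
   separates "spot signal" from background, using one of three standard
   histogram algorithms (`triangle` — the default, robust for sparse spots
   on a dominant background mode — `li`, or `otsu`; 256-bin histograms for
   otsu/triangle, minimum cross-entropy iteration on raw values for li).
   The method is a configuration choice, not an automatic selection: which
   algorithm suits an experiment depends on staining density and is best
   fixed per dataset by inspection. A constant image has no threshold and
   yields an empty mask with a warning. Foreground is strictly above the
   threshold.

3. **Local maxima.** A voxel is a candidate peak iff it lies in the
   threshold mask and its value is ≥ all 26 neighbors. A connected plateau
   of equal-valued maxima (a flat-topped spot, common after quantization)
   collapses to one candidate at its lexicographically smallest `(z, y, x)`
   voxel, preventing double counting. Candidate intensities are read from
   the filtered stack (where the maxima were found); this is configurable to
   the raw stack.

4. **Resolution-limited merging.** The merging neighborhood is a spheroid
   with lateral radius `r_xy = 0.61 λ / NA` and axial radius `z_radius_um`
   (default 1 µm, reflecting the several-fold poorer axial resolution of
   wide-field optics). At NA 1.4 and λ = 668 nm, `r_xy` = 0.291 µm. The
   0.61 coefficient is the classical Rayleigh-type lateral resolution
   constant; it is exposed in the configuration (`lateral_coefficient`)
   because conventions differ (e.g. λ/(2 NA) is also called a diffraction
   limit and would give 0.239 µm here). Merging is greedy by decreasing
   intensity: a candidate is discarded iff it lies within the spheroid of an
   already retained, brighter candidate, by the physical membership test
   `(Δx/r_xy)² + (Δy/r_xy)² + (Δz/r_z)² ≤ 1`. Intensity ties break by
   lexicographic center so results are deterministic. The retained set
   satisfies, by construction, that no peak lies inside a brighter retained
   peak's spheroid.

5. **Iterative Glass' delta filter.** For each surviving peak,
   `Δ = (mean_peak − mean_bg) / sd_bg`, where the peak voxels are the
   spheroid around the center clipped to the stack and to the peak's own
   cell footprint, and the background voxels are all voxels of that cell's
   footprint (across every z-slice) outside *every* detected peak's
   spheroid. Glass' delta rather than a plain intensity cut makes the filter
   contrast-calibrated: it is invariant under affine intensity transforms of
   the stack, so a τ chosen on one image transfers to differently exposed
   images. Peaks with Δ < τ (`effect_size_threshold`, default 0.5; the
   useful range in practice is about 0.2–1.0) are discarded, their voxels
   rejoin the background, and the filter repeats until the count stops
   changing. The loop provably terminates within (initial count + 1)
   iterations because the count strictly decreases until the fixed point.
   Cascades are real: removing a dim peak returns its voxels to the
   background, raising the background mean and spread, which can drag a
   borderline peak under τ on the next round — the test suite constructs
   exactly this case and checks the fixed point against a brute-force
   reimplementation.

Peaks whose `(y, x)` position falls outside every cell are dropped before
step 5: the background that defines Δ is per-cell, so a peak with no cell
has no defined effect size. Background statistics are per cell, not pooled
across cells, matching the definition of the background as the cell's own
mask. `sd_bg` uses the population (n) denominator; with realistic
background sizes (thousands of voxels) the difference from n−1 is
negligible, but fixing one convention is necessary for exact oracle
equality. `sd_bg = 0` or an empty background raises an error rather than
returning an infinite or undefined Δ.

Coordinates in all tables are 0-based voxel indices in `(z, y, x)` order;
physical positions are voxel index × voxel size, in µm.

# Cell volume, staging, and concentration

Cell segmentation masks are 2D (the input expected from standard yeast
segmentation tools); volume is reconstructed by revolving the mask about its
major axis, the first principal axis of the pixel cloud. By Pappus'
theorem the revolved volume equals `π Σ |w_i|` over mask pixels, with `w`
the perpendicular distance to the axis (pixels straddling the axis use the
exact integral of |w| over the pixel square). This is algebraically the
same solid as summing disks of the local column height but linear in the
mask, which makes it markedly less sensitive to boundary rasterization.
Exactness holds for axis-symmetric shapes (cylinders are exact; spheres to
within ~1% at radius 10 px). Rotating or translating a realistically sized
cell (40–60 px across at 0.103 µm/px, i.e. tens of fL) changes the estimate
by under 2%; for much smaller masks the discretized mask itself varies by
more than that under rotation, which bounds any mask-based estimator.

Staging uses the bud-to-mother volume ratio: unbudded with one nucleus →
G1; budded with ratio < 0.3 → S; budded with ratio ≥ 0.3 → G2/M; budded
with two nuclei → G2/M regardless of ratio (standing in, with an auditable
rationale string, for the visual inspection that distinguishes post-anaphase
pairs from neighboring G1 cells); unbudded with ≠ 1 nucleus → ambiguous.
The boundary value 0.3 itself is assigned to G2/M — the rule set leaves the
boundary open, and a deterministic convention is required. A budded pair
reports one row: spot counts and volumes of mother and bud are pooled, so
the concentration refers to the mother–bud pair as a single cell; this
attribution is the package's documented choice and is configurable by
simply not supplying the pedigree.

mRNA concentration is spots per fL (1 fL = 1 µm³).

# Trace quantification

Reporter traces sampled at a fixed interval (default 3 min) show a G1
plateau `P_G1`, a rise, and a G2 plateau `P_G2`. The produced amount is
`median(last 4 points) − median(first 4 points)` — medians absorb
single-frame outliers. Production timing uses plateau means over the first
and last `k_plateau = 4` points (consistent with the 4-point medians; the
plateau extent is the caller's responsibility and `k` is configurable) and a
10% threshold: `t_start` is the last sampled time with intensity strictly
below `1.1 P_G1`, `t_end` the first strictly above `0.9 P_G2`. The
inequalities are strict; a sample exactly at a threshold does not satisfy
the condition, and a relative guard of 1e-9 resolves floating-point ties so
that analytically-exact boundary samples behave as the strict rule demands.
No smoothing is applied before threshold crossing. A flat trace (where
`0.9 P_G2 < 1.1 P_G1`) has no production phase and errors as degenerate.

Autofluorescence is modeled as `α + β·V`, fitted by least squares to
control cells not expressing the reporter; when all control volumes are
equal the design is singular and the model degrades to a constant. Corrected
intensities may go negative and are retained — truncating at zero would bias
low signals upward.

# Kinetics

mRNA decay after transcription shut-off is fitted as
`N(t) = N0 · exp(−k t)` by nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`), pooling the individual replicate points rather than replicate
means, initialized from a log-linear regression. `N0` is free by default
even though the series is normalized at t = 0: that normalization divides by
a noisy measurement, and constraining `N0 = 1` would push its noise into
`k`. A fixed-`N0` mode is provided for comparison. A non-positive fitted
rate reports "no decay detected" with an undefined half-life instead of a
negative one. Half-life is ln 2 / k.

Doubling time is ln 2 over the slope of log(OD600) versus time within an
exponential-phase window. When no window is given, every contiguous window
of ≥ 4 points is scanned and the one with the highest R² (positive slope
required) wins, ties within 1e-9 going to the longer window — so a fully
exponential curve uses all its points, while lag and saturation phases are
excluded automatically. Normalized stability is half-life divided by
doubling time, a dimensionless measure of stability against growth
dilution.

# Population statistics

Relative mRNA concentration from qPCR is `2^(Cq_ref − Cq_gene)`, with
technical replicates averaged on the Cq scale first. Fold changes divide
each biological replicate's relative concentration by the reference
condition's mean, then average (mean-of-ratios); the alternative
ratio-of-means order is equally defensible in principle and the choice is
documented here precisely because it is not forced — the reference
condition's own fold change is 1 by construction under both.

Scaling exponents are ordinary least squares of log(y) on log(V) (natural
logs internally; the exponent is base-invariant), with a t-based 95% CI.
An exponent of 1 for amounts means concentration is constant; constant
amounts give a concentration exponent of exactly −1 by algebra, which the
fit reproduces to machine precision on noiseless data. Linear fits report
t-based parameter CIs and pointwise confidence bands; two slopes are
compared with the standard interaction test on the pooled model
`y ~ x * group`.

Two-group comparisons follow a normality gate: Shapiro–Wilk on both groups
at α = 0.05; both pass → unpaired two-tailed equal-variance t-test;
otherwise → two-sided Mann–Whitney. A zero-variance group cannot be tested
by Shapiro–Wilk and routes to the Mann–Whitney path. No multiple-testing
correction is applied; p-values are per comparison. The gate's type-I error
stays near the nominal α on simulated Gaussian nulls (checked by a
2000-draw Monte-Carlo in the test suite).

# The synthetic-data generators

The generators exist so every stage has ground truth. Their defaults are the
study conditions the rest of the package assumes:

- **Stacks** (`generate_smfish_stack`): cells are 2D ellipses on a grid
  (masks are 2D, as consumed by the pipeline), extruded across z, with
  concentric elliptical nuclei; spots are separable 3D Gaussians
  (`psf_sigma_xy` 0.10 µm, `psf_sigma_z` 0.35 µm — nominal wide-field PSF
  widths at this NA and wavelength) of configurable peak amplitude on a
  per-cell constant background; noise is Poisson on signal + background
  followed by Gaussian read noise, clipped at zero, stored as floating
  point. An optional minimum spot separation supports detection benchmarks;
  impossible placements error out. Geometry defaults (20 z-slices at
  0.240 µm; 0.103 µm pixels) mirror a standard wide-field acquisition.
  What is *not* emulated: Airy rings and aberrations, camera gain and
  fixed-pattern noise, autofluorescence gradients, segmentation errors, and
  transcription-site clusters. Passing detection tests on these stacks
  therefore demonstrates algorithmic correctness — recovery of known ground
  truth under Poisson-limited imaging — not robustness to every real-image
  artifact.
- **Traces** (`generate_trace`): plateau–linear rise–plateau with additive
  Gaussian noise and optional injected autofluorescence `α + β·V`. Defaults
  (P_G1 = 100, rise of 100 over 30–60 min, 3-min sampling, 120 min total)
  give the canonical twofold step.
- **Decay** (`generate_decay_series`): `exp(−ln2·t/t½)·(1 + ε)` with
  multiplicative Gaussian noise of CV `noise_cv`; timepoints default to
  0–60 min, four replicates, CV 0.1 — the scale of a shut-off qPCR
  experiment.
- **Populations** (`generate_population`): lognormal volumes (median 60 fL,
  sigma 0.25 — a typical haploid size distribution) and Poisson counts with
  `E[count | V] = c·V^a`.
- **Cq tables** (`generate_cq_table`): `Cq_gene = Cq_ref − log2(rel) +
  noise`, three technical replicates per sample, noise on both channels.

All generators take a seed and are bit-reproducible under it; RNG state is
restored afterwards.

# Verification strategy and problem sizes

Every nontrivial algorithmic step is tested against an independent
brute-force oracle on small instances: exhaustive threshold search for Otsu,
a triple-loop neighborhood scan for local maxima, a voxel-loop Δ
computation, and a naive reimplementation of the filter iteration (plus an
explicit fixed-point check and, on a 3-peak instance, an enumeration of the
discard path). Detection performance (recall and precision ≥ 0.95) is
measured on seeded stacks of 16 × 110 × 110 voxels with five cells × six
spots at ≥ 0.7 µm separation and amplitude 80 — comfortably above the
effect-size threshold, which is the regime the performance guarantee
addresses. Monte-Carlo recovery checks use 200–500 replicates and 2000
draws for the type-I error; these sizes keep the full suite under a minute
while leaving Monte-Carlo error well below the asserted tolerances.

# Known limitations

- No sub-voxel localization or Gaussian fitting of spot shape; positions
  are voxel-resolution.
- Transcription sites containing several nascent mRNAs are counted as one
  spot (by design of the resolution-limited merge).
- The threshold algorithm and τ are per-experiment configuration; no
  automatic per-image selection is attempted.
- 2D masks mean the volume model assumes rotational symmetry about the
  in-plane major axis.
- The plateau extent `k = 4` is a stated convention; traces that extend far
  beyond division violate the plateau assumption and should be trimmed by
  the caller.
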