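# spotglass

Quantitative analysis of single-molecule RNA FISH (smFISH) and single-cell
fluorescence data in budding yeast, built around the question of how gene
expression scales with cell volume. Histone transcripts are the motivating
case: their amounts stay roughly constant as cells grow, so their
concentration dilutes as 1/V, whereas most transcripts scale proportionally
with volume. Telling those regimes apart requires counting individual mRNA
molecules per cell, measuring each cell's volume, staging the cell cycle,
and fitting the resulting population statistics — which is exactly what this
package does, for microscopists and quantitative biologists working with 3D
image stacks, time-lapse traces, qPCR tables, and growth curves.

## What it implements

**3D spot calling.** mRNAs appear as diffraction-limited spots in z-stacks.
The caller runs five steps: (1) a 3D Gaussian prefilter (default sigma 0.75
voxel); (2) automatic global thresholding of the spot signal (triangle, Li,
or Otsu); (3) 26-connected local-maxima detection inside the threshold mask;
(4) merging of peaks that fall within a resolution-limited spheroid — lateral
radius r_xy = 0.61 λ/NA (0.291 µm at NA 1.4 and λ = 668 nm), axial radius
1 µm — keeping only the brightest; (5) an iterative effect-size filter that
computes each peak's Glass' delta,

    Δ = (mean_peak − mean_background) / sd_background,

with peak voxels inside the spheroid and background voxels inside the cell
mask but outside every detected peak, discards peaks with Δ below a
threshold τ (typically 0.2–1.0), and repeats — discarded peaks rejoin the
background — until the peak count is stable. The surviving peaks are the
mRNA count per cell.

**Cell staging and concentrations.** Cell volume is reconstructed from the
2D segmentation mask as a solid of revolution about the major axis; the
cell-cycle stage follows the bud-to-mother volume ratio (unbudded + one
nucleus → G1; ratio < 0.3 → S; otherwise G2/M); mRNA concentration is
spots per fL.

**Traces, kinetics, and population statistics.** Produced amount and
production-phase timing from plateau–rise–plateau reporter traces (10%
thresholds 1.1·P_G1 and 0.9·P_G2); volume-dependent autofluorescence
correction; single-exponential mRNA decay fits (t½ = ln2/k) after
transcription shut-off; doubling times from log-linear OD600 growth; ΔCq
relative concentrations 2^(Cq_ref − Cq_gene) and fold changes; log–log
scaling exponents with 95% CIs; slope comparisons; and a Shapiro–Wilk-gated
choice between the t-test and the Mann–Whitney test.

**Synthetic data.** Every stage has a generator with known ground truth —
simulated stacks with Gaussian-PSF spots on Poisson + read-noise
backgrounds, production traces, decay series, volume-scaled populations, and
Cq tables — so the whole pipeline is testable without microscopy data.

## Worked example

```r
library(spotglass)

# simulate a stack with 5 cells x 6 spots of known position, then call spots
p <- stack_sim_params(shape = c(16L, 110L, 110L), n_cells = 5L, n_spots = 6L,
                      spot_amplitude = 80, min_sep_um = 0.8, seed = 42L)
sim <- generate_smfish_stack(p)
cfg <- spot_config(threshold_method = "otsu", effect_size_threshold = 1.0)
spots <- call_spots(sim$stack, sim$cell_labels, config = cfg)
spot_counts(spots, sim$cell_labels)
#>   cell_id n_spots
#> 1       1       6
#> 2       2       6
#> 3       3       6
#> 4       4       6
#> 5       5       6

# population scaling: amounts proportional to volume (exponent 1) imply a
# flat concentration (exponent 0)
pop <- generate_population(population_sim_params(n_cells = 2000L,
                                                 scaling_exponent = 1,
                                                 c = 0.5, seed = 7L))
fit_scaling_exponent(pop$volume_fl, pmax(pop$mrna_count, 0.5))
#> scaling_fit: exponent 1.0186 (95% CI 0.9852 to 1.0521, n = 2000)

# mRNA half-life from a simulated shut-off time course
dec <- generate_decay_series(decay_sim_params(half_life = 20, noise_cv = 0.1,
                                              n_replicates = 4L, seed = 3L))
fit_exponential_decay(dec)
#> decay_fit: k = 0.03504 /min, half-life = 19.78 min, N0 = 0.9746 (n = 28)

# production-phase timing on a noiseless reporter trace
production_phase(generate_trace(trace_sim_params(noise_sd = 0)))
#> production_summary: amount 100.0 a.u.; plateaus 100.0 -> 200.0; phase 30-57 min (27 min)
```

All 30 simulated spots are recovered in their correct cells; the scaling
exponent's CI covers the programmed value 1; the decay fit recovers the
20-min half-life within the noise; and on the standard ramp trace the 10%
rule yields a 27-min production phase.

A command-line wrapper for the spot caller is installed at
`inst/scripts/call_spots.R`:

```sh
Rscript inst/scripts/call_spots.R --stack stack.tif --cells cells.tif --out spots.csv
```

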