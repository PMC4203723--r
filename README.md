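# stretchFRET

Analysis toolkit for experiments in which adherent cells (typically human
mesenchymal stem cells) on an elastic polyacrylamide substrate are imaged
with a FRET-based calcium biosensor while the substrate is mechanically
stretched by pulling a glass probe tip inserted into the gel near the cell.
The package covers both measurement chains of such an experiment, plus the
synthetic data needed to test them without a microscope:

- **Ratiometric calcium readout** — background-subtracted FRET/donor
  (YPet/ECFP) emission-ratio stacks and per-ROI traces, with a division
  guard for dim pixels and support for acquisition pauses.
- **Oscillometry** — peak detection on ratio traces; frequency as peaks
  per minute of elapsed valid time; amplitude as the mean emission ratio
  at the peaks; the oscillating classification (at least two peaks) and
  responder fractions with exact binomial confidence intervals;
  loading-vs-unloading segment comparisons.
- **Substrate mechanics** — fiducial-bead localization, robust bead
  matching between the unloaded reference frame and the loaded frame
  (relaxation labeling, reliable even when displacements are several times
  the bead spacing), interpolation of the displacement field onto a
  regular grid, normal strains *Eₓ = ∂uₓ/∂x*, *E_y = ∂u_y/∂y*, the total
  strain index *E = √(Eₓ² + E_y²)*, peak strain over a query region, and
  stress *S = E_peak × Young's modulus* (a peak strain index of 0.3 on a
  20 kPa gel gives S = 0.3 × 20000 = 6000 N/m²).
- **Group statistics** — two-group Student's t-tests (Welch and paired by
  flag) and Bonferroni multiple comparison of group means at the family
  95% confidence level, with the star-coded bar-graph tables conventional
  in this literature.
- **Synthetic data** — single-cell calcium traces (baseline plus
  double-exponential transients at a set frequency and amplitude, with
  interval jitter), their rendering into two anti-correlated fluorescence
  channels with Poisson photon noise and Gaussian read noise (optionally
  with a calcium wave propagating from the probe-proximal edge), and
  bead-field pairs deformed by a Gaussian tip-pull displacement model with
  closed-form strain ground truth.

See the methods vignette (`vignettes/stretchFRET-methods.Rmd`) for the
models, parameter choices and validation results.

## Worked example

```r
library(stretchFRET)

## calcium arm: simulate a cell oscillating at 2 peaks/min for 10 min,
## render it into a noisy two-channel stack, and analyze it back
tr  <- simulateTrace(calciumTraceModel(duration_s = 600,
                                       frequency_per_min = 2, seed = 1))
stk <- renderStack(tr, cellRenderSpec(diskMask(48, 48, radius_px = 16),
                                      seed = 2))
bg  <- estimateBackground(stk, stk@truth$spec@cell_mask)
rs  <- computeRatioStack(stk, background_per_channel = bg)
trace <- extractTrace(rs, stk@truth$spec@cell_mask, "cell1")
summarizeOscillations(detectPeaks(trace), trace)
#> OscillationSummary 'cell1' [NA]: 19 peaks in 10.0 min -> 1.900 /min,
#>   amplitude 1.460 (absolute), oscillating

## mechanics arm: a tip-pull bead pair calibrated so the analytic peak
## strain index is 0.3 (stress 6000 N/m^2 on a 20 kPa gel)
field <- tipPullField(pull_vector_um = c(0.3 * 30 * sqrt(exp(1)), 0),
                      decay_sigma_um = 30, bead_density_per_um2 = 0.04,
                      seed = 3)
sim <- simulateBeadPair(field, region_um = c(-80, 80, -80, 80))
rec <- reconstructStrain(sim@ref_obs, sim@loaded_obs,
                         young_modulus_pa = 20000,
                         max_search_radius_um = 18)
rec$strain
#> StrainMap (small strain): peak strain index 0.3056,
#>   stress 6113 N/m^2 on a 20000 Pa substrate
plot(rec$strain)   # strain-index map, conventional display range 0-0.3
```

The recovered frequency (1.9/min vs the generated 2/min — one transient
fell in the jittered tail of the window), amplitude (1.46 vs the generated
baseline 1 + amplitude 0.5, read at the 10 s sampling grid) and peak
strain (0.306 vs the closed-form 0.3) illustrate the measurement chain
end to end.

A thin command-line wrapper over these functions is included at
`inst/scripts/stretchfret.R` (subcommands `simulate trace|stack|beads`,
`strain`, `compare`).

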