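# shared fixtures, all generated in code

# a small noiseless rendering spec over a disk cell
noiselessSpec <- function(ny = 24, nx = 24, radius_px = 8, seed = 1L, ...) {
  cellRenderSpec(diskMask(ny, nx, radius_px = radius_px),
                 poisson_noise = FALSE, read_noise_sd = 0, background = 0,
                 seed = seed, ...)
}

# simulate a population of cells, returning per-cell OscillationSummary
simulatePopulation <- function(n_cells, frequency_per_min, peak_amplitude = 0.5,
                               duration_s = 600, jitter_frac = 0.2,
                               frame_interval_s = 10, min_separation_s = 20,
                               group_label = "grp", seed_base = 1000L, ...) {
  lapply(seq_len(n_cells), function(i) {
    tr <- simulateTrace(calciumTraceModel(
      duration_s = duration_s, frequency_per_min = frequency_per_min,
      peak_amplitude = peak_amplitude, jitter_frac = jitter_frac,
      frame_interval_s = frame_interval_s, seed = seed_base + i, ...))
    rt <- asRatioTrace(tr, roi_id = sprintf("cell%03d", i))
    summarizeOscillations(
      detectPeaks(rt, min_separation_s = min_separation_s), rt,
      group_label = group_label)
  })
}

# the tip-pull scenario emulating the study conditions: peak strain 0.3 on a
# 20 kPa gel, displacements within the 0-15 um map range, 1 bead / 25 um^2,
# 0.05 um localization noise
paperScaleField <- function(seed = 3L) {
  tipPullField(pull_vector_um = c(0.3 * 30 * sqrt(exp(1)), 0),
               decay_sigma_um = 30, bead_density_per_um2 = 0.04,
               localization_noise_um = 0.05, seed = seed)
}
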