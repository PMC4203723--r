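test_that("simulateTrace honors frequency, onset and the silent-cell case", {
  # silent cell: flat at baseline
  flat <- simulateTrace(calciumTraceModel(frequency_per_min = 0,
                                          baseline_ratio = 1.2))
  expect_true(all(ratioValues(flat) == 1.2))

  # 2 peaks/min over 5 min without jitter: exactly 10 transients
  tr <- simulateTrace(calciumTraceModel(duration_s = 300,
                                        frequency_per_min = 2,
                                        jitter_frac = 0))
  expect_identical(length(tr@event_times_s), 10L)

  # jittered event count stays within +/-1 of the nominal count
  for (seed in 1:10) {
    trj <- simulateTrace(calciumTraceModel(duration_s = 600,
                                           frequency_per_min = 2,
                                           jitter_frac = 0.3, seed = seed))
    expect_lte(abs(length(trj@event_times_s) - 20), 1)
  }

  expect_error(calciumTraceModel(duration_s = -5), "duration_s")
  expect_error(calciumTraceModel(frame_interval_s = 0), "frame_interval_s")
})

test_that("transient peak height equals the amplitude (dense-time oracle)", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 300,
                                        frequency_per_min = 1,
                                        rise_s = 2, decay_s = 15,
                                        peak_amplitude = 0.5,
                                        jitter_frac = 0))
  # independent oracle: the normalized double-exponential pulse evaluated on
  # a dense grid peaks at exactly 1, so the dense-time trace maximum is
  # baseline + amplitude
  td <- seq(0, 60, by = 0.01)
  pulse <- exp(-td / 15) - exp(-td / 2)
  oracle_max <- 1 + 0.5 * max(pulse) / max(pulse)
  expect_equal(max(traceAt(tr, seq(0, 300, by = 0.01))), oracle_max,
               tolerance = 1e-9)
  # the 10 s sampling can only undershoot the true peak, within the
  # documented band
  samp <- max(ratioValues(tr)) - 1
  expect_gte(samp, 0.4)
  expect_lte(samp, 0.5)
})

test_that("same seed gives bit-identical traces and stacks", {
  m <- calciumTraceModel(duration_s = 200, seed = 11L)
  expect_identical(simulateTrace(m), simulateTrace(m))
  tr <- simulateTrace(m)
  spec <- cellRenderSpec(diskMask(16, 16, radius_px = 5), seed = 4L)
  expect_identical(renderStack(tr, spec)@data, renderStack(tr, spec)@data)
  f <- tipPullField(seed = 9L)
  s1 <- simulateBeadPair(f, region_um = c(-40, 40, -40, 40))
  s2 <- simulateBeadPair(f, region_um = c(-40, 40, -40, 40))
  expect_identical(s1@ref_obs, s2@ref_obs)
  expect_identical(s1@loaded_obs, s2@loaded_obs)
})

test_that("noiseless synchronous rendering reproduces the trace per pixel", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 200, jitter_frac = 0))
  spec <- noiselessSpec()
  stk <- renderStack(tr, spec)
  inside <- which(spec@cell_mask)
  for (i in seq_along(tr@times_s)) {
    r <- stk@data[, , 2, i][inside] / stk@data[, , 1, i][inside]
    expect_lt(max(abs(r - tr@ratio[i])), 1e-12)
  }
  # outside the mask: background only (here zero)
  expect_true(all(stk@data[, , , 1][!array(spec@cell_mask,
                                           c(dim(spec@cell_mask), 2))] == 0))
})

test_that("onset delays follow distance over wave speed", {
  mask <- matrix(TRUE, 1, 11)
  spec <- cellRenderSpec(mask, pixel_size_um = 10, wave_speed_um_s = 10,
                         wave_origin = c(0, 0), poisson_noise = FALSE,
                         read_noise_sd = 0, background = 0)
  d <- onsetDelays(spec)
  # two pixels 100 um apart along the propagation axis: 10 s delay difference
  expect_equal(d[1, 11] - d[1, 1], 10)
  # synchronous case
  spec0 <- cellRenderSpec(mask, wave_speed_um_s = 0)
  expect_true(all(onsetDelays(spec0) == 0))
})

test_that("noisy rendered stack tracks the trace (mask-mean correlation)", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 490, jitter_frac = 0,
                                        seed = 5L))
  spec <- cellRenderSpec(diskMask(24, 24, radius_px = 8), seed = 21L)
  stk <- renderStack(tr, spec)   # 50 frames with photon + read noise
  rs <- computeRatioStack(stk, background_per_channel = c(
    donor = spec@background, fret = spec@background))
  trace <- extractTrace(rs, spec@cell_mask)
  expect_identical(length(ratioValues(trace)), 50L)
  expect_gt(cor(ratioValues(trace), ratioValues(tr)), 0.99)
})

test_that("simulateBeadPair ground truth matches its closed form", {
  # null load: displaced == reference, zero strain
  f0 <- tipPullField(pull_vector_um = c(0, 0))
  s0 <- simulateBeadPair(f0, region_um = c(-40, 40, -40, 40))
  expect_identical(s0@loaded_true, s0@ref_true)
  expect_true(all(totalStrain(s0@strain) == 0))

  # displacement at the tip equals the pull vector (Gaussian peak = 1)
  f <- tipPullField(tip_xy_um = c(3, -7), pull_vector_um = c(4, -2))
  expect_equal(as.numeric(tipPullDisplacement(f, cbind(3, -7))), c(4, -2))

  # analytic strain vs central finite differences of the closed form
  # at 0.1 um step (the independent oracle)
  f1 <- tipPullField(pull_vector_um = c(10, 0), decay_sigma_um = 50)
  sim <- simulateBeadPair(f1, region_um = c(-100, 100, -100, 100),
                          grid_spacing_um = 10)
  h <- 0.1
  gx <- sim@strain@grid_x_um
  gy <- sim@strain@grid_y_um
  fdEx <- matrix(NA_real_, length(gy), length(gx))
  fdEy <- matrix(NA_real_, length(gy), length(gx))
  for (j in seq_along(gx)) {
    up <- tipPullDisplacement(f1, cbind(gx[j] + h, gy))
    um <- tipPullDisplacement(f1, cbind(gx[j] - h, gy))
    fdEx[, j] <- (up[, 1] - um[, 1]) / (2 * h)
  }
  for (i in seq_along(gy)) {
    up <- tipPullDisplacement(f1, cbind(gx, gy[i] + h))
    um <- tipPullDisplacement(f1, cbind(gx, gy[i] - h))
    fdEy[i, ] <- (up[, 2] - um[, 2]) / (2 * h)
  }
  scale <- max(abs(fdEx))
  expect_lt(max(abs(sim@strain@Ex - fdEx)) / scale, 1e-4)
  expect_lt(max(abs(sim@strain@Ey - fdEy)) / scale, 1e-4)
  # closed-form peak: U0 / (sigma * sqrt(e)) on the x axis
  expect_equal(peakStrain(sim@strain), 10 / (50 * sqrt(exp(1))),
               tolerance = 1e-3)
  expect_error(simulateBeadPair(f1, region_um = c(0, 1, 0, 1)), "empty")
})
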