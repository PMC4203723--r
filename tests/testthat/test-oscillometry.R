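flatTrace <- function(n = 31, value = 1, interval = 10) {
  new("RatioTrace", times_s = (seq_len(n) - 1) * interval,
      ratio = rep(value, n), valid = rep(TRUE, n), roi_id = "flat")
}

test_that("detectPeaks finds constructed peaks and nothing on flat traces", {
  expect_identical(length(peakTimes(detectPeaks(flatTrace()))), 0L)

  tr <- simulateTrace(calciumTraceModel(duration_s = 300,
                                        frequency_per_min = 2,
                                        jitter_frac = 0))
  pk <- detectPeaks(asRatioTrace(tr))
  expect_identical(length(peakTimes(pk)), 10L)

  # jittered traces: per-cell recovered count within +/-1 of generated count
  for (i in 1:20) {
    trj <- simulateTrace(calciumTraceModel(duration_s = 600,
                                           frequency_per_min = 2,
                                           jitter_frac = 0.3,
                                           seed = 100L + i))
    pkj <- detectPeaks(asRatioTrace(trj))
    expect_lte(abs(length(peakTimes(pkj)) - length(trj@event_times_s)), 1)
  }
  expect_error(detectPeaks(flatTrace(2)), "3 valid frames")
})

test_that("summaries report peaks per minute and mean peak ratio", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 300,
                                        frequency_per_min = 2,
                                        jitter_frac = 0))
  rt <- asRatioTrace(tr)
  sm <- summarizeOscillations(detectPeaks(rt), rt)
  expect_equal(frequencyPerMin(sm), 10 / 5)  # 10 peaks in 5 min
  expect_true(isOscillating(sm))

  pk <- new("PeakSet", peak_times_s = c(30, 90, 150),
            peak_ratios = c(1.5, 1.7, 1.9), baseline_ratio = 1,
            prominence_threshold = 0.1, min_separation_s = 20)
  sm2 <- summarizeOscillations(pk, flatTrace())
  expect_equal(meanPeakAmplitude(sm2), 1.7)
  sm3 <- summarizeOscillations(pk, flatTrace(),
                               amplitude_mode = "baseline_subtracted")
  expect_equal(meanPeakAmplitude(sm3), 0.7)
  # skip-first-peak drops the initial transient from both metrics
  sm4 <- summarizeOscillations(pk, flatTrace(), skip_first_peak = TRUE)
  expect_identical(sm4@n_peaks, 2L)
  expect_equal(meanPeakAmplitude(sm4), 1.8)
  # single transient is not an oscillation
  pk1 <- new("PeakSet", peak_times_s = 30, peak_ratios = 1.5,
             baseline_ratio = 1, prominence_threshold = 0.1,
             min_separation_s = 20)
  expect_false(isOscillating(summarizeOscillations(pk1, flatTrace())))
  expect_error(summarizeOscillations(pk, flatTrace(5)), "1 min")
})

test_that("group means recover generator frequency and amplitude within 10%", {
  freqs <- c(0.5, 1, 2, 4)
  amps <- c(0.2, 0.5, 1.0)
  for (f in freqs) {
    # 5 s sampling: the 4/min condition (15 s inter-peak intervals) is not
    # resolvable at the 10 s default with a 20 s peak separation
    sms <- simulatePopulation(50, f, frame_interval_s = 5,
                              min_separation_s = 10,
                              seed_base = 2000L + round(100 * f))
    df <- summariesToDataFrame(sms)
    expect_lt(abs(mean(df$frequency_per_min) - f) / f, 0.10)
  }
  for (a in amps) {
    sms <- simulatePopulation(30, 2, peak_amplitude = a,
                              seed_base = 3000L + round(100 * a))
    df <- summariesToDataFrame(sms)
    # absolute-peak convention: mean peak ratio ~ baseline + amplitude
    expect_lt(abs(mean(df$mean_peak_amplitude) - (1 + a)) / (1 + a), 0.10)
  }
})

test_that("metrics use elapsed time, not frame counts", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 600,
                                        frequency_per_min = 1.5,
                                        jitter_frac = 0, seed = 7L))
  rt <- asRatioTrace(tr)
  f1 <- frequencyPerMin(summarizeOscillations(detectPeaks(rt), rt))
  # resample the noiseless ground truth at half the frame interval
  t2 <- seq(0, 600, by = 5)
  rt2 <- new("RatioTrace", times_s = t2, ratio = traceAt(tr, t2),
             valid = rep(TRUE, length(t2)), roi_id = "dense")
  f2 <- frequencyPerMin(summarizeOscillations(detectPeaks(rt2), rt2))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("adding a constant shifts baseline and amplitude by that constant", {
  tr <- simulateTrace(calciumTraceModel(duration_s = 300, seed = 3L))
  rt <- asRatioTrace(tr)
  rt2 <- new("RatioTrace", times_s = rt@times_s, ratio = rt@ratio + 0.8,
             valid = rt@valid, roi_id = "shifted")
  p1 <- detectPeaks(rt)
  p2 <- detectPeaks(rt2)
  expect_equal(p2@baseline_ratio, p1@baseline_ratio + 0.8)
  expect_equal(peakRatios(p2), peakRatios(p1) + 0.8)
  s1 <- summarizeOscillations(p1, rt)
  s2 <- summarizeOscillations(p2, rt2)
  expect_equal(meanPeakAmplitude(s2), meanPeakAmplitude(s1) + 0.8)
})

test_that("responder fraction reports exact percentages with a binomial CI", {
  none <- data.frame(oscillating = rep(FALSE, 10))
  expect_equal(responderFraction(none)$fraction_pct, 0)
  all_ <- data.frame(oscillating = rep(TRUE, 7))
  expect_equal(responderFraction(all_)$fraction_pct, 100)
  expect_error(responderFraction(none[0, , drop = FALSE]), "empty group")

  # population with P(oscillating) = 0.8: estimate's 95% CI covers 80%
  osc <- withr::with_seed(42, runif(200) < 0.8)
  rf <- responderFraction(data.frame(oscillating = osc))
  expect_lte(rf$ci_lo_pct, 80)
  expect_gte(rf$ci_hi_pct, 80)
})

test_that("segmentCompare contrasts loading vs unloading windows", {
  # oscillations only in the first half: second-half frequency is zero
  active <- simulateTrace(calciumTraceModel(duration_s = 600,
                                            frequency_per_min = 2,
                                            jitter_frac = 0, seed = 5L))
  half <- asRatioTrace(active)
  half@ratio[half@times_s > 300] <- 1
  segs <- list(loading = c(0, 300), unloading = c(300.5, 600))
  res <- segmentCompare(half, segs)
  expect_equal(res$summaries$frequency_per_min[
    res$summaries$segment == "unloading"], 0)
  expect_gt(res$summaries$frequency_per_min[
    res$summaries$segment == "loading"], 1)

  # identical halves give equal frequencies
  sym <- flatTrace(61)
  sym@ratio[c(10, 40)] <- 2; sym@ratio[c(20, 50)] <- 2
  res2 <- segmentCompare(sym, list(a = c(0, 290), b = c(300, 590)))
  expect_equal(diff(res2$summaries$frequency_per_min), 0, tolerance = 1e-9)

  expect_error(segmentCompare(half, list(a = c(0, 300), b = c(200, 500))),
               "overlap")

  # 5 cells oscillating under load and silent after: paired difference
  traces <- lapply(1:5, function(i) {
    tr <- simulateTrace(calciumTraceModel(duration_s = 600,
                                          frequency_per_min = 2,
                                          seed = 600L + i))
    rt <- asRatioTrace(tr, sprintf("cell%d", i))
    rt@ratio[rt@times_s > 300] <- 1
    rt
  })
  res3 <- segmentCompare(traces, segs, paired = TRUE)
  expect_lt(pairwiseResults(res3$comparison)$p_value, 0.05)
})
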