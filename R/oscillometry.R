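#' @include AllClasses.R
NULL

#' Detect calcium peaks in a ratio trace
#'
#' Local maxima of the valid samples that exceed the trace baseline (the
#' 10th percentile of valid ratios) by at least `prominence_threshold`,
#' retained greedily by descending height subject to a minimum time
#' separation.  All timing uses the trace's real acquisition times, so
#' pauses in acquisition are handled correctly.
#'
#' @param trace a [RatioTrace-class] (or [CalciumTrace-class], converted
#'   with all frames valid) with at least 3 valid frames.
#' @param prominence_threshold minimum height above baseline (ratio units);
#'   default 0.1.
#' @param min_separation_s minimum time between peaks (s); default 20 s,
#'   i.e. two frames at a 10 s acquisition interval.
#' @return a [PeakSet-class].
#' @examples
#' tr <- simulateTrace(calciumTraceModel(duration_s = 300,
#'                                       frequency_per_min = 2,
#'                                       jitter_frac = 0))
#' length(peakTimes(detectPeaks(asRatioTrace(tr))))  # 10
#' @export
detectPeaks <- function(trace, prominence_threshold = 0.1,
                        min_separation_s = 20) {
  if (is(trace, "CalciumTrace")) trace <- asRatioTrace(trace)
  stopifnot(is(trace, "RatioTrace"))
  .assertScalar(prominence_threshold, "prominence_threshold", nonneg = TRUE)
  .assertScalar(min_separation_s, "min_separation_s", nonneg = TRUE)
  if (!any(trace@valid)) stop("all frames invalid")
  t <- trace@times_s[trace@valid]
  v <- trace@ratio[trace@valid]
  n <- length(v)
  if (n < 3L) stop("trace must have at least 3 valid frames")
  baseline <- unname(quantile(v, 0.10))
  height_floor <- baseline + prominence_threshold

  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] >= height_floor]
  keep <- integer(0)
  for (j in cand[order(v[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(t[j] - t[keep]) >= min_separation_s)) {
      keep <- c(keep, j)
    }
  }
  keep <- sort(keep)
  new("PeakSet", peak_times_s = t[keep], peak_ratios = v[keep],
      baseline_ratio = baseline,
      prominence_threshold = prominence_threshold,
      min_separation_s = min_separation_s)
}

#' Summarize oscillation metrics of one cell
#'
#' Frequency is the number of peaks divided by the valid observation time in
#' minutes (peaks per minute); amplitude is the mean FRET/donor emission
#' ratio at the peaks.  The literal absolute-peak reading ("the average peak
#' of the emission ratio") is the default; `amplitude_mode =
#' "baseline_subtracted"` reports mean(peak - baseline) instead.  A cell is
#' oscillating when it shows at least `min_peaks_oscillating` (default 2)
#' peaks: a single transient is not an oscillation.  `skip_first_peak`
#' excludes the initial transient, whose triggering can differ mechanistically
#' from the sustained oscillation, from both metrics.
#'
#' @param peaks a [PeakSet-class] from [detectPeaks()].
#' @param trace the corresponding [RatioTrace-class]; must span at least one
#'   minute of valid time (peaks per minute are undefined below that).
#' @param skip_first_peak drop the first peak from the metrics?
#' @param amplitude_mode "absolute" (default) or "baseline_subtracted".
#' @param min_peaks_oscillating classification minimum (default 2).
#' @param cell_id,group_label identifiers carried into the summary.
#' @return an [OscillationSummary-class].
#' @export
summarizeOscillations <- function(peaks, trace, skip_first_peak = FALSE,
                                  amplitude_mode = c("absolute",
                                                     "baseline_subtracted"),
                                  min_peaks_oscillating = 2L,
                                  cell_id = trace@roi_id,
                                  group_label = NA_character_) {
  stopifnot(is(peaks, "PeakSet"))
  if (is(trace, "CalciumTrace")) trace <- asRatioTrace(trace)
  stopifnot(is(trace, "RatioTrace"))
  amplitude_mode <- match.arg(amplitude_mode)
  tv <- trace@times_s[trace@valid]
  duration_min <- (max(tv) - min(tv)) / 60
  if (duration_min < 1) {
    stop("trace shorter than 1 min of valid time; ",
         "frequency in min^-1 is undefined")
  }
  pr <- peaks@peak_ratios
  if (skip_first_peak && length(pr)) pr <- pr[-1]
  n <- length(pr)
  amp <- if (!n) NA_real_
         else if (amplitude_mode == "absolute") mean(pr)
         else mean(pr - peaks@baseline_ratio)
  new("OscillationSummary",
      n_peaks = as.integer(n),
      frequency_per_min = n / duration_min,
      mean_peak_amplitude = amp,
      duration_min = duration_min,
      oscillating = n >= min_peaks_oscillating,
      cell_id = cell_id,
      group_label = as.character(group_label),
      amplitude_mode = amplitude_mode)
}

#' Fraction of cells showing calcium oscillations, with a binomial CI
#'
#' Percentage of cells classified as oscillating within a condition, with a
#' Clopper-Pearson exact binomial confidence interval
#' (via [stats::binom.test()]).
#'
#' @param summaries a list of [OscillationSummary-class] objects or a
#'   data.frame with columns `oscillating` and (optionally) `group_label`.
#' @param group_label restrict to one group label (NULL = all cells).
#' @param conf_level confidence level (default 0.95).
#' @return a one-row data.frame: group_label, n, n_oscillating,
#'   fraction_pct, ci_lo_pct, ci_hi_pct, ci_method.
#' @examples
#' responderFraction(data.frame(oscillating = rep(FALSE, 10)))$fraction_pct
#' @export
responderFraction <- function(summaries, group_label = NULL,
                              conf_level = 0.95) {
  df <- if (is.data.frame(summaries)) summaries
        else summariesToDataFrame(summaries)
  if (!is.null(group_label)) {
    df <- df[df$group_label %in% group_label, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty group")
  x <- sum(df$oscillating)
  n <- nrow(df)
  ci <- binom.test(x, n, conf.level = conf_level)$conf.int
  data.frame(
    group_label = if (is.null(group_label)) "all" else group_label,
    n = n, n_oscillating = x,
    fraction_pct = 100 * x / n,
    ci_lo_pct = 100 * ci[1], ci_hi_pct = 100 * ci[2],
    ci_method = "Clopper-Pearson"
  )
}

#' Restrict a trace to a time window
#'
#' @param trace a [RatioTrace-class].
#' @param t_start_s,t_end_s window bounds (s), inclusive.
#' @return a [RatioTrace-class] containing the frames inside the window.
#' @export
subsetTrace <- function(trace, t_start_s, t_end_s) {
  stopifnot(is(trace, "RatioTrace"), t_end_s > t_start_s)
  sel <- trace@times_s >= t_start_s & trace@times_s <= t_end_s
  if (!any(sel)) stop("window contains no frames")
  new("RatioTrace", times_s = trace@times_s[sel], ratio = trace@ratio[sel],
      valid = trace@valid[sel], roi_id = trace@roi_id)
}

#' Compare oscillation metrics between labeled time segments
#'
#' Computes oscillation summaries independently within each labeled window
#' (e.g. "loading" vs "unloading" phases of a stretch experiment) for one or
#' more cells, then compares a chosen metric between the first two segments
#' with a two-group t-test (see [twoGroupTTest()]).  Segments must not
#' overlap and must each span at least one minute.
#'
#' @param traces a [RatioTrace-class] or list thereof (one per cell).
#' @param segments named list of c(start_s, end_s) windows.
#' @param metric metric to compare: "frequency_per_min" (default),
#'   "mean_peak_amplitude" or "n_peaks".
#' @param paired paired t-test across cells? (default FALSE).
#' @param prominence_threshold,min_separation_s passed to [detectPeaks()].
#' @param ... passed to [summarizeOscillations()].
#' @return list with `summaries` (data.frame: one row per cell x segment)
#'   and `comparison` (a [GroupComparison-class], or NULL with fewer than
#'   two segments or fewer than 2 cells).
#' @export
segmentCompare <- function(traces, segments, metric = "frequency_per_min",
                           paired = FALSE, prominence_threshold = 0.1,
                           min_separation_s = 20, ...) {
  if (is(traces, "RatioTrace")) traces <- list(traces)
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    stop("segments must be a named list of c(start_s, end_s)")
  }
  segm <- do.call(rbind, segments)
  if (any(segm[, 2] <= segm[, 1])) stop("segment end must exceed start")
  if (nrow(segm) > 1) {
    o <- order(segm[, 1])
    if (any(segm[o, 1][-1] < segm[o, 2][-nrow(segm)])) {
      stop("overlapping segments")
    }
  }
  rows <- list()
  for (ci in seq_along(traces)) {
    tr <- traces[[ci]]
    for (sg in names(segments)) {
      sub <- subsetTrace(tr, segments[[sg]][1], segments[[sg]][2])
      pk <- detectPeaks(sub, prominence_threshold, min_separation_s)
      sm <- summarizeOscillations(pk, sub, group_label = sg, ...)
      row <- as.data.frame.OscillationSummary(sm)
      row$segment <- sg
      rows[[length(rows) + 1L]] <- row
    }
  }
  summaries <- do.call(rbind, rows)
  comparison <- NULL
  if (length(segments) >= 2) {
    s1 <- names(segments)[1]
    s2 <- names(segments)[2]
    a <- summaries[summaries$segment == s1, metric]
    b <- summaries[summaries$segment == s2, metric]
    if (length(a) >= 2 && length(b) >= 2) {
      comparison <- twoGroupTTest(a, b, paired = paired,
                                  labels = c(s1, s2), metric = metric)
    }
  }
  list(summaries = summaries, comparison = comparison)
}
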