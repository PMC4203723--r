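#' @include AllClasses.R
NULL

#' Construct a calcium-trace model
#'
#' Parameter bundle for [simulateTrace()].  Defaults describe a cell imaged
#' for 10 minutes at a 10 s frame interval, oscillating at 2 peaks/min with
#' transients of 0.5 ratio units (rise 2 s, decay 15 s) on a baseline ratio
#' of 1, with 20\% inter-peak interval jitter.
#'
#' @param duration_s total duration (s).
#' @param frame_interval_s sampling interval (s).
#' @param baseline_ratio baseline emission ratio.
#' @param peak_amplitude transient height above baseline (ratio units).
#' @param frequency_per_min nominal peaks per minute (0 = silent cell).
#' @param rise_s,decay_s transient rise/decay time constants (s).
#' @param jitter_frac fractional inter-peak interval jitter in [0, 1).
#' @param onset_s time of the first transient (s).
#' @param seed integer seed.
#' @return a [CalciumTraceModel-class].
#' @examples
#' m <- calciumTraceModel(duration_s = 300, frequency_per_min = 2,
#'                        jitter_frac = 0)
#' tr <- simulateTrace(m)
#' length(tr@event_times_s)  # 10 transients: 2/min x 5 min
#' @export
calciumTraceModel <- function(duration_s = 600, frame_interval_s = 10,
                              baseline_ratio = 1, peak_amplitude = 0.5,
                              frequency_per_min = 2, rise_s = 2, decay_s = 15,
                              jitter_frac = 0.2, onset_s = 15, seed = 1L) {
  .assertScalar(duration_s, "duration_s", positive = TRUE)
  .assertScalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  new("CalciumTraceModel",
      duration_s = duration_s, frame_interval_s = frame_interval_s,
      baseline_ratio = baseline_ratio, peak_amplitude = peak_amplitude,
      frequency_per_min = frequency_per_min, rise_s = rise_s,
      decay_s = decay_s, jitter_frac = jitter_frac, onset_s = onset_s,
      seed = as.integer(seed))
}

# Double-exponential transient kernel, normalized to unit peak height.
# h(t) = (exp(-t/decay) - exp(-t/rise)) / hmax for t >= 0, 0 before.
.pulseKernel <- function(t, rise_s, decay_s) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (abs(rise_s - decay_s) < 1e-12) {
    # limiting form t/tau * exp(1 - t/tau), peak 1 at t = tau
    out[pos] <- (tp / rise_s) * exp(1 - tp / rise_s)
  } else {
    tpk <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
    hmax <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
    out[pos] <- (exp(-tp / decay_s) - exp(-tp / rise_s)) / hmax
  }
  out
}

# Ratio signal at arbitrary times.  Overlapping transients combine by
# maximum, not sum, so every peak reads exactly baseline + peak_amplitude
# (with a pure sum, the decay tail of one transient would inflate the next
# peak above the nominal amplitude).
.traceSignal <- function(times_s, event_times_s, model) {
  k <- numeric(length(times_s))
  for (ev in event_times_s) {
    k <- pmax(k, .pulseKernel(times_s - ev, model@rise_s, model@decay_s))
  }
  model@baseline_ratio + model@peak_amplitude * k
}

#' Simulate a single-cell calcium ratio trace
#'
#' Draws transient onset times starting at `onset_s` with inter-event
#' intervals 60/frequency * (1 + jitter_frac * U(-1, 1)), then samples
#' baseline + amplitude * kernel sums at the frame interval.  With
#' `jitter_frac = 0` the number of transients equals the nominal
#' frequency times the duration (within one event).  Identical seeds give
#' bit-identical traces.
#'
#' @param model a [CalciumTraceModel-class].
#' @return a [CalciumTrace-class] with the sampled series, the ground-truth
#'   event times, and the model (so the continuous signal can be
#'   re-evaluated, see [traceAt()]).
#' @examples
#' tr <- simulateTrace(calciumTraceModel(frequency_per_min = 0))
#' all(ratioValues(tr) == 1)  # silent cell: flat at baseline
#' @export
simulateTrace <- function(model) {
  stopifnot(is(model, "CalciumTraceModel"))
  validObject(model)
  events <- withSeed(model@seed, {
    ev <- numeric(0)
    if (model@frequency_per_min > 0 && model@peak_amplitude > 0) {
      mean_interval <- 60 / model@frequency_per_min
      t <- model@onset_s
      while (t < model@duration_s) {
        ev <- c(ev, t)
        t <- t + mean_interval *
          (1 + model@jitter_frac * runif(1, -1, 1))
      }
    }
    ev
  })
  times <- seq(0, model@duration_s, by = model@frame_interval_s)
  new("CalciumTrace",
      times_s = times,
      ratio = .traceSignal(times, events, model),
      event_times_s = events,
      model = model)
}

#' Evaluate the continuous ground-truth signal of a synthetic trace
#'
#' Evaluates the underlying baseline-plus-transients signal of a
#' [CalciumTrace-class] at arbitrary times (used e.g. by [renderStack()] to
#' delay-shift the signal per pixel for a propagating onset).
#'
#' @param trace a [CalciumTrace-class] from [simulateTrace()].
#' @param times_s numeric vector of evaluation times (s); times before the
#'   first event return the baseline.
#' @return numeric vector of emission-ratio values.
#' @export
traceAt <- function(trace, times_s) {
  stopifnot(is(trace, "CalciumTrace"))
  .traceSignal(times_s, trace@event_times_s, trace@model)
}

#' Convert a synthetic trace to an analysis-ready RatioTrace
#'
#' @param trace a [CalciumTrace-class].
#' @param roi_id identifier for the resulting trace.
#' @return a [RatioTrace-class] with all frames valid.
#' @export
asRatioTrace <- function(trace, roi_id = "cell1") {
  stopifnot(is(trace, "CalciumTrace"))
  new("RatioTrace", times_s = trace@times_s, ratio = trace@ratio,
      valid = rep(TRUE, length(trace@times_s)), roi_id = roi_id)
}
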