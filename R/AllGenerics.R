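#' @include AllClasses.R
NULL

#' Accessors for stretchFRET objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: `traceTimes`/`ratioValues` for time series, `peakTimes`/
#' `peakRatios` for [PeakSet-class], `frequencyPerMin`/`meanPeakAmplitude`/
#' `isOscillating` for [OscillationSummary-class], `totalStrain`/
#' `peakStrain`/`stressPa` for [StrainMap-class], and `pairwiseResults` for
#' [GroupComparison-class].
#'
#' @param object an object of the documented class.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("ratioValues", function(object) standardGeneric("ratioValues"))
#' @rdname accessors
#' @export
setGeneric("validFrames", function(object) standardGeneric("validFrames"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("peakRatios", function(object) standardGeneric("peakRatios"))
#' @rdname accessors
#' @export
setGeneric("frequencyPerMin",
           function(object) standardGeneric("frequencyPerMin"))
#' @rdname accessors
#' @export
setGeneric("meanPeakAmplitude",
           function(object) standardGeneric("meanPeakAmplitude"))
#' @rdname accessors
#' @export
setGeneric("isOscillating", function(object) standardGeneric("isOscillating"))
#' @rdname accessors
#' @export
setGeneric("totalStrain", function(object) standardGeneric("totalStrain"))
#' @rdname accessors
#' @export
setGeneric("peakStrain", function(object) standardGeneric("peakStrain"))
#' @rdname accessors
#' @export
setGeneric("stressPa", function(object) standardGeneric("stressPa"))
#' @rdname accessors
#' @export
setGeneric("pairwiseResults",
           function(object) standardGeneric("pairwiseResults"))

#' @rdname accessors
#' @export
setMethod("traceTimes", "CalciumTrace", function(object) object@times_s)
#' @rdname accessors
#' @export
setMethod("traceTimes", "RatioTrace", function(object) object@times_s)
#' @rdname accessors
#' @export
setMethod("ratioValues", "CalciumTrace", function(object) object@ratio)
#' @rdname accessors
#' @export
setMethod("ratioValues", "RatioTrace", function(object) object@ratio)
#' @rdname accessors
#' @export
setMethod("validFrames", "RatioTrace", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("peakTimes", "PeakSet", function(object) object@peak_times_s)
#' @rdname accessors
#' @export
setMethod("peakRatios", "PeakSet", function(object) object@peak_ratios)
#' @rdname accessors
#' @export
setMethod("frequencyPerMin", "OscillationSummary",
          function(object) object@frequency_per_min)
#' @rdname accessors
#' @export
setMethod("meanPeakAmplitude", "OscillationSummary",
          function(object) object@mean_peak_amplitude)
#' @rdname accessors
#' @export
setMethod("isOscillating", "OscillationSummary",
          function(object) object@oscillating)
#' @rdname accessors
#' @export
setMethod("totalStrain", "StrainMap", function(object) object@E_total)
#' @rdname accessors
#' @export
setMethod("peakStrain", "StrainMap", function(object) object@peak_strain)
#' @rdname accessors
#' @export
setMethod("stressPa", "StrainMap", function(object) object@stress_pa)
#' @rdname accessors
#' @export
setMethod("pairwiseResults", "GroupComparison",
          function(object) object@pairwise)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf(
    "CalciumTrace: %d frames over %.1f s (interval %.1f s), %d transients\n",
    length(object@times_s), object@model@duration_s,
    object@model@frame_interval_s, length(object@event_times_s)
  ))
  cat(sprintf("  baseline %.3f, amplitude %.3f, nominal %.2f peaks/min\n",
              object@model@baseline_ratio, object@model@peak_amplitude,
              object@model@frequency_per_min))
})

setMethod("show", "FretStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "FretStack: %d x %d px, %d channels, %d frames (%.2f um/px, %.1f s/frame)\n",
    d[1], d[2], d[3], d[4], object@meta@pixel_size_um,
    object@meta@frame_interval_s
  ))
})

setMethod("show", "RatioTrace", function(object) {
  cat(sprintf(
    "RatioTrace '%s': %d frames (%d valid), t = [%.1f, %.1f] s\n",
    object@roi_id, length(object@times_s), sum(object@valid),
    min(object@times_s), max(object@times_s)
  ))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf(
    "PeakSet: %d peaks (baseline %.3f, prominence >= %.3f, separation >= %.0f s)\n",
    length(object@peak_times_s), object@baseline_ratio,
    object@prominence_threshold, object@min_separation_s
  ))
})

setMethod("show", "OscillationSummary", function(object) {
  cat(sprintf(
    "OscillationSummary '%s' [%s]: %d peaks in %.1f min -> %.3f /min, amplitude %.3f (%s), %s\n",
    object@cell_id, object@group_label, object@n_peaks, object@duration_min,
    object@frequency_per_min, object@mean_peak_amplitude,
    object@amplitude_mode,
    if (object@oscillating) "oscillating" else "not oscillating"
  ))
})

setMethod("show", "BeadMatchSet", function(object) {
  cat(sprintf(
    "BeadMatchSet: %d matched pairs (%d ref / %d loaded unmatched), radius %.1f um\n",
    nrow(object@ref_xy_um), object@unmatched_ref, object@unmatched_loaded,
    object@max_search_radius_um
  ))
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@ux_um^2 + object@uy_um^2)
  cat(sprintf(
    "DisplacementField: %d x %d grid at %.1f um spacing, |u| in [%.3f, %.3f] um\n",
    length(object@grid_y_um), length(object@grid_x_um),
    object@grid_spacing_um, min(mag), max(mag)
  ))
})

setMethod("show", "StrainMap", function(object) {
  cat(sprintf(
    "StrainMap (%s strain): peak strain index %.4f",
    object@definition, object@peak_strain
  ))
  if (is.finite(object@young_modulus_pa)) {
    cat(sprintf(", stress %.0f N/m^2 on a %.0f Pa substrate",
                object@stress_pa, object@young_modulus_pa))
  }
  cat("\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of '%s' by %s (%.0f%% confidence)\n",
              object@metric, object@method, 100 * object@conf_level))
  print(object@groups, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("Pairwise:\n")
    print(object@pairwise, row.names = FALSE)
  }
})

# ---------------------------------------------------------------------------
# data.frame coercions
# ---------------------------------------------------------------------------

#' Coerce stretchFRET objects to data.frame
#'
#' @param x object to coerce.
#' @param row.names,optional,... ignored, present for generic compatibility.
#' @return a base data.frame.
#' @name as.data.frame-methods
NULL

#' @rdname as.data.frame-methods
#' @export
as.data.frame.RatioTrace <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(time_s = x@times_s, ratio = x@ratio, valid = x@valid,
             roi_id = x@roi_id)
}

#' @rdname as.data.frame-methods
#' @export
as.data.frame.OscillationSummary <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(
    cell_id = x@cell_id, group_label = x@group_label, n_peaks = x@n_peaks,
    frequency_per_min = x@frequency_per_min,
    mean_peak_amplitude = x@mean_peak_amplitude,
    duration_min = x@duration_min, oscillating = x@oscillating
  )
}

#' @rdname as.data.frame-methods
#' @export
as.data.frame.DisplacementField <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  g <- expand.grid(y_um = x@grid_y_um, x_um = x@grid_x_um)
  data.frame(x_um = g$x_um, y_um = g$y_um,
             ux_um = as.vector(x@ux_um), uy_um = as.vector(x@uy_um))
}

#' @rdname as.data.frame-methods
#' @export
as.data.frame.StrainMap <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  g <- expand.grid(y_um = x@grid_y_um, x_um = x@grid_x_um)
  data.frame(x_um = g$x_um, y_um = g$y_um, Ex = as.vector(x@Ex),
             Ey = as.vector(x@Ey), E_total = as.vector(x@E_total))
}

#' Collect per-cell oscillation summaries into a data.frame
#'
#' @param summaries a list of [OscillationSummary-class] objects.
#' @return one row per cell with columns cell_id, group_label, n_peaks,
#'   frequency_per_min, mean_peak_amplitude, duration_min, oscillating.
#' @export
summariesToDataFrame <- function(summaries) {
  if (is(summaries, "OscillationSummary")) summaries <- list(summaries)
  stopifnot(length(summaries) > 0)
  do.call(rbind, lapply(summaries, as.data.frame.OscillationSummary))
}
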