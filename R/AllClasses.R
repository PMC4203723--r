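#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# synthgen types
# ---------------------------------------------------------------------------

#' Parameter model for a synthetic single-cell calcium trace
#'
#' Describes a calcium-reporter emission-ratio time course as a flat baseline
#' plus repeated transients (double-exponential rise/decay pulses) occurring
#' at a nominal frequency, with optional fractional jitter of the inter-peak
#' intervals.  Units: seconds for all times, peaks per minute for the
#' frequency, dimensionless emission-ratio units for baseline and amplitude.
#'
#' @slot duration_s total simulated duration (s); must be > 0.
#' @slot frame_interval_s sampling interval (s); default 10 s, the typical
#'   acquisition interval for this kind of experiment.
#' @slot baseline_ratio emission ratio between transients.
#' @slot peak_amplitude transient height above baseline (ratio units), >= 0.
#' @slot frequency_per_min nominal number of transients per minute, >= 0.
#' @slot rise_s,decay_s rise and decay time constants of the transient (s).
#' @slot jitter_frac fractional randomization of inter-peak intervals in
#'   [0, 1): each interval is 60/frequency * (1 + jitter_frac * U(-1, 1)).
#' @slot onset_s time of the first transient (s).
#' @slot seed integer seed; all randomness of the trace derives from it.
#'
#' @seealso [calciumTraceModel()], [simulateTrace()]
#' @export
setClass("CalciumTraceModel",
  slots = c(
    duration_s = "numeric",
    frame_interval_s = "numeric",
    baseline_ratio = "numeric",
    peak_amplitude = "numeric",
    frequency_per_min = "numeric",
    rise_s = "numeric",
    decay_s = "numeric",
    jitter_frac = "numeric",
    onset_s = "numeric",
    seed = "integer"
  ),
  prototype = list(
    duration_s = 600, frame_interval_s = 10, baseline_ratio = 1,
    peak_amplitude = 0.5, frequency_per_min = 2, rise_s = 2, decay_s = 15,
    jitter_frac = 0.2, onset_s = 15, seed = 1L
  ),
  validity = function(object) {
    msg <- character()
    if (object@duration_s <= 0) msg <- c(msg, "duration_s must be > 0")
    if (object@frame_interval_s <= 0) {
      msg <- c(msg, "frame_interval_s must be > 0")
    }
    if (object@peak_amplitude < 0) msg <- c(msg, "peak_amplitude must be >= 0")
    if (object@frequency_per_min < 0) {
      msg <- c(msg, "frequency_per_min must be >= 0")
    }
    if (object@jitter_frac < 0 || object@jitter_frac >= 1) {
      msg <- c(msg, "jitter_frac must be in [0, 1)")
    }
    if (object@rise_s <= 0 || object@decay_s <= 0) {
      msg <- c(msg, "rise_s and decay_s must be > 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic calcium trace with ground truth
#'
#' Result of [simulateTrace()]: the sampled emission-ratio series plus the
#' underlying event (transient onset) times and the generating model, so that
#' the continuous-time ground truth can be re-evaluated at arbitrary times
#' (see [traceAt()]).
#'
#' @slot times_s frame acquisition times (s).
#' @slot ratio emission ratio at each frame.
#' @slot event_times_s ground-truth transient onset times (s).
#' @slot model the generating [CalciumTraceModel-class].
#' @export
setClass("CalciumTrace",
  slots = c(
    times_s = "numeric",
    ratio = "numeric",
    event_times_s = "numeric",
    model = "CalciumTraceModel"
  ),
  validity = function(object) {
    if (length(object@times_s) != length(object@ratio)) {
      return("times_s and ratio must have equal length")
    }
    TRUE
  }
)

#' Rendering specification for a two-channel FRET stack
#'
#' How a ground-truth calcium trace is turned into a donor/FRET image stack.
#' The two channels share a per-pixel photon budget (donor_base + fret_base)
#' that is split so the noiseless background-subtracted FRET/donor ratio
#' equals the calcium signal exactly; raising the ratio moves photons from
#' the donor to the FRET channel (sensitized emission).  A nonzero
#' wave_speed_um_s delays the calcium onset at each pixel by its distance
#' from wave_origin divided by the speed, emulating a calcium wave that
#' starts at the edge proximal to the stretch probe and propagates distally.
#'
#' @slot cell_mask logical matrix (rows = y, cols = x); TRUE inside the cell.
#' @slot pixel_size_um physical pixel size (um/pixel).
#' @slot donor_base,fret_base baseline photon counts per channel inside the
#'   cell; their sum is the conserved per-pixel photon budget.
#' @slot gain_anticorr fraction of the calcium-driven ratio modulation that
#'   is rendered (1 = full anti-correlated modulation).
#' @slot wave_speed_um_s propagation speed of the calcium onset (um/s);
#'   0 means synchronous onset over the whole mask.
#' @slot wave_origin pixel coordinate c(x, y) (0-based pixel centers) of the
#'   proximal onset point.
#' @slot background additive background counts in both channels.
#' @slot read_noise_sd Gaussian read noise sd (counts); 0 disables it.
#' @slot poisson_noise apply Poisson photon noise to the counts?
#' @slot seed integer seed for all rendering noise.
#' @seealso [cellRenderSpec()], [renderStack()]
#' @export
setClass("CellRenderSpec",
  slots = c(
    cell_mask = "matrix",
    pixel_size_um = "numeric",
    donor_base = "numeric",
    fret_base = "numeric",
    gain_anticorr = "numeric",
    wave_speed_um_s = "numeric",
    wave_origin = "numeric",
    background = "numeric",
    read_noise_sd = "numeric",
    poisson_noise = "logical",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@cell_mask)) {
      msg <- c(msg, "cell_mask must be a logical matrix")
    } else if (!any(object@cell_mask)) {
      msg <- c(msg, "cell_mask must contain at least one TRUE pixel")
    }
    if (object@background < 0) msg <- c(msg, "background must be >= 0")
    if (object@donor_base <= object@background ||
        object@fret_base <= object@background) {
      msg <- c(msg, "donor_base and fret_base must exceed background")
    }
    if (object@wave_speed_um_s < 0) {
      msg <- c(msg, "wave_speed_um_s must be >= 0")
    }
    if (length(object@wave_origin) != 2L) {
      msg <- c(msg, "wave_origin must be c(x, y)")
    }
    if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Acquisition metadata for a two-channel stack
#'
#' @slot frame_interval_s nominal frame interval (s).
#' @slot pixel_size_um physical pixel size (um/pixel).
#' @slot channel_roles named integer vector mapping c(donor=, fret=) to
#'   channel indices; the two roles must be distinct.
#' @slot times_s per-frame acquisition times (s).  May contain gaps larger
#'   than frame_interval_s (e.g. an acquisition pause while the probe tip is
#'   placed); all downstream metrics use these real elapsed times, never
#'   frame counts.
#' @export
setClass("StackMeta",
  slots = c(
    frame_interval_s = "numeric",
    pixel_size_um = "numeric",
    channel_roles = "integer",
    times_s = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@frame_interval_s <= 0) {
      msg <- c(msg, "frame_interval_s must be > 0")
    }
    roles <- object@channel_roles
    if (!all(c("donor", "fret") %in% names(roles))) {
      msg <- c(msg, "channel_roles must name both 'donor' and 'fret'")
    } else if (roles[["donor"]] == roles[["fret"]]) {
      msg <- c(msg, "donor and fret must map to distinct channels")
    }
    if (length(object@times_s) > 1 && any(diff(object@times_s) <= 0)) {
      msg <- c(msg, "times_s must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Two-channel fluorescence image stack
#'
#' Pixel data are stored as a 4-D array indexed [y, x, channel, frame]
#' (image convention: origin top-left, x along columns, y along rows).
#' Stacks produced by [renderStack()] also carry the per-pixel ground-truth
#' onset delay raster and the generating trace.
#'
#' @slot data numeric array [y, x, channel, frame] of counts.
#' @slot meta a [StackMeta-class].
#' @slot onset_delay_s ground-truth per-pixel onset delay (s); empty matrix
#'   for stacks read from disk.
#' @slot truth list with the generating CalciumTrace and CellRenderSpec for
#'   synthetic stacks; empty list otherwise.
#' @export
setClass("FretStack",
  slots = c(
    data = "array",
    meta = "StackMeta",
    onset_delay_s = "matrix",
    truth = "list"
  ),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) {
      return("data must be a 4-D array [y, x, channel, frame]")
    }
    if (max(object@meta@channel_roles) > d[3]) {
      return("channel_roles index beyond available channels")
    }
    if (length(object@meta@times_s) &&
        length(object@meta@times_s) != d[4]) {
      return("meta times_s length must equal the number of frames")
    }
    TRUE
  }
)

# ---------------------------------------------------------------------------
# ratiometric types
# ---------------------------------------------------------------------------

#' Per-pixel emission-ratio stack with validity mask
#'
#' @slot ratio numeric array [y, x, frame]; FRET/donor emission ratio.
#' @slot valid logical array of the same shape; FALSE where the
#'   background-subtracted donor signal fell below the intensity floor (the
#'   division guard) and the ratio is undefined.
#' @slot meta the originating [StackMeta-class].
#' @export
setClass("RatioStack",
  slots = c(ratio = "array", valid = "array", meta = "StackMeta"),
  validity = function(object) {
    if (!identical(dim(object@ratio), dim(object@valid))) {
      return("ratio and valid must have identical dimensions")
    }
    if (any(!is.finite(object@ratio[object@valid]))) {
      return("valid pixels must have finite ratios")
    }
    TRUE
  }
)

#' Single-ROI emission-ratio time series
#'
#' @slot times_s per-frame acquisition time (s), strictly increasing;
#'   may contain gaps (acquisition pauses).
#' @slot ratio FRET/donor emission ratio per frame.
#' @slot valid logical; FALSE for frames excluded from analysis.
#' @slot roi_id identifier of the ROI / cell.
#' @export
setClass("RatioTrace",
  slots = c(
    times_s = "numeric",
    ratio = "numeric",
    valid = "logical",
    roi_id = "character"
  ),
  validity = function(object) {
    n <- length(object@times_s)
    if (length(object@ratio) != n || length(object@valid) != n) {
      return("times_s, ratio and valid must have equal length")
    }
    if (n > 1 && any(diff(object@times_s) <= 0)) {
      return("times_s must be strictly increasing")
    }
    ok <- object@ratio[object@valid]
    if (any(!is.finite(ok)) || any(ok <= 0)) {
      return("ratio must be finite and > 0 on valid frames")
    }
    TRUE
  }
)

# ---------------------------------------------------------------------------
# oscillometry types
# ---------------------------------------------------------------------------

#' Detected calcium peaks of one trace
#'
#' @slot peak_times_s peak times (s), strictly increasing.
#' @slot peak_ratios emission-ratio value at each peak.
#' @slot baseline_ratio baseline estimate (10th percentile of valid ratios).
#' @slot prominence_threshold minimum height above baseline required of a
#'   peak (ratio units).
#' @slot min_separation_s minimum time between retained peaks (s).
#' @export
setClass("PeakSet",
  slots = c(
    peak_times_s = "numeric",
    peak_ratios = "numeric",
    baseline_ratio = "numeric",
    prominence_threshold = "numeric",
    min_separation_s = "numeric"
  ),
  validity = function(object) {
    if (length(object@peak_times_s) != length(object@peak_ratios)) {
      return("peak_times_s and peak_ratios must have equal length")
    }
    if (length(object@peak_times_s) > 1 &&
        any(diff(object@peak_times_s) <= 0)) {
      return("peak_times_s must be strictly increasing")
    }
    if (length(object@peak_ratios) &&
        any(object@peak_ratios <
            object@baseline_ratio + object@prominence_threshold - 1e-12)) {
      return("every peak_ratio must be >= baseline + prominence_threshold")
    }
    TRUE
  }
)

#' Oscillation metrics of one cell
#'
#' Frequency is the number of detected peaks divided by the valid observation
#' time in minutes; amplitude is, by default, the mean emission-ratio value
#' at the peaks (the absolute-peak convention), optionally baseline
#' subtracted.  A cell is classified as oscillating when it shows at least
#' two peaks in the observation window (a single transient is not an
#' oscillation).
#'
#' @slot n_peaks number of peaks counted.
#' @slot frequency_per_min peaks per minute of valid observation time.
#' @slot mean_peak_amplitude mean peak ratio (or baseline-subtracted mean,
#'   see amplitude_mode); NA when no peaks.
#' @slot duration_min valid observation time (min).
#' @slot oscillating logical classification.
#' @slot cell_id,group_label identifiers (group e.g. "PMS", "PMS+GdCl3").
#' @slot amplitude_mode "absolute" or "baseline_subtracted".
#' @export
setClass("OscillationSummary",
  slots = c(
    n_peaks = "integer",
    frequency_per_min = "numeric",
    mean_peak_amplitude = "numeric",
    duration_min = "numeric",
    oscillating = "logical",
    cell_id = "character",
    group_label = "character",
    amplitude_mode = "character"
  ),
  validity = function(object) {
    if (object@duration_min > 0 &&
        abs(object@frequency_per_min -
            object@n_peaks / object@duration_min) > 1e-9) {
      return("frequency_per_min must equal n_peaks / duration_min")
    }
    if (object@oscillating && object@n_peaks < 2L) {
      return("oscillating requires at least 2 peaks")
    }
    TRUE
  }
)

# ---------------------------------------------------------------------------
# substrate mechanics types
# ---------------------------------------------------------------------------

#' Tip-pull substrate deformation model
#'
#' Displacement of the gel surface when a probe tip inserted at tip_xy_um is
#' pulled by pull_vector_um: u(x, y) = pull_vector *
#' exp(-||(x, y) - tip||^2 / (2 * decay_sigma_um^2)), an isotropic Gaussian
#' decay around the tip with closed-form strain.
#'
#' @slot tip_xy_um probe position c(x, y) in um.
#' @slot pull_vector_um direction and magnitude of the maximal displacement.
#' @slot decay_sigma_um spatial decay length (um), > 0.
#' @slot bead_density_per_um2 fiducial bead density (beads/um^2).
#' @slot localization_noise_um sd of bead centroid localization noise (um).
#' @slot seed integer seed for bead placement and localization noise.
#' @seealso [tipPullField()], [simulateBeadPair()]
#' @export
setClass("TipPullField",
  slots = c(
    tip_xy_um = "numeric",
    pull_vector_um = "numeric",
    decay_sigma_um = "numeric",
    bead_density_per_um2 = "numeric",
    localization_noise_um = "numeric",
    seed = "integer"
  ),
  prototype = list(
    tip_xy_um = c(0, 0), pull_vector_um = c(10, 0), decay_sigma_um = 50,
    bead_density_per_um2 = 0.02, localization_noise_um = 0.05, seed = 1L
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@tip_xy_um) != 2L || length(object@pull_vector_um) != 2L) {
      msg <- c(msg, "tip_xy_um and pull_vector_um must be length-2 c(x, y)")
    }
    if (object@decay_sigma_um <= 0) msg <- c(msg, "decay_sigma_um must be > 0")
    if (object@bead_density_per_um2 <= 0) {
      msg <- c(msg, "bead_density_per_um2 must be > 0")
    }
    if (object@localization_noise_um < 0) {
      msg <- c(msg, "localization_noise_um must be >= 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Matched bead pairs between reference and loaded frames
#'
#' @slot ref_xy_um,loaded_xy_um matched coordinates (row i of one corresponds
#'   to row i of the other); each an n x 2 matrix (x_um, y_um).
#' @slot unmatched_ref,unmatched_loaded counts of beads left unmatched.
#' @slot max_search_radius_um maximum allowed pair distance (um).
#' @export
setClass("BeadMatchSet",
  slots = c(
    ref_xy_um = "matrix",
    loaded_xy_um = "matrix",
    unmatched_ref = "integer",
    unmatched_loaded = "integer",
    max_search_radius_um = "numeric"
  ),
  validity = function(object) {
    if (!identical(dim(object@ref_xy_um), dim(object@loaded_xy_um))) {
      return("ref and loaded matched coordinates must have equal dimensions")
    }
    if (nrow(object@ref_xy_um)) {
      d <- sqrt(rowSums((object@loaded_xy_um - object@ref_xy_um)^2))
      if (any(d > object@max_search_radius_um + 1e-9)) {
        return("per-pair displacement exceeds max_search_radius_um")
      }
    }
    TRUE
  }
)

#' Gridded substrate displacement field
#'
#' @slot grid_x_um,grid_y_um regular grid node coordinates (um).
#' @slot ux_um,uy_um displacement components at the nodes, matrices indexed
#'   [y, x] (um); finite everywhere.
#' @slot grid_spacing_um node spacing (um).
#' @export
setClass("DisplacementField",
  slots = c(
    grid_x_um = "numeric",
    grid_y_um = "numeric",
    ux_um = "matrix",
    uy_um = "matrix",
    grid_spacing_um = "numeric"
  ),
  validity = function(object) {
    dm <- c(length(object@grid_y_um), length(object@grid_x_um))
    if (!all(dim(object@ux_um) == dm) || !all(dim(object@uy_um) == dm)) {
      return("ux_um and uy_um must be [length(grid_y), length(grid_x)]")
    }
    if (any(!is.finite(object@ux_um)) || any(!is.finite(object@uy_um))) {
      return("displacement components must be finite everywhere")
    }
    TRUE
  }
)

#' Substrate strain-index map with peak strain and stress
#'
#' Normal strain components Ex = d(ux)/dx and Ey = d(uy)/dy (small-strain
#' definition; a Green-strain variant is available) and the total strain
#' index E_total = sqrt(Ex^2 + Ey^2).  Stress is peak strain times the
#' substrate Young's modulus (S = strain x E, in N/m^2 = Pa).
#'
#' @slot grid_x_um,grid_y_um grid node coordinates (um).
#' @slot Ex,Ey dimensionless normal strain components, matrices [y, x].
#' @slot E_total total strain index, >= 0.
#' @slot peak_strain maximum E_total over the query region.
#' @slot young_modulus_pa substrate Young's modulus (Pa); NA when the map is
#'   a pure-geometry ground truth.
#' @slot stress_pa peak_strain * young_modulus_pa (Pa).
#' @slot definition "small" or "green".
#' @export
setClass("StrainMap",
  slots = c(
    grid_x_um = "numeric",
    grid_y_um = "numeric",
    Ex = "matrix",
    Ey = "matrix",
    E_total = "matrix",
    peak_strain = "numeric",
    young_modulus_pa = "numeric",
    stress_pa = "numeric",
    definition = "character"
  ),
  validity = function(object) {
    if (any(object@E_total < -1e-12)) return("E_total must be >= 0")
    if (any(object@E_total + 1e-9 <
            pmax(abs(object@Ex), abs(object@Ey)) / sqrt(2))) {
      return("E_total must be >= max(|Ex|, |Ey|)/sqrt(2) at every node")
    }
    if (is.finite(object@young_modulus_pa) &&
        abs(object@stress_pa -
            object@peak_strain * object@young_modulus_pa) > 1e-6) {
      return("stress_pa must equal peak_strain * young_modulus_pa")
    }
    TRUE
  }
)

#' Synthetic bead-pair experiment with analytic ground truth
#'
#' Result of [simulateBeadPair()]: true and observed (localization-noise
#' corrupted) bead coordinates for the reference and loaded frames, plus the
#' analytic displacement field and strain map of the generating tip-pull
#' model evaluated on a regular grid.  Row i of every coordinate matrix is
#' the same physical bead, so the ground-truth correspondence is the row
#' pairing.  The analytic ground truth excludes localization noise.
#'
#' @slot ref_true,loaded_true noise-free bead coordinates (n x 2, um).
#' @slot ref_obs,loaded_obs observed coordinates with localization noise.
#' @slot field analytic [DisplacementField-class] of the tip-pull model.
#' @slot strain analytic [StrainMap-class] (exact differentiation of u).
#' @slot model the generating [TipPullField-class].
#' @slot region_um region extent c(xmin, xmax, ymin, ymax).
#' @export
setClass("BeadPairSim",
  slots = c(
    ref_true = "matrix",
    loaded_true = "matrix",
    ref_obs = "matrix",
    loaded_obs = "matrix",
    field = "DisplacementField",
    strain = "StrainMap",
    model = "TipPullField",
    region_um = "numeric"
  )
)

# ---------------------------------------------------------------------------
# statistics types
# ---------------------------------------------------------------------------

#' Group comparison of an oscillation metric
#'
#' Per-group sample sizes, means and standard deviations together with
#' pairwise test results: mean differences with confidence intervals at the
#' (Bonferroni-adjusted, for multiple comparison) 95\% level, p-values and a
#' significance flag.
#'
#' @slot metric name of the compared metric.
#' @slot groups data.frame with columns label, n, mean, sd.
#' @slot pairwise data.frame with columns group1, group2, diff, ci_lo, ci_hi,
#'   t, df, p_value, p_adjusted, significant (and stars when built for a
#'   figure table).
#' @slot method "student_t", "welch_t", "paired_t" or
#'   "bonferroni_multicompare".
#' @slot conf_level family confidence level (0.95).
#' @export
setClass("GroupComparison",
  slots = c(
    metric = "character",
    groups = "data.frame",
    pairwise = "data.frame",
    method = "character",
    conf_level = "numeric"
  )
)
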