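#' @include AllClasses.R
NULL

#' Construct stack acquisition metadata
#'
#' @param frame_interval_s nominal frame interval (s).
#' @param pixel_size_um pixel size (um/pixel).
#' @param channel_roles named integer vector mapping "donor" and "fret" to
#'   channel indices (distinct).
#' @param times_s per-frame acquisition times (s); may contain gaps for
#'   acquisition pauses.  Defaults to a regular grid when a frame count is
#'   later known (leave empty here).
#' @return a [StackMeta-class].
#' @export
stackMeta <- function(frame_interval_s = 10, pixel_size_um = 1,
                      channel_roles = c(donor = 1L, fret = 2L),
                      times_s = numeric(0)) {
  if (!all(c("donor", "fret") %in% names(channel_roles))) {
    stop("configuration error: channel_roles must assign both ",
         "'donor' and 'fret'")
  }
  new("StackMeta", frame_interval_s = frame_interval_s,
      pixel_size_um = pixel_size_um,
      channel_roles = vapply(channel_roles, as.integer, integer(1)),
      times_s = as.numeric(times_s))
}

.stackTimes <- function(meta, nt) {
  if (length(meta@times_s)) meta@times_s
  else (seq_len(nt) - 1) * meta@frame_interval_s
}

#' Per-pixel FRET/donor emission-ratio stack
#'
#' Computes ratio = (fret - bg_fret) / (donor - bg_donor) wherever the
#' background-subtracted donor signal is at least `intensity_floor` (the
#' division guard against ratio blow-up at dim pixels) and the
#' background-subtracted FRET signal is positive; all other pixels are
#' marked invalid and carry NA, never an infinity.
#'
#' @param stack a [FretStack-class] or a 4-D array [y, x, channel, frame].
#' @param meta a [StackMeta-class]; taken from the stack when omitted.
#' @param background_per_channel named numeric c(donor=, fret=) background
#'   counts, >= 0; see [estimateBackground()].
#' @param intensity_floor minimum background-subtracted donor signal for a
#'   valid ratio (> 0).  Default 10 counts, i.e. 5x a typical read-noise sd
#'   of 2 counts.
#' @return a [RatioStack-class].
#' @examples
#' a <- array(0, c(1, 1, 2, 1)); a[1, 1, 1, 1] <- 100; a[1, 1, 2, 1] <- 200
#' rs <- computeRatioStack(a, stackMeta(), c(donor = 0, fret = 0))
#' rs@ratio[1, 1, 1]  # 2.0
#' @export
computeRatioStack <- function(stack, meta = NULL,
                              background_per_channel = c(donor = 0, fret = 0),
                              intensity_floor = 10) {
  if (is(stack, "FretStack")) {
    if (is.null(meta)) meta <- stack@meta
    dat <- stack@data
  } else {
    dat <- stack
    if (is.null(meta)) stop("configuration error: meta required for raw arrays")
  }
  stopifnot(is(meta, "StackMeta"))
  if (any(background_per_channel < 0)) stop("background must be >= 0")
  .assertScalar(intensity_floor, "intensity_floor", positive = TRUE)
  if (!all(c("donor", "fret") %in% names(background_per_channel))) {
    stop("configuration error: background_per_channel must name donor and fret")
  }
  roles <- meta@channel_roles
  donor <- dat[, , roles[["donor"]], , drop = FALSE]
  fret <- dat[, , roles[["fret"]], , drop = FALSE]
  dm <- dim(dat)[c(1, 2, 4)]
  donor <- array(donor, dm) - background_per_channel[["donor"]]
  fret <- array(fret, dm) - background_per_channel[["fret"]]

  valid <- (donor >= intensity_floor) & (fret > 0)
  ratio <- array(NA_real_, dm)
  ratio[valid] <- fret[valid] / donor[valid]

  if (!length(meta@times_s)) {
    meta@times_s <- .stackTimes(meta, dm[3])
  }
  new("RatioStack", ratio = ratio, valid = valid, meta = meta)
}

#' Estimate per-channel background as the modal intensity outside ROIs
#'
#' The background is taken as the mode of a kernel density estimate of the
#' pixel intensities outside all ROI masks, pooled over frames; a single
#' scalar per channel.
#'
#' @param stack a [FretStack-class].
#' @param roi_masks a logical matrix or list of logical matrices marking
#'   cell pixels to exclude; NULL uses the whole image.
#' @return named numeric c(donor=, fret=).
#' @export
estimateBackground <- function(stack, roi_masks = NULL) {
  stopifnot(is(stack, "FretStack"))
  d <- dim(stack@data)
  outside <- matrix(TRUE, d[1], d[2])
  if (!is.null(roi_masks)) {
    if (is.matrix(roi_masks)) roi_masks <- list(roi_masks)
    for (m in roi_masks) outside <- outside & !m
  }
  if (!any(outside)) stop("no pixels outside the ROI masks")
  roles <- stack@meta@channel_roles
  vapply(c(donor = "donor", fret = "fret"), function(role) {
    ch <- stack@data[, , roles[[role]], , drop = FALSE]
    vals <- as.vector(array(ch, d[c(1, 2, 4)])[rep(outside, d[4])])
    dens <- density(vals, n = 512)
    dens$x[which.max(dens$y)]
  }, numeric(1))
}

#' Extract a per-ROI emission-ratio trace
#'
#' Per-frame trace value is the mean ratio over the valid pixels of the ROI;
#' frames where fewer than `min_valid_frac` of the ROI pixels are valid are
#' flagged invalid in the trace.
#'
#' @param rstack a [RatioStack-class] from [computeRatioStack()].
#' @param roi logical matrix, TRUE for ROI pixels; must be nonempty.
#' @param roi_id identifier for the trace.
#' @param min_valid_frac minimum fraction of valid ROI pixels for a frame to
#'   count (default 0.5).
#' @return a [RatioTrace-class].
#' @export
extractTrace <- function(rstack, roi, roi_id = "roi1", min_valid_frac = 0.5) {
  stopifnot(is(rstack, "RatioStack"))
  if (!is.matrix(roi) || !is.logical(roi)) {
    stop("roi must be a logical matrix")
  }
  if (!all(dim(roi) == dim(rstack@ratio)[1:2])) {
    stop("dimension error: roi does not match the ratio stack")
  }
  if (!any(roi)) stop("empty ROI")
  nt <- dim(rstack@ratio)[3]
  n_roi <- sum(roi)
  vals <- numeric(nt)
  ok <- logical(nt)
  for (i in seq_len(nt)) {
    v <- rstack@valid[, , i] & roi
    nv <- sum(v)
    ok[i] <- nv >= max(1, min_valid_frac * n_roi)
    vals[i] <- if (nv) mean(rstack@ratio[, , i][v]) else NA_real_
  }
  if (mean(ok) < 0.9) {
    warning(sprintf(
      "ROI '%s' intersects valid pixels on only %.0f%% of frames", roi_id,
      100 * mean(ok)))
  }
  ok <- ok & is.finite(vals) & vals > 0
  new("RatioTrace", times_s = .stackTimes(rstack@meta, nt), ratio = vals,
      valid = ok, roi_id = roi_id)
}
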