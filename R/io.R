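#' @include AllClasses.R ratiometric.R
NULL

# TIFF storage scale: counts are stored as 16-bit samples, value = count/scale
.TIFF_SCALE <- 65535

#' Write / read a two-channel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major with channels interleaved (frame 1 donor,
#' frame 1 FRET, frame 2 donor, ...), i.e. dimension order T, C, Y, X;
#' channel 1 = donor, channel 2 = FRET.  Counts are stored as 16-bit
#' samples; the intensity scale and the acquisition metadata (frame
#' interval, pixel size, channel roles, frame times) go to a JSON sidecar.
#'
#' @param stack a [FretStack-class].
#' @param path TIFF file path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return `writeFretStack` invisibly returns `path`; `readFretStack`
#'   returns a [FretStack-class] (ground-truth slots empty).
#' @export
writeFretStack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(is(stack, "FretStack"))
  d <- dim(stack@data)
  counts <- pmin(pmax(stack@data, 0), .TIFF_SCALE)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) {
    for (ch in seq_len(d[3])) {
      pages[[k]] <- counts[, , ch, t] / .TIFF_SCALE
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- stack@meta
  jsonlite::write_json(
    list(
      n_frames = d[4], n_channels = d[3], shape = d[1:2],
      frame_interval_s = meta@frame_interval_s,
      pixel_size_um = meta@pixel_size_um,
      channel_roles = as.list(meta@channel_roles),
      times_s = .stackTimes(meta, d[4]),
      intensity_scale = .TIFF_SCALE
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeFretStack
#' @export
readFretStack <- function(path, sidecar = paste0(path, ".json")) {
  meta_js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- meta_js$n_channels
  nt <- meta_js$n_frames
  stopifnot(length(pages) == nc * nt)
  d1 <- dim(pages[[1]])
  dat <- array(0, c(d1[1], d1[2], nc, nt))
  k <- 1L
  for (t in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      dat[, , ch, t] <- pages[[k]] * meta_js$intensity_scale
      k <- k + 1L
    }
  }
  meta <- stackMeta(
    frame_interval_s = meta_js$frame_interval_s,
    pixel_size_um = meta_js$pixel_size_um,
    channel_roles = unlist(meta_js$channel_roles),
    times_s = meta_js$times_s
  )
  new("FretStack", data = dat, meta = meta,
      onset_delay_s = matrix(numeric(0), 0, 0), truth = list())
}

#' Write / read an ROI ratio trace as CSV
#'
#' Columns: time_s, ratio, valid.
#'
#' @param trace a [RatioTrace-class].
#' @param path CSV path.
#' @param roi_id identifier given to a trace read from disk.
#' @return `writeTraceCSV` invisibly returns `path`; `readTraceCSV` a
#'   [RatioTrace-class].
#' @export
writeTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "RatioTrace"))
  write.csv(as.data.frame.RatioTrace(trace)[, c("time_s", "ratio", "valid")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path, roi_id = basename(path)) {
  df <- read.csv(path)
  new("RatioTrace", times_s = df$time_s, ratio = df$ratio,
      valid = as.logical(df$valid), roi_id = roi_id)
}

#' Write / read reference and loaded bead coordinates as CSV
#'
#' Columns: frame_label ("ref" or "loaded"), x_um, y_um.
#'
#' @param ref,loaded bead coordinates (n x 2, um).
#' @param path CSV path.
#' @return `writeBeadTableCSV` invisibly returns `path`;
#'   `readBeadTableCSV` a list with elements `ref` and `loaded`.
#' @export
writeBeadTableCSV <- function(ref, loaded, path) {
  ref <- .beadXY(ref, "ref")
  loaded <- .beadXY(loaded, "loaded")
  df <- rbind(
    data.frame(frame_label = "ref", x_um = ref[, 1], y_um = ref[, 2]),
    data.frame(frame_label = "loaded", x_um = loaded[, 1],
               y_um = loaded[, 2])
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeadTableCSV
#' @export
readBeadTableCSV <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("frame_label", "x_um", "y_um") %in% names(df)))
  list(ref = .beadXY(df[df$frame_label == "ref", c("x_um", "y_um")]),
       loaded = .beadXY(df[df$frame_label == "loaded", c("x_um", "y_um")]))
}

#' Write a gridded displacement/strain field as CSV
#'
#' Columns: x_um, y_um, ux_um, uy_um and, when a strain map is supplied,
#' Ex, Ey, E_total (units in the headers: um for coordinates and
#' displacements, strains dimensionless).
#'
#' @param field a [DisplacementField-class].
#' @param path CSV path.
#' @param strain optional [StrainMap-class] on the same grid.
#' @return invisibly, `path`.
#' @export
writeFieldCSV <- function(field, path, strain = NULL) {
  df <- as.data.frame.DisplacementField(field)
  if (!is.null(strain)) {
    df <- cbind(df, as.data.frame.StrainMap(strain)[, c("Ex", "Ey",
                                                        "E_total")])
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a strain/stress summary as JSON
#'
#' @param strain a [StrainMap-class].
#' @param path JSON path.
#' @return invisibly, `path`.
#' @export
writeStrainSummaryJSON <- function(strain, path) {
  stopifnot(is(strain, "StrainMap"))
  jsonlite::write_json(
    list(peak_strain = strain@peak_strain,
         young_modulus_pa = strain@young_modulus_pa,
         stress_pa = strain@stress_pa,
         strain_definition = strain@definition),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write per-cell oscillation summaries as CSV
#'
#' One row per cell: cell_id, group_label, n_peaks, frequency_per_min,
#' mean_peak_amplitude, duration_min, oscillating.
#'
#' @param summaries list of [OscillationSummary-class] or a data.frame.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
writeSummariesCSV <- function(summaries, path) {
  df <- if (is.data.frame(summaries)) summaries
        else summariesToDataFrame(summaries)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
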