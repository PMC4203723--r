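#' @include AllClasses.R synthgen-trace.R
NULL

#' Construct a cell rendering specification
#'
#' @param cell_mask logical matrix (rows = y, cols = x), TRUE inside the
#'   cell; see [diskMask()] for a convenient constructor.
#' @param pixel_size_um physical pixel size (um/pixel).
#' @param donor_base,fret_base baseline photon counts per channel inside the
#'   cell.
#' @param gain_anticorr fraction of the ratio modulation rendered into the
#'   channels (1 = full anti-correlation).
#' @param wave_speed_um_s calcium-onset propagation speed (um/s); 0 means
#'   synchronous onset.
#' @param wave_origin c(x, y) pixel coordinate of the proximal onset point
#'   (0-based pixel centers).
#' @param background additive background counts per channel.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param poisson_noise apply Poisson photon noise?
#' @param seed integer seed for all rendering noise.
#' @return a [CellRenderSpec-class].
#' @export
cellRenderSpec <- function(cell_mask, pixel_size_um = 1, donor_base = 600,
                           fret_base = 600, gain_anticorr = 1,
                           wave_speed_um_s = 0, wave_origin = c(0, 0),
                           background = 50, read_noise_sd = 2,
                           poisson_noise = TRUE, seed = 1L) {
  new("CellRenderSpec",
      cell_mask = cell_mask, pixel_size_um = pixel_size_um,
      donor_base = donor_base, fret_base = fret_base,
      gain_anticorr = gain_anticorr, wave_speed_um_s = wave_speed_um_s,
      wave_origin = as.numeric(wave_origin), background = background,
      read_noise_sd = read_noise_sd, poisson_noise = poisson_noise,
      seed = as.integer(seed))
}

#' Disk-shaped cell mask
#'
#' @param ny,nx raster dimensions (rows, cols).
#' @param center c(x, y) disk center in 0-based pixel coordinates; defaults
#'   to the raster center.
#' @param radius_px disk radius in pixels.
#' @return logical ny x nx matrix.
#' @export
diskMask <- function(ny, nx, center = c((nx - 1) / 2, (ny - 1) / 2),
                     radius_px = min(ny, nx) / 3) {
  px <- .pixelCentersUm(ny, nx, 1)
  dx2 <- outer(rep(1, ny), (px$x - center[1])^2)
  dy2 <- outer((px$y - center[2])^2, rep(1, nx))
  dx2 + dy2 <= radius_px^2
}

#' Ground-truth per-pixel onset delays for a propagating calcium wave
#'
#' Delay at pixel p is distance(p, wave_origin) / wave_speed (in seconds),
#' or 0 everywhere when the speed is 0 (synchronous onset).
#'
#' @param spec a [CellRenderSpec-class].
#' @return numeric matrix of delays (s), same shape as the cell mask.
#' @export
onsetDelays <- function(spec) {
  stopifnot(is(spec, "CellRenderSpec"))
  ny <- nrow(spec@cell_mask)
  nx <- ncol(spec@cell_mask)
  if (spec@wave_speed_um_s == 0) {
    return(matrix(0, ny, nx))
  }
  px <- .pixelCentersUm(ny, nx, spec@pixel_size_um)
  ox <- spec@wave_origin[1] * spec@pixel_size_um
  oy <- spec@wave_origin[2] * spec@pixel_size_um
  dx2 <- outer(rep(1, ny), (px$x - ox)^2)
  dy2 <- outer((px$y - oy)^2, rep(1, nx))
  sqrt(dx2 + dy2) / spec@wave_speed_um_s
}

#' Render a calcium trace into a two-channel FRET image stack
#'
#' Inside the cell mask a fixed per-pixel photon budget (donor_base +
#' fret_base) is split between the channels so that the noiseless
#' background-subtracted FRET/donor ratio equals the (delay-shifted)
#' calcium signal exactly: donor = T / (1 + r), fret = T r / (1 + r).
#' FRET intensity therefore rises and donor falls with calcium
#' (anti-correlated channels).  Outside the mask only background is
#' rendered.  Poisson photon noise and Gaussian read noise are applied when
#' enabled; both derive from the spec's seed, so identical seeds give
#' bit-identical stacks.
#'
#' @param trace a [CalciumTrace-class] ground truth from [simulateTrace()].
#' @param spec a [CellRenderSpec-class]; its frame geometry must be
#'   compatible with the trace sampling.
#' @return a [FretStack-class] (channel 1 = donor, channel 2 = FRET) whose
#'   `onset_delay_s` slot carries the ground-truth delay raster and whose
#'   `truth` list holds the trace and spec.
#' @export
renderStack <- function(trace, spec) {
  stopifnot(is(trace, "CalciumTrace"), is(spec, "CellRenderSpec"))
  validObject(spec)
  ny <- nrow(spec@cell_mask)
  nx <- ncol(spec@cell_mask)
  nt <- length(trace@times_s)
  delays <- onsetDelays(spec)

  budget <- spec@donor_base + spec@fret_base
  dat <- array(0, dim = c(ny, nx, 2L, nt))
  inside <- which(spec@cell_mask)
  dvec <- delays[inside]
  base <- trace@model@baseline_ratio
  for (i in seq_len(nt)) {
    r <- traceAt(trace, trace@times_s[i] - dvec)
    reff <- base + spec@gain_anticorr * (r - base)
    donor <- budget / (1 + reff)
    frames_d <- matrix(0, ny, nx)
    frames_f <- matrix(0, ny, nx)
    frames_d[inside] <- donor
    frames_f[inside] <- budget - donor
    dat[, , 1L, i] <- frames_d + spec@background
    dat[, , 2L, i] <- frames_f + spec@background
  }

  if (spec@poisson_noise || spec@read_noise_sd > 0) {
    dat <- withSeed(spec@seed, {
      x <- dat
      if (spec@poisson_noise) {
        x[] <- rpois(length(x), lambda = as.vector(x))
      }
      if (spec@read_noise_sd > 0) {
        x <- x + rnorm(length(x), sd = spec@read_noise_sd)
      }
      x
    })
  }

  meta <- stackMeta(frame_interval_s = trace@model@frame_interval_s,
                    pixel_size_um = spec@pixel_size_um,
                    channel_roles = c(donor = 1L, fret = 2L),
                    times_s = trace@times_s)
  new("FretStack", data = dat, meta = meta, onset_delay_s = delays,
      truth = list(trace = trace, spec = spec))
}
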