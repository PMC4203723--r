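#' @include AllClasses.R mechanics.R
NULL

.plotRaster <- function(x_um, y_um, z, range, main, col) {
  z <- pmin(pmax(z, range[1]), range[2])
  # transpose: image() expects z[x, y]; flip y for image convention
  image(x_um, y_um, t(z), zlim = range, col = col, main = main,
        xlab = "x (um)", ylab = "y (um)", ylim = rev(range(y_um)),
        useRaster = TRUE)
}

#' Plot a displacement-magnitude map
#'
#' Cold-to-hot pseudocolor of |u| clipped to the display range
#' (default 0-15 um), image convention with the y axis pointing down.
#'
#' @param x a [DisplacementField-class].
#' @param y unused.
#' @param display_range_um display range c(lo, hi) in um.
#' @param ... unused.
#' @export
setMethod("plot", signature(x = "DisplacementField", y = "missing"),
  function(x, y, display_range_um = c(0, 15), ...) {
    mag <- sqrt(x@ux_um^2 + x@uy_um^2)
    .plotRaster(x@grid_x_um, x@grid_y_um, mag, display_range_um,
                "substrate displacement |u| (um)",
                hcl.colors(64, "Spectral", rev = TRUE))
    invisible(NULL)
  })

#' Plot a strain-index map
#'
#' Cold-to-hot pseudocolor of the total strain index clipped to the display
#' range (default 0-0.3).
#'
#' @param x a [StrainMap-class].
#' @param y unused.
#' @param display_range display range c(lo, hi), dimensionless.
#' @param ... unused.
#' @export
setMethod("plot", signature(x = "StrainMap", y = "missing"),
  function(x, y, display_range = c(0, 0.3), ...) {
    .plotRaster(x@grid_x_um, x@grid_y_um, x@E_total, display_range,
                "substrate strain index", hcl.colors(64, "Spectral",
                                                     rev = TRUE))
    invisible(NULL)
  })

#' Plot a ratio trace
#'
#' @param x a [RatioTrace-class].
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "RatioTrace", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@times_s[x@valid], x@ratio[x@valid], type = "l",
                   xlab = "time (s)", ylab = "FRET/donor emission ratio",
                   main = x@roi_id, ...)
    invisible(NULL)
  })
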