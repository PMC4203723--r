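# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  All generator randomness flows through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce bead coordinates: accepts an n x 2 matrix or a data.frame with
# x_um / y_um columns; returns an n x 2 matrix with columns x_um, y_um.
.beadXY <- function(xy, name = "coordinates") {
  if (is.data.frame(xy)) {
    if (all(c("x_um", "y_um") %in% names(xy))) {
      xy <- cbind(xy$x_um, xy$y_um)
    } else {
      xy <- as.matrix(xy[, 1:2])
    }
  }
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || !is.numeric(xy)) {
    stop(sprintf("'%s' must be an n x 2 numeric matrix (x_um, y_um)", name),
         call. = FALSE)
  }
  colnames(xy) <- c("x_um", "y_um")
  xy
}

# Pixel-center coordinates in micrometres for a ny x nx raster
# (image convention: origin top-left, x along columns, y along rows,
# 0-based pixel centers).
.pixelCentersUm <- function(ny, nx, pixel_size_um) {
  list(
    x = (seq_len(nx) - 1) * pixel_size_um,
    y = (seq_len(ny) - 1) * pixel_size_um
  )
}
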