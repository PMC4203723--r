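#' @include AllClasses.R
NULL

#' Construct a tip-pull deformation model
#'
#' @param tip_xy_um probe tip position c(x, y) (um).
#' @param pull_vector_um pull direction and magnitude U0 (um); the
#'   displacement at the tip itself.
#' @param decay_sigma_um Gaussian decay length of the displacement (um).
#' @param bead_density_per_um2 fiducial bead density (beads/um^2).
#' @param localization_noise_um bead centroid localization noise sd (um).
#' @param seed integer seed.
#' @return a [TipPullField-class].
#' @export
tipPullField <- function(tip_xy_um = c(0, 0), pull_vector_um = c(10, 0),
                         decay_sigma_um = 50, bead_density_per_um2 = 0.02,
                         localization_noise_um = 0.05, seed = 1L) {
  new("TipPullField",
      tip_xy_um = as.numeric(tip_xy_um),
      pull_vector_um = as.numeric(pull_vector_um),
      decay_sigma_um = decay_sigma_um,
      bead_density_per_um2 = bead_density_per_um2,
      localization_noise_um = localization_noise_um,
      seed = as.integer(seed))
}

#' Closed-form tip-pull displacement
#'
#' u(x, y) = pull_vector * exp(-||(x, y) - tip||^2 / (2 sigma^2)).
#'
#' @param field a [TipPullField-class].
#' @param xy n x 2 matrix of positions (um).
#' @return n x 2 matrix of displacements (ux_um, uy_um).
#' @export
tipPullDisplacement <- function(field, xy) {
  xy <- .beadXY(xy)
  d2 <- (xy[, 1] - field@tip_xy_um[1])^2 + (xy[, 2] - field@tip_xy_um[2])^2
  g <- exp(-d2 / (2 * field@decay_sigma_um^2))
  cbind(ux_um = field@pull_vector_um[1] * g,
        uy_um = field@pull_vector_um[2] * g)
}

# Exact small-strain components of the Gaussian tip-pull field.
# With g = exp(-((x-tx)^2+(y-ty)^2)/(2 s^2)):
#   Ex = d(ux)/dx = -Px (x - tx) / s^2 * g
#   Ey = d(uy)/dy = -Py (y - ty) / s^2 * g
.tipPullStrainExact <- function(field, grid_x, grid_y) {
  s2 <- field@decay_sigma_um^2
  dx <- grid_x - field@tip_xy_um[1]
  dy <- grid_y - field@tip_xy_um[2]
  g <- exp(-(outer(dy^2, dx^2, "+")) / (2 * s2))  # [y, x]
  Ex <- -field@pull_vector_um[1] / s2 * sweep(g, 2, dx, "*")
  Ey <- -field@pull_vector_um[2] / s2 * sweep(g, 1, dy, "*")
  list(Ex = Ex, Ey = Ey)
}

#' Simulate a reference/loaded fiducial bead pair with analytic ground truth
#'
#' Beads are placed uniformly at the stated density in the region; each bead
#' is displaced by the closed-form tip-pull field (loaded = reference +
#' u(reference)).  Observed coordinates add isotropic Gaussian localization
#' noise to both frames; the returned analytic displacement field and strain
#' map (exact differentiation of u on a regular grid) exclude that noise.
#'
#' @param field a [TipPullField-class].
#' @param region_um region extent c(xmin, xmax, ymin, ymax) (um).
#' @param grid_spacing_um node spacing of the analytic ground-truth grid.
#' @return a [BeadPairSim-class].
#' @examples
#' sim <- simulateBeadPair(tipPullField(pull_vector_um = c(0, 0)),
#'                         region_um = c(-50, 50, -50, 50))
#' max(totalStrain(sim@strain))  # null load: zero strain everywhere
#' @export
simulateBeadPair <- function(field, region_um = c(-80, 80, -80, 80),
                             grid_spacing_um = 5) {
  stopifnot(is(field, "TipPullField"))
  validObject(field)
  if (length(region_um) != 4L || region_um[2] <= region_um[1] ||
      region_um[4] <= region_um[3]) {
    stop("region_um must be c(xmin, xmax, ymin, ymax) with positive extent")
  }
  area <- (region_um[2] - region_um[1]) * (region_um[4] - region_um[3])
  n <- round(field@bead_density_per_um2 * area)
  if (n < 1L) stop("empty field: region contains no beads at this density")
  if (n < 20L) {
    warning("fewer than 20 beads in region; field reconstruction will be poor")
  }

  sim <- withSeed(field@seed, {
    ref <- cbind(x_um = runif(n, region_um[1], region_um[2]),
                 y_um = runif(n, region_um[3], region_um[4]))
    u <- tipPullDisplacement(field, ref)
    loaded <- ref + u
    noise <- field@localization_noise_um
    ref_obs <- ref + matrix(rnorm(2 * n, sd = noise), n, 2)
    loaded_obs <- loaded + matrix(rnorm(2 * n, sd = noise), n, 2)
    colnames(loaded) <- colnames(ref_obs) <- colnames(loaded_obs) <-
      c("x_um", "y_um")
    list(ref = ref, loaded = loaded, ref_obs = ref_obs,
         loaded_obs = loaded_obs)
  })

  grid_x <- seq(region_um[1], region_um[2], by = grid_spacing_um)
  grid_y <- seq(region_um[3], region_um[4], by = grid_spacing_um)
  gxy <- cbind(rep(grid_x, each = length(grid_y)),
               rep(grid_y, times = length(grid_x)))
  u_grid <- tipPullDisplacement(field, gxy)
  ux <- matrix(u_grid[, 1], length(grid_y), length(grid_x))
  uy <- matrix(u_grid[, 2], length(grid_y), length(grid_x))
  dfield <- new("DisplacementField", grid_x_um = grid_x, grid_y_um = grid_y,
                ux_um = ux, uy_um = uy, grid_spacing_um = grid_spacing_um)

  E <- .tipPullStrainExact(field, grid_x, grid_y)
  Et <- sqrt(E$Ex^2 + E$Ey^2)
  strain <- new("StrainMap", grid_x_um = grid_x, grid_y_um = grid_y,
                Ex = E$Ex, Ey = E$Ey, E_total = Et,
                peak_strain = max(Et), young_modulus_pa = NA_real_,
                stress_pa = NA_real_, definition = "small")

  new("BeadPairSim",
      ref_true = sim$ref, loaded_true = sim$loaded,
      ref_obs = sim$ref_obs, loaded_obs = sim$loaded_obs,
      field = dfield, strain = strain, model = field,
      region_um = as.numeric(region_um))
}

#' Render fiducial beads into a fluorescence image
#'
#' Beads are drawn as isotropic Gaussian spots on a constant background,
#' with optional Poisson photon noise and Gaussian read noise; used to test
#' bead localization ([detectBeads()]) against known subpixel positions.
#'
#' @param xy_um bead positions, n x 2 (um).
#' @param shape_px image dimensions c(ny, nx) in pixels.
#' @param pixel_size_um pixel size (um/pixel).
#' @param amplitude peak counts of one bead above background.
#' @param psf_sigma_um Gaussian spot sd (um).
#' @param background background counts.
#' @param read_noise_sd Gaussian read noise sd (counts); 0 disables.
#' @param poisson_noise apply Poisson noise?
#' @param seed integer seed (only used when noise is enabled).
#' @return numeric ny x nx matrix of counts.
#' @export
renderBeadImage <- function(xy_um, shape_px, pixel_size_um = 0.5,
                            amplitude = 1000, psf_sigma_um = 0.6,
                            background = 100, read_noise_sd = 0,
                            poisson_noise = FALSE, seed = 1L) {
  xy <- .beadXY(xy_um)
  ny <- shape_px[1]
  nx <- shape_px[2]
  px <- .pixelCentersUm(ny, nx, pixel_size_um)
  img <- matrix(background, ny, nx)
  s2 <- psf_sigma_um^2
  for (k in seq_len(nrow(xy))) {
    gx <- exp(-(px$x - xy[k, 1])^2 / (2 * s2))
    gy <- exp(-(px$y - xy[k, 2])^2 / (2 * s2))
    img <- img + amplitude * outer(gy, gx)
  }
  if (poisson_noise || read_noise_sd > 0) {
    img <- withSeed(seed, {
      x <- img
      if (poisson_noise) x[] <- rpois(length(x), as.vector(x))
      if (read_noise_sd > 0) x <- x + rnorm(length(x), sd = read_noise_sd)
      x
    })
  }
  img
}
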