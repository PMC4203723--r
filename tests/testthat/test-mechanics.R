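test_that("detectBeads localizes synthetic beads with subpixel accuracy", {
  # single bead at a subpixel position, noiseless: within 0.05 px
  xy <- cbind(10.3 * 0.5, 20.7 * 0.5)  # px -> um at 0.5 um/px
  img <- renderBeadImage(xy, c(40, 40), pixel_size_um = 0.5)
  hit <- detectBeads(img, expected_diameter_um = 1, pixel_size_um = 0.5)
  expect_identical(nrow(hit), 1L)
  expect_lt(max(abs(hit / 0.5 - c(10.3, 20.7))), 0.05)

  # blank image: empty result with a warning
  blank <- matrix(100, 30, 30)
  expect_warning(none <- detectBeads(blank, 1, 0.5), "no beads")
  expect_identical(nrow(none), 0L)

  # two beads 3 diameters apart: exactly two detections
  xy2 <- rbind(c(5, 5), c(8, 5))
  img2 <- renderBeadImage(xy2, c(40, 40), pixel_size_um = 0.5)
  expect_identical(nrow(detectBeads(img2, 1, 0.5)), 2L)

  # noisy beads at SNR ~ 10: accuracy better than 0.2 px (well-separated
  # beads on a jittered lattice so detections never merge)
  set.seed(4)
  xy3 <- as.matrix(expand.grid(x = c(5, 10, 15), y = c(6, 13))) +
    matrix(runif(12, -0.8, 0.8), 6, 2)
  img3 <- renderBeadImage(xy3, c(40, 40), pixel_size_um = 0.5,
                          amplitude = 300, background = 100,
                          poisson_noise = TRUE, read_noise_sd = 5,
                          seed = 9L)
  hits3 <- detectBeads(img3, 1, 0.5)
  expect_identical(nrow(hits3), 6L)
  d <- sqrt(outer(hits3[, 1], xy3[, 1], "-")^2 +
            outer(hits3[, 2], xy3[, 2], "-")^2)
  expect_lt(max(apply(d, 2, min)) / 0.5, 0.2)
})

test_that("greedy matching handles identity, translation and errors", {
  # greedy nearest-neighbor assignment presumes displacements well below
  # the bead spacing: jittered lattice, spacing 10 um, translation 2 um
  set.seed(2)
  ref <- as.matrix(expand.grid(x_um = seq(0, 90, 10),
                               y_um = seq(0, 90, 10))) +
    matrix(runif(200, -1.5, 1.5), 100, 2)
  colnames(ref) <- c("x_um", "y_um")
  m0 <- matchBeads(ref, ref, 5)
  expect_identical(nrow(m0@ref_xy_um), 100L)
  expect_true(all(m0@loaded_xy_um == m0@ref_xy_um))

  tr <- sweep(ref, 2, c(2, 0), "+")
  m1 <- matchBeads(ref, tr, 5)
  disp <- m1@loaded_xy_um - m1@ref_xy_um
  expect_true(all(abs(disp[, 1] - 2) < 1e-12 & abs(disp[, 2]) < 1e-12))

  expect_error(matchBeads(ref, tr + 100, 5), "zero bead matches")
})

test_that("robust matching recovers the true correspondence of a tip pull", {
  sim <- simulateBeadPair(tipPullField(seed = 2L),
                          region_um = c(-80, 80, -80, 80))
  m <- matchBeadsRobust(sim@ref_obs, sim@loaded_obs, 20)
  # recover ground-truth row pairing via coordinate lookup
  ri <- match(asplit(round(m@ref_xy_um, 9), 1),
              asplit(round(sim@ref_obs, 9), 1))
  li <- match(asplit(round(m@loaded_xy_um, 9), 1),
              asplit(round(sim@loaded_obs, 9), 1))
  expect_gt(mean(ri == li), 0.95)
  expect_gt(nrow(m@ref_xy_um), 0.85 * nrow(sim@ref_obs))
})

test_that("interpolation is exact at beads and accurate on smooth fields", {
  set.seed(8)
  ref <- cbind(x_um = runif(50, 0, 60), y_um = runif(50, 0, 60))
  # zero displacement -> zero field everywhere
  m0 <- new("BeadMatchSet", ref_xy_um = ref, loaded_xy_um = ref,
            unmatched_ref = 0L, unmatched_loaded = 0L,
            max_search_radius_um = 5)
  f0 <- interpolateDisplacement(m0, 5)
  expect_lt(max(abs(f0@ux_um)), 1e-8)
  expect_lt(max(abs(f0@uy_um)), 1e-8)

  # constant translation -> constant field (for both estimators)
  mt <- new("BeadMatchSet", ref_xy_um = ref,
            loaded_xy_um = sweep(ref, 2, c(3, -1), "+"),
            unmatched_ref = 0L, unmatched_loaded = 0L,
            max_search_radius_um = 5)
  for (meth in c("tps", "loclin")) {
    ft <- interpolateDisplacement(mt, 5, method = meth)
    expect_lt(max(abs(ft@ux_um - 3)), 1e-6)
    expect_lt(max(abs(ft@uy_um + 1)), 1e-6)
  }

  # TPS reproduces the displacement exactly at bead sites: put grid nodes
  # through a subset of bead positions laid on a lattice
  lattice <- as.matrix(expand.grid(x_um = seq(0, 60, 10),
                                   y_um = seq(0, 60, 10)))
  f <- tipPullField(tip_xy_um = c(30, 30), pull_vector_um = c(4, 2),
                    decay_sigma_um = 25)
  u <- tipPullDisplacement(f, lattice)
  mg <- new("BeadMatchSet", ref_xy_um = lattice, loaded_xy_um = lattice + u,
            unmatched_ref = 0L, unmatched_loaded = 0L,
            max_search_radius_um = 10)
  fld <- interpolateDisplacement(mg, 10, bbox = c(0, 60, 0, 60))  # nodes on beads
  idx <- cbind(match(lattice[, 2], fld@grid_y_um),
               match(lattice[, 1], fld@grid_x_um))
  expect_lt(max(abs(fld@ux_um[idx] - u[, 1])), 1e-8)
  expect_lt(max(abs(fld@uy_um[idx] - u[, 2])), 1e-8)

  # dense-bead field accuracy: gridded field RMSE < 2% of |pull_vector|
  sim <- simulateBeadPair(
    tipPullField(pull_vector_um = c(10, 0), decay_sigma_um = 50,
                 bead_density_per_um2 = 1 / 25,
                 localization_noise_um = 0, seed = 3L),
    region_um = c(-70, 70, -70, 70))
  mm <- matchBeadsRobust(sim@ref_obs, sim@loaded_obs, 15)
  fld2 <- interpolateDisplacement(mm, 5, bbox = c(-60, 60, -60, 60))
  truth <- tipPullDisplacement(
    sim@model, cbind(rep(fld2@grid_x_um, each = length(fld2@grid_y_um)),
                     rep(fld2@grid_y_um, times = length(fld2@grid_x_um))))
  rmse <- sqrt(mean((fld2@ux_um - matrix(truth[, 1], length(fld2@grid_y_um)))^2 +
                    (fld2@uy_um - matrix(truth[, 2], length(fld2@grid_y_um)))^2))
  expect_lt(rmse, 0.02 * 10)

  expect_error(interpolateDisplacement(
    new("BeadMatchSet", ref_xy_um = cbind(1:5, 2 * (1:5)),
        loaded_xy_um = cbind(1:5, 2 * (1:5)), unmatched_ref = 0L,
        unmatched_loaded = 0L, max_search_radius_um = 5), 5),
    "degenerate")
})

test_that("strain maps follow the small-strain definition and stress rule", {
  gx <- seq(0, 40, by = 5)
  ny <- length(gx)
  # rigid translation: zero strain, zero stress
  ft <- new("DisplacementField", grid_x_um = gx, grid_y_um = gx,
            ux_um = matrix(2, ny, ny), uy_um = matrix(-7, ny, ny),
            grid_spacing_um = 5)
  st <- computeStrain(ft, 20000)
  expect_lt(max(totalStrain(st)), 1e-10)
  expect_equal(stressPa(st), 0)

  # linear stretch ux = 0.1 x: Ex = E_total = 0.1 at every node
  fl <- new("DisplacementField", grid_x_um = gx, grid_y_um = gx,
            ux_um = outer(rep(1, ny), 0.1 * gx), uy_um = matrix(0, ny, ny),
            grid_spacing_um = 5)
  sl <- computeStrain(fl, 20000)
  expect_equal(max(abs(sl@Ex - 0.1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(totalStrain(sl) - 0.1)), 0, tolerance = 1e-12)

  # the worked stress example: peak strain 0.3 on a 20 kPa substrate
  fs <- new("DisplacementField", grid_x_um = gx, grid_y_um = gx,
            ux_um = outer(rep(1, ny), 0.3 * gx), uy_um = matrix(0, ny, ny),
            grid_spacing_um = 5)
  expect_identical(stressPa(computeStrain(fs, 20000)), 6000)

  # stress scales exactly linearly with the Young's modulus
  expect_identical(stressPa(computeStrain(fs, 40000)), 12000)

  # Green strain adds the quadratic term
  sg <- computeStrain(fs, 20000, definition = "green")
  expect_equal(max(sg@Ex), 0.3 + 0.5 * 0.09, tolerance = 1e-12)

  expect_error(computeStrain(
    new("DisplacementField", grid_x_um = c(0, 5), grid_y_um = c(0, 5),
        ux_um = matrix(0, 2, 2), uy_um = matrix(0, 2, 2),
        grid_spacing_um = 5), 20000), "grid too small")
})

test_that("rigid motion of the loaded frame leaves strain unchanged", {
  sim <- simulateBeadPair(tipPullField(localization_noise_um = 0, seed = 5L),
                          region_um = c(-60, 60, -60, 60))
  rec1 <- reconstructStrain(sim@ref_obs, sim@loaded_obs,
                            max_search_radius_um = 15)
  shifted <- sweep(sim@loaded_obs, 2, c(1.2, -0.7), "+")
  rec2 <- reconstructStrain(sim@ref_obs, shifted,
                            max_search_radius_um = 15)
  expect_lt(max(abs(totalStrain(rec2$strain) - totalStrain(rec1$strain))),
            1e-8)
})

test_that("reconstructed peak strain matches the closed form within 5%", {
  sim <- simulateBeadPair(paperScaleField(seed = 4L),
                          region_um = c(-80, 80, -80, 80))
  rec <- reconstructStrain(sim@ref_obs, sim@loaded_obs,
                           max_search_radius_um = 18,
                           grid_spacing_um = 4)
  expect_lt(abs(peakStrain(rec$strain) - 0.3) / 0.3, 0.05)
})

test_that("halving the grid spacing barely moves the peak strain", {
  # smooth noiseless field: grid-refinement consistency of the estimator
  f <- tipPullField(pull_vector_um = c(10, 0), decay_sigma_um = 40,
                    bead_density_per_um2 = 0.04,
                    localization_noise_um = 0, seed = 8L)
  sim <- simulateBeadPair(f, region_um = c(-80, 80, -80, 80))
  m <- matchBeadsRobust(sim@ref_obs, sim@loaded_obs, 15)
  p1 <- peakStrain(computeStrain(interpolateDisplacement(m, 4), 20000))
  p2 <- peakStrain(computeStrain(interpolateDisplacement(m, 2), 20000))
  expect_lt(abs(p2 - p1) / p1, 0.02)
  # and both agree with the closed-form peak on this clean field
  expect_lt(abs(p1 - 10 / (40 * sqrt(exp(1)))) / p1, 0.02)
})

test_that("display rasters clip to the conventional map ranges", {
  sim <- simulateBeadPair(paperScaleField(seed = 6L),
                          region_um = c(-80, 80, -80, 80))
  maps <- renderMaps(sim@field, sim@strain)
  expect_equal(attr(maps$displacement, "display_range"), c(0, 15))
  expect_equal(attr(maps$strain, "display_range"), c(0, 0.3))
  # field calibrated to peak strain 0.3 and |u| max ~14.8: strain raster
  # reaches the top of its range, displacement raster stays within
  expect_equal(max(maps$strain), 0.3, tolerance = 1e-9)
  expect_lte(max(maps$displacement), 15)
  expect_gt(max(maps$displacement), 14)
  # zero field: both rasters at the range minimum
  sim0 <- simulateBeadPair(tipPullField(pull_vector_um = c(0, 0)),
                           region_um = c(-40, 40, -40, 40))
  maps0 <- renderMaps(sim0@field, sim0@strain)
  expect_true(all(maps0$displacement == 0) && all(maps0$strain == 0))
})
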