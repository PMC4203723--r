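#' @include AllClasses.R
NULL

#' Localize fiducial beads with subpixel accuracy
#'
#' Candidate beads are local intensity maxima above `min_intensity`
#' (non-maximum suppression over one bead diameter); each candidate is
#' refined by an intensity-weighted centroid of the background-subtracted
#' window around it.
#'
#' @param image numeric matrix of counts (rows = y, cols = x).
#' @param expected_diameter_um approximate bead image diameter (um).
#' @param pixel_size_um pixel size (um/pixel).
#' @param min_intensity minimum peak counts; defaults to the image median
#'   plus 5 median absolute deviations.
#' @return n x 2 matrix (x_um, y_um) of bead centers (0-based pixel-center
#'   convention, in um); empty with a warning when none are found.
#' @export
detectBeads <- function(image, expected_diameter_um = 1, pixel_size_um = 0.5,
                        min_intensity = NULL) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (is.null(min_intensity)) {
    min_intensity <- median(image) + 5 * max(mad(image), 1e-12)
  }
  ny <- nrow(image)
  nx <- ncol(image)
  r <- max(1L, as.integer(round(expected_diameter_um / pixel_size_um)))

  cand <- which(image > min_intensity, arr.ind = TRUE)
  # keep only strict local maxima within a (2r+1) window
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    wi <- max(1, i - r):min(ny, i + r)
    wj <- max(1, j - r):min(nx, j + r)
    w <- image[wi, wj]
    keep[k] <- image[i, j] >= max(w) &&
      sum(w == max(w)) == 1L  # unique maximum in the window
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no beads found above min_intensity")
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("x_um", "y_um"))))
  }

  out <- matrix(NA_real_, nrow(cand), 2)
  rc <- r + 1L  # centroid window slightly wider than the suppression radius
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    wi <- max(1, i - rc):min(ny, i + rc)
    wj <- max(1, j - rc):min(nx, j + rc)
    w <- image[wi, wj] - min(image[wi, wj])
    tot <- sum(w)
    if (tot <= 0) {
      out[k, ] <- c(j - 1, i - 1)
    } else {
      cy <- sum(rowSums(w) * (wi - 1)) / tot
      cx <- sum(colSums(w) * (wj - 1)) / tot
      out[k, ] <- c(cx, cy)
    }
  }
  out <- out * pixel_size_um
  colnames(out) <- c("x_um", "y_um")
  out[order(out[, 2], out[, 1]), , drop = FALSE]
}

# Greedy ascending-distance one-to-one assignment between two point sets.
# Returns an m x 2 matrix of (ref index, loaded index) pairs.
.greedyPairs <- function(ref, loaded, radius) {
  nr <- nrow(ref)
  nl <- nrow(loaded)
  d2 <- outer(ref[, 1], loaded[, 1], "-")^2 +
        outer(ref[, 2], loaded[, 2], "-")^2
  ok <- which(d2 <= radius^2)
  if (!length(ok)) return(matrix(integer(0), 0, 2))
  ord <- ok[order(d2[ok])]
  ri <- ((ord - 1) %% nr) + 1L
  li <- ((ord - 1) %/% nr) + 1L
  used_r <- logical(nr)
  used_l <- logical(nl)
  out_r <- integer(0)
  out_l <- integer(0)
  for (k in seq_along(ord)) {
    if (!used_r[ri[k]] && !used_l[li[k]]) {
      used_r[ri[k]] <- TRUE
      used_l[li[k]] <- TRUE
      out_r <- c(out_r, ri[k])
      out_l <- c(out_l, li[k])
    }
  }
  cbind(out_r, out_l)
}

#' Match beads between reference and loaded frames
#'
#' Globally consistent nearest-neighbor assignment: candidate pairs within
#' `max_search_radius_um` are accepted greedily in ascending distance order,
#' never reusing a bead.  Reliable when displacements are small compared to
#' the inter-bead spacing; for deformations comparable to or larger than the
#' spacing use [matchBeadsIterative()].
#'
#' @param ref,loaded bead coordinates (n x 2 matrices or data.frames with
#'   x_um / y_um columns).
#' @param max_search_radius_um maximum allowed pair distance (um).
#' @return a [BeadMatchSet-class]; errors when no pair matches.
#' @export
matchBeads <- function(ref, loaded, max_search_radius_um = 5) {
  ref <- .beadXY(ref, "ref")
  loaded <- .beadXY(loaded, "loaded")
  if (!nrow(ref) || !nrow(loaded)) stop("both frames must contain beads")
  pairs <- .greedyPairs(ref, loaded, max_search_radius_um)
  if (!nrow(pairs)) {
    stop("zero bead matches within max_search_radius_um")
  }
  new("BeadMatchSet",
      ref_xy_um = ref[pairs[, 1], , drop = FALSE],
      loaded_xy_um = loaded[pairs[, 2], , drop = FALSE],
      unmatched_ref = as.integer(nrow(ref) - nrow(pairs)),
      unmatched_loaded = as.integer(nrow(loaded) - nrow(pairs)),
      max_search_radius_um = max_search_radius_um)
}

# median nearest-neighbor spacing of a point set
.nnSpacing <- function(xy) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  median(apply(d, 1, min))
}

# Local-linear (first-order Savitzky-Golay style) smoother of scattered
# displacements, evaluated at arbitrary points.  Coordinates are centered
# and scaled by the bandwidth before fitting, with a small ridge on the
# slope terms, so the fit stays stable for one-sided neighbor sets.
.localLinear <- function(pts, mref, disp, h, ridge = 1e-6) {
  n <- nrow(pts)
  u <- matrix(0, n, 2)
  hs <- if (length(h) == 1L) rep(h, n) else h
  for (i in seq_len(n)) {
    zx <- (mref[, 1] - pts[i, 1]) / hs[i]
    zy <- (mref[, 2] - pts[i, 2]) / hs[i]
    w <- exp(-(zx^2 + zy^2) / 2)
    sw <- sum(w)
    if (sw < 1e-10) next
    if (sum(w > 0.05) < 5) {
      u[i, ] <- colSums(disp * w) / sw
      next
    }
    X <- cbind(1, zx, zy)
    XW <- X * w
    A <- crossprod(XW, X) + diag(c(0, ridge * sw, ridge * sw))
    b <- tryCatch(solve(A, crossprod(XW, disp)), error = function(e) NULL)
    u[i, ] <- if (is.null(b) || !all(is.finite(b))) colSums(disp * w) / sw
              else b[1, ]
  }
  u
}

# Normalized local-plane consistency statistics: for each matched bead,
# fit a plane to the displacements of its k nearest matched neighbors,
# leaving the bead itself out, and compare the bead's displacement to the
# plane prediction.  Gradient-corrected analogue of the normalized median
# test used to validate particle-tracking vectors.  The plane is chosen by
# (approximate) least median of squares over a fixed set of neighbor
# triples, so a coherent minority of wrong matches among the neighbors
# cannot drag the fit towards itself.
.planeStats <- function(mref, disp, k = 10) {
  n <- nrow(mref)
  d <- as.matrix(dist(mref))
  diag(d) <- Inf
  fluct <- numeric(n)
  spread <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(min(k, n - 1))]
    kn <- length(nb)
    # deterministic spread-out candidate triples within the neighborhood
    third <- max(1, floor(kn / 3))
    triples <- lapply(0:7, function(t) 1 + (c(0, third, 2 * third) + t) %% kn)
    X <- cbind(1, mref[nb, 1] - mref[i, 1], mref[nb, 2] - mref[i, 2])
    U <- disp[nb, , drop = FALSE]
    best_med <- Inf
    best_b <- NULL
    for (tri in triples) {
      if (any(tri > kn)) next
      b <- tryCatch(solve(X[tri, , drop = FALSE], U[tri, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(b) || !all(is.finite(b))) next
      r <- sqrt(rowSums((U - X %*% b)^2))
      m <- median(r)
      if (m < best_med) {
        best_med <- m
        best_b <- b
      }
    }
    if (is.null(best_b)) {
      # fall back to the least-squares plane
      best_b <- tryCatch(qr.solve(X, U), error = function(e) NULL)
      if (is.null(best_b)) {
        spread[i] <- Inf
        next
      }
      best_med <- median(sqrt(rowSums((U - X %*% best_b)^2)))
    }
    spread[i] <- best_med
    fluct[i] <- sqrt(sum((disp[i, ] - best_b[1, ])^2))
  }
  list(fluct = fluct, spread = spread)
}

# Iterative peeling with the robust plane test: repeatedly drop matches
# whose displacement deviates from the local consensus plane by more than
# `thresh` times the neighbor spread (with an absolute floor tied to the
# global fluctuation level), until stable.  Peeling dismantles clusters of
# mutually consistent wrong matches from the outside.
.planeKeepIter <- function(mref, disp, k = 10, thresh = 3, eps = 0.1,
                           max_rounds = 10) {
  keep <- rep(TRUE, nrow(mref))
  if (nrow(mref) <= k + 2) return(keep)
  for (r in seq_len(max_rounds)) {
    st <- .planeStats(mref[keep, , drop = FALSE],
                      disp[keep, , drop = FALSE], k)
    bad <- st$fluct > pmax(thresh * (st$spread + eps),
                           5 * median(st$fluct))
    if (!any(bad)) break
    idx <- which(keep)
    keep[idx[bad]] <- FALSE
  }
  keep
}

# Wide-neighborhood quadratic consistency test: like .planeStats but with a
# leave-self-out least-median-of-squares *quadratic* surface over k = 20
# neighbors.  The quadratic absorbs the field's genuine curvature, so the
# only thing that can deviate is a measurement inconsistency; a compact
# cluster of wrong matches (offset by at least one bead spacing) is a
# minority within the wide neighborhood and gets flagged wholesale, where
# it would dominate a 10-neighbor test.
.quadStats <- function(mref, disp, k = 20) {
  n <- nrow(mref)
  d <- as.matrix(dist(mref))
  diag(d) <- Inf
  fluct <- numeric(n)
  spread <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(min(k, n - 1))]
    kn <- length(nb)
    if (kn < 8) {
      spread[i] <- Inf
      next
    }
    sc <- median(d[i, nb])
    dx <- (mref[nb, 1] - mref[i, 1]) / sc
    dy <- (mref[nb, 2] - mref[i, 2]) / sc
    X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2)
    U <- disp[nb, , drop = FALSE]
    sixth <- max(1, floor(kn / 6))
    best_med <- Inf
    best_b <- NULL
    for (t in 0:7) {
      sub <- 1 + (0:5 * sixth + t) %% kn
      b <- tryCatch(solve(X[sub, , drop = FALSE], U[sub, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(b) || !all(is.finite(b))) next
      r <- sqrt(rowSums((U - X %*% b)^2))
      m <- median(r)
      if (m < best_med) {
        best_med <- m
        best_b <- b
      }
    }
    if (is.null(best_b)) {
      best_b <- tryCatch(qr.solve(X, U), error = function(e) NULL)
      if (is.null(best_b)) {
        spread[i] <- Inf
        next
      }
      best_med <- median(sqrt(rowSums((U - X %*% best_b)^2)))
    }
    spread[i] <- best_med
    fluct[i] <- sqrt(sum((disp[i, ] - best_b[1, ])^2))
  }
  list(fluct = fluct, spread = spread)
}

# cluster-scale peeling with the quadratic test
.quadKeepIter <- function(mref, disp, k = 20, thresh = 3, eps = 0.1,
                          max_rounds = 10) {
  keep <- rep(TRUE, nrow(mref))
  if (nrow(mref) <= k + 2) return(keep)
  for (r in seq_len(max_rounds)) {
    st <- .quadStats(mref[keep, , drop = FALSE],
                     disp[keep, , drop = FALSE], k)
    bad <- st$fluct > pmax(thresh * (st$spread + eps),
                           5 * median(st$fluct))
    if (!any(bad)) break
    idx <- which(keep)
    keep[idx[bad]] <- FALSE
  }
  keep
}

# Barnard-Thompson relaxation labeling: candidate pair probabilities are
# iteratively reinforced by the support of displacement-compatible
# candidates of neighboring reference beads.  Two candidates are compatible
# when their displacements differ by less than a tolerance that grows with
# the neighbor distance times `strain_bound` (the largest locally credible
# strain).  Returns the one-to-one assignment of highest converged
# probability.
.relaxAssign <- function(ref, loaded, max_r, strain_bound = 0.35,
                         n_iter = 15, A = 0.3, B = 3, slack = 0.3,
                         p_floor = 0.2) {
  n <- nrow(ref)
  m <- nrow(loaded)
  s <- .nnSpacing(ref)
  nb_r <- 2.2 * s
  d2 <- outer(ref[, 1], loaded[, 1], "-")^2 +
        outer(ref[, 2], loaded[, 2], "-")^2
  cand <- which(d2 <= max_r^2, arr.ind = TRUE)
  if (!nrow(cand)) stop("zero bead matches within max_search_radius_um")
  P_i <- cand[, 1]
  P_j <- cand[, 2]
  np <- nrow(cand)
  dvec <- loaded[P_j, , drop = FALSE] - ref[P_i, , drop = FALSE]
  dn2 <- outer(ref[, 1], ref[, 1], "-")^2 + outer(ref[, 2], ref[, 2], "-")^2
  diag(dn2) <- Inf
  edges <- which(dn2 <= nb_r^2, arr.ind = TRUE)
  byRef <- vector("list", n)
  sp <- split(seq_len(np), P_i)
  byRef[as.integer(names(sp))] <- sp
  bufi <- vector("list", nrow(edges))
  bufj <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    pi_ <- byRef[[edges[e, 1]]]
    pk <- byRef[[edges[e, 2]]]
    if (is.null(pi_) || is.null(pk)) next
    tol_e <- 0.3 + strain_bound * sqrt(dn2[edges[e, 1], edges[e, 2]])
    dd <- outer(dvec[pi_, 1], dvec[pk, 1], "-")^2 +
          outer(dvec[pi_, 2], dvec[pk, 2], "-")^2
    hit <- which(dd <= tol_e^2, arr.ind = TRUE)
    if (nrow(hit)) {
      bufi[[e]] <- pi_[hit[, 1]]
      bufj[[e]] <- pk[hit[, 2]]
    }
  }
  C <- Matrix::sparseMatrix(i = unlist(bufi), j = unlist(bufj), x = 1,
                            dims = c(np, np))
  nnb <- tabulate(edges[, 1], nbins = n)
  P <- 1 / (tabulate(P_i, nbins = n)[P_i] + 1)
  for (it in seq_len(n_iter)) {
    S <- as.numeric(C %*% P) / pmax(nnb[P_i], 1)
    Pn <- P * (A + B * S)
    tot <- rowsum(Pn, P_i)[, 1]
    P <- Pn / (tot[P_i] + slack * mean(tot))
  }
  o <- order(P, decreasing = TRUE)
  used_r <- logical(n)
  used_l <- logical(m)
  sel <- logical(np)
  for (k in o) {
    if (P[k] < p_floor) break
    if (!used_r[P_i[k]] && !used_l[P_j[k]]) {
      used_r[P_i[k]] <- TRUE
      used_l[P_j[k]] <- TRUE
      sel[k] <- TRUE
    }
  }
  cbind(P_i[sel], P_j[sel])
}

#' Robust bead matching for large coherent deformations
#'
#' Greedy nearest-neighbor matching breaks down once displacements exceed
#' the inter-bead spacing (a tip-pull experiment moves beads by up to 15 um
#' against a ~2.5 um spacing).  This matcher uses relaxation labeling
#' (iteratively reinforcing candidate pairs whose displacement agrees with
#' that of neighboring beads' candidates, the classical approach in
#' particle-tracking velocimetry) to establish the coherent correspondence,
#' then refines it: outliers are peeled off with a local-plane consistency
#' test, a smooth local-linear displacement predictor is fitted, the frames
#' are re-matched greedily on the small residuals, and the final match set
#' is validated with the same plane test.
#'
#' @param ref,loaded bead coordinates as in [matchBeads()].
#' @param max_search_radius_um candidate radius; must exceed the largest
#'   expected displacement (um).
#' @param strain_bound largest locally credible strain, used for the
#'   displacement-compatibility tolerance between neighboring beads.
#' @return a [BeadMatchSet-class].
#' @export
matchBeadsRobust <- function(ref, loaded, max_search_radius_um = 20,
                             strain_bound = 0.35) {
  ref <- .beadXY(ref, "ref")
  loaded <- .beadXY(loaded, "loaded")
  if (!nrow(ref) || !nrow(loaded)) stop("both frames must contain beads")
  s <- .nnSpacing(ref)
  validKeep <- function(mref, mdisp) {
    .planeKeepIter(mref, mdisp) & .quadKeepIter(mref, mdisp)
  }
  pairs <- .relaxAssign(ref, loaded, max_search_radius_um, strain_bound)
  disp <- loaded[pairs[, 2], , drop = FALSE] - ref[pairs[, 1], , drop = FALSE]
  keep <- validKeep(ref[pairs[, 1], , drop = FALSE], disp)
  u_pred <- .localLinear(ref, ref[pairs[keep, 1], , drop = FALSE],
                         disp[keep, , drop = FALSE], 1.3 * s)
  pairs <- .greedyPairs(ref + u_pred, loaded, 0.8 * s)
  if (!nrow(pairs)) stop("zero bead matches within max_search_radius_um")
  disp <- loaded[pairs[, 2], , drop = FALSE] - ref[pairs[, 1], , drop = FALSE]
  keep <- validKeep(ref[pairs[, 1], , drop = FALSE], disp)
  pairs <- pairs[keep, , drop = FALSE]
  rm_ <- ref[pairs[, 1], , drop = FALSE]
  lm_ <- loaded[pairs[, 2], , drop = FALSE]
  dmax <- max(sqrt(rowSums((lm_ - rm_)^2)))
  new("BeadMatchSet",
      ref_xy_um = rm_, loaded_xy_um = lm_,
      unmatched_ref = as.integer(nrow(ref) - nrow(pairs)),
      unmatched_loaded = as.integer(nrow(loaded) - nrow(pairs)),
      max_search_radius_um = max(max_search_radius_um, dmax))
}

# Thin-plate-spline system: kernel U(r) = r^2 log(r) (0 at r = 0).
.tpsKernel <- function(d2) {
  k <- matrix(0, nrow(d2), ncol(d2))
  pos <- d2 > 0
  k[pos] <- 0.5 * d2[pos] * log(d2[pos])  # r^2 log r = d2 * log(sqrt(d2))
  k
}

#' Interpolate scattered bead displacements onto a regular grid
#'
#' Two estimators are offered.  `method = "tps"` (the default) is
#' thin-plate-spline interpolation: with `lambda = 0` the surface passes
#' exactly through every bead displacement, a positive `lambda` trades
#' fidelity at the beads for smoothness.  `method = "loclin"` is an
#' adaptive local-linear smoother: each grid node carries a weighted
#' first-order fit of the surrounding displacements with a Gaussian kernel
#' whose bandwidth widens, where beads are sparse, until at least `k_min`
#' beads support the fit.  Exact interpolation differentiates bead
#' localization noise straight into spurious strain, so the smoother is the
#' better choice for measured (noisy) bead positions; the spline is exact
#' for clean data.
#'
#' @param matches a [BeadMatchSet-class].
#' @param grid_spacing_um grid node spacing (um).
#' @param method "tps" (exact thin-plate spline) or "loclin" (adaptive
#'   local-linear smoother).
#' @param lambda TPS smoothing parameter (dimensionless, >= 0); 0 = exact
#'   interpolation.
#' @param bandwidth_um base Gaussian kernel sd of the local-linear
#'   smoother (um).
#' @param k_min minimum number of beads supporting each local fit; the
#'   bandwidth grows to 0.6x the distance to the k_min-th nearest bead
#'   where needed.
#' @param bbox optional c(xmin, xmax, ymin, ymax) grid extent; defaults to
#'   the matched-bead bounding box inset by two grid spacings, so the field
#'   is only reconstructed where it is supported by data on all sides
#'   (both estimators extrapolate poorly outside the bead hull).
#' @return a [DisplacementField-class].
#' @export
interpolateDisplacement <- function(matches, grid_spacing_um = 5,
                                    method = c("tps", "loclin"), lambda = 0,
                                    bandwidth_um = 3.5, k_min = 8,
                                    bbox = NULL) {
  stopifnot(is(matches, "BeadMatchSet"))
  method <- match.arg(method)
  xy <- matches@ref_xy_um
  n <- nrow(xy)
  if (n < 4L) stop("need at least 4 matched beads")
  if (qr(cbind(1, xy))$rank < 3L) {
    stop("degenerate bead geometry (collinear beads)")
  }
  u <- matches@loaded_xy_um - xy

  if (is.null(bbox)) {
    inset <- 2 * grid_spacing_um
    bbox <- c(min(xy[, 1]) + inset, max(xy[, 1]) - inset,
              min(xy[, 2]) + inset, max(xy[, 2]) - inset)
    if (bbox[2] - bbox[1] < grid_spacing_um ||
        bbox[4] - bbox[3] < grid_spacing_um) {
      bbox <- c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
    }
  }
  grid_x <- seq(bbox[1], bbox[2], by = grid_spacing_um)
  grid_y <- seq(bbox[3], bbox[4], by = grid_spacing_um)
  gx <- rep(grid_x, each = length(grid_y))
  gy <- rep(grid_y, times = length(grid_x))

  if (method == "tps") {
    d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
    K <- .tpsKernel(d2)
    # scale-aware ridge: lambda is relative to the mean kernel magnitude
    if (lambda > 0) {
      K <- K + diag(n) * lambda * mean(abs(K))
    }
    P <- cbind(1, xy)
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    rhs <- rbind(u, matrix(0, 3, 2))
    coef <- solve(A, rhs)
    d2g <- outer(gx, xy[, 1], "-")^2 + outer(gy, xy[, 2], "-")^2
    E <- cbind(.tpsKernel(d2g), 1, gx, gy)
    ug <- E %*% coef
  } else {
    pts <- cbind(gx, gy)
    dmat <- sqrt(outer(gx, xy[, 1], "-")^2 + outer(gy, xy[, 2], "-")^2)
    kth <- min(k_min, n)
    dk <- apply(dmat, 1, function(r) sort(r, partial = kth)[kth])
    hs <- pmax(bandwidth_um, 0.6 * dk)
    ug <- .localLinear(pts, xy, u, hs)
  }
  new("DisplacementField",
      grid_x_um = grid_x, grid_y_um = grid_y,
      ux_um = matrix(ug[, 1], length(grid_y), length(grid_x)),
      uy_um = matrix(ug[, 2], length(grid_y), length(grid_x)),
      grid_spacing_um = grid_spacing_um)
}

# central finite differences along matrix columns (x) / rows (y),
# one-sided at the borders
.gradX <- function(m, h) {
  nx <- ncol(m)
  g <- m
  g[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * h)
  g[, 1] <- (m[, 2] - m[, 1]) / h
  g[, nx] <- (m[, nx] - m[, nx - 1]) / h
  g
}

.gradY <- function(m, h) {
  ny <- nrow(m)
  g <- m
  g[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * h)
  g[1, ] <- (m[2, ] - m[1, ]) / h
  g[ny, ] <- (m[ny, ] - m[ny - 1, ]) / h
  g
}

#' Strain-index map, peak strain and stress from a displacement field
#'
#' Normal strains Ex = d(ux)/dx and Ey = d(uy)/dy by central finite
#' differences (one-sided at grid borders) and the total strain index
#' E_total = sqrt(Ex^2 + Ey^2).  The peak strain is the maximum E_total over
#' the query region (the whole field by default; pass a cell mask to
#' measure the strain of the substrate at the position of the cell), and
#' stress = peak strain x Young's modulus (N/m^2).  `definition = "green"`
#' adds the quadratic Green-strain terms
#' Ex = d(ux)/dx + ((d(ux)/dx)^2 + (d(uy)/dx)^2) / 2 (and symmetrically for
#' Ey).
#'
#' @param field a [DisplacementField-class] with at least a 3 x 3 grid.
#' @param young_modulus_pa substrate Young's modulus (Pa); e.g. 20000 for a
#'   20 kPa polyacrylamide gel.
#' @param query_region optional logical matrix (same shape as the grid)
#'   restricting the peak-strain search.
#' @param definition "small" (default) or "green".
#' @return a [StrainMap-class].
#' @examples
#' # linear stretch ux = 0.1 x: Ex = E_total = 0.1 everywhere
#' gx <- seq(0, 40, by = 5); gy <- seq(0, 40, by = 5)
#' f <- new("DisplacementField", grid_x_um = gx, grid_y_um = gy,
#'          ux_um = outer(rep(1, 9), 0.1 * gx), uy_um = matrix(0, 9, 9),
#'          grid_spacing_um = 5)
#' stressPa(computeStrain(f, young_modulus_pa = 20000))  # 0.1 * 20000
#' @export
computeStrain <- function(field, young_modulus_pa = 20000,
                          query_region = NULL,
                          definition = c("small", "green")) {
  stopifnot(is(field, "DisplacementField"))
  definition <- match.arg(definition)
  ny <- length(field@grid_y_um)
  nx <- length(field@grid_x_um)
  if (ny < 3L || nx < 3L) stop("grid too small: need at least 3 x 3 nodes")
  h <- field@grid_spacing_um
  dux_dx <- .gradX(field@ux_um, h)
  duy_dy <- .gradY(field@uy_um, h)
  if (definition == "small") {
    Ex <- dux_dx
    Ey <- duy_dy
  } else {
    duy_dx <- .gradX(field@uy_um, h)
    dux_dy <- .gradY(field@ux_um, h)
    Ex <- dux_dx + 0.5 * (dux_dx^2 + duy_dx^2)
    Ey <- duy_dy + 0.5 * (duy_dy^2 + dux_dy^2)
  }
  Et <- sqrt(Ex^2 + Ey^2)
  if (is.null(query_region)) {
    peak <- max(Et)
  } else {
    if (!all(dim(query_region) == dim(Et))) {
      stop("query_region must match the grid dimensions")
    }
    if (!any(query_region)) stop("empty query region")
    peak <- max(Et[query_region])
  }
  new("StrainMap",
      grid_x_um = field@grid_x_um, grid_y_um = field@grid_y_um,
      Ex = Ex, Ey = Ey, E_total = Et, peak_strain = peak,
      young_modulus_pa = young_modulus_pa,
      stress_pa = peak * young_modulus_pa,
      definition = definition)
}

#' Display rasters for displacement and strain maps
#'
#' Clips the displacement magnitude and total strain index to fixed display
#' ranges (defaults 0-15 um and 0-0.3, the conventional ranges for this
#' kind of map) and records the range used.
#'
#' @param field a [DisplacementField-class].
#' @param strain a [StrainMap-class] on the same grid.
#' @param displacement_range_um,strain_range display ranges c(lo, hi).
#' @return list with `displacement` and `strain` matrices (clipped) carrying
#'   a "display_range" attribute each.
#' @export
renderMaps <- function(field, strain,
                       displacement_range_um = c(0, 15),
                       strain_range = c(0, 0.3)) {
  stopifnot(is(field, "DisplacementField"), is(strain, "StrainMap"))
  mag <- sqrt(field@ux_um^2 + field@uy_um^2)
  disp <- pmin(pmax(mag, displacement_range_um[1]), displacement_range_um[2])
  attr(disp, "display_range") <- displacement_range_um
  st <- pmin(pmax(strain@E_total, strain_range[1]), strain_range[2])
  attr(st, "display_range") <- strain_range
  list(displacement = disp, strain = st)
}

#' Reconstruct displacement, strain and stress from bead frames
#'
#' The full measurement pipeline for one loading experiment: establish the
#' bead correspondence between the unloaded reference frame and the loaded
#' frame ([matchBeadsRobust()] by default, which tolerates displacements
#' several times the bead spacing), interpolate the matched displacements
#' onto a regular grid (the adaptive local-linear smoother by default,
#' suited to localization-noise-corrupted bead positions), and derive the
#' strain-index map, peak strain and stress.
#'
#' @param ref,loaded bead coordinates of the reference (unloaded) and
#'   loaded frames.
#' @param young_modulus_pa substrate Young's modulus (Pa); 20000 for the
#'   typical 20 kPa polyacrylamide gel.
#' @param grid_spacing_um grid spacing of the reconstructed field (um).
#' @param max_search_radius_um matching radius (um); must exceed the
#'   largest expected displacement.
#' @param method interpolation method, see [interpolateDisplacement()];
#'   default "loclin".
#' @param robust use [matchBeadsRobust()] (default) or plain greedy
#'   [matchBeads()].
#' @param query_region optional logical matrix restricting the peak-strain
#'   search (e.g. a cell mask).  The peak is always restricted to
#'   data-supported grid nodes - those within 1.5 median bead spacings of a
#'   matched bead - because the interpolated field is unreliable inside
#'   coverage holes; a supplied query_region is intersected with that
#'   support mask.
#' @param definition passed to [computeStrain()].
#' @param ... further arguments to [interpolateDisplacement()].
#' @return list with `matches` ([BeadMatchSet-class]), `field`
#'   ([DisplacementField-class]) and `strain` ([StrainMap-class]).
#' @export
reconstructStrain <- function(ref, loaded, young_modulus_pa = 20000,
                              grid_spacing_um = 4,
                              max_search_radius_um = 20,
                              method = "loclin", robust = TRUE,
                              query_region = NULL, definition = "small",
                              ...) {
  matches <- if (robust) {
    matchBeadsRobust(ref, loaded, max_search_radius_um)
  } else {
    matchBeads(ref, loaded, max_search_radius_um)
  }
  field <- interpolateDisplacement(matches, grid_spacing_um,
                                   method = method, ...)
  xy <- matches@ref_xy_um
  dmin <- matrix(
    apply(sqrt(outer(rep(field@grid_x_um, each = length(field@grid_y_um)),
                     xy[, 1], "-")^2 +
               outer(rep(field@grid_y_um, times = length(field@grid_x_um)),
                     xy[, 2], "-")^2), 1, min),
    length(field@grid_y_um), length(field@grid_x_um))
  support <- dmin <= 1.5 * .nnSpacing(xy)
  if (!is.null(query_region)) support <- support & query_region
  strain <- computeStrain(field, young_modulus_pa, support, definition)
  list(matches = matches, field = field, strain = strain)
}
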