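# Periodic Poisson solve: del^2 chi = div V, spectral inversion on the box
# grid. V arrays are (n1, n2, n3); returns chi with zero mean.
poisson_indicator <- function(Vx, Vy, Vz, box) {
  d <- dim(Vx)
  kvec <- function(n, L) {
    f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
    if (n == 1) f <- 0
    2 * pi * f[1:n] / L
  }
  kx <- kvec(d[1], box[1])
  ky <- kvec(d[2], box[2])
  kz <- kvec(d[3], box[3])
  Vxh <- fft(Vx)
  Vyh <- fft(Vy)
  Vzh <- fft(Vz)
  KX <- array(kx, d)
  KY <- array(rep(ky, each = d[1]), d)
  KZ <- array(rep(kz, each = d[1] * d[2]), d)
  k2 <- KX^2 + KY^2 + KZ^2
  divh <- 1i * (KX * Vxh + KY * Vyh + KZ * Vzh)
  k2[1] <- Inf
  chih <- -divh / k2
  Re(fft(chih, inverse = TRUE)) / prod(d)
}

# Periodic trilinear interpolation of a grid field at points.
trilinear <- function(field, off, h, points) {
  d <- dim(field)
  out <- numeric(nrow(points))
  fx <- (points[, 1] - off[1]) / h[1]
  fy <- (points[, 2] - off[2]) / h[2]
  fz <- (points[, 3] - off[3]) / h[3]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  wrap <- function(i, n) ((i %% n) + n) %% n + 1
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
      (if (dk) tz else 1 - tz)
    idx <- cbind(wrap(i0 + di, d[1]), wrap(j0 + dj, d[2]),
                 wrap(k0 + dk, d[3]))
    out <- out + w * field[idx]
  }
  out
}

#' Reconstruct a triangulated leaflet surface from an oriented point cloud
#'
#' Solves the indicator-function problem on a periodic grid spanning the
#' simulation box: the oriented normals are splatted onto the grid with a
#' Gaussian kernel, and the scalar indicator (one on the tail side of the
#' leaflet, zero on the solvent side) is obtained by spectrally inverting the
#' Poisson equation whose right-hand side is the divergence of that vector
#' field. The iso-surface at the mean indicator value over the input points
#' is extracted by marching tetrahedra, giving a triangle mesh spanning the
#' box with an open seam at the periodic faces (flagged as boundary tiles).
#'
#' The grid is anchored to the cloud centroid modulo the cell size, which
#' makes the reconstruction exactly equivariant under rigid translations of
#' the input. Components not supported by data (e.g. the compensating sheet
#' a periodic Poisson solve produces for an open surface) and components
#' below 1% of the total area are dropped.
#'
#' @param cloud an `oriented_cloud` from [make_oriented_cloud()].
#' @param grid_factor grid cell size as a fraction of the mean anchor
#'   spacing.
#' @param sigma_factor Gaussian splat width as a fraction of the mean anchor
#'   spacing.
#' @param max_dist_tol warn if any input point is farther than this (in
#'   Angstrom) from the reconstructed surface.
#' @return a `leaflet_mesh`; mesh normals are consistent with the cloud
#'   normals (pointing toward the lipid tails).
#' @export
reconstruct_surface <- function(cloud, grid_factor = 0.5, sigma_factor = 1.0,
                                max_dist_tol = 3) {
  pts <- cloud$points
  if (nrow(pts) < 10) {
    stop("surface reconstruction needs at least 10 oriented points (got ",
         nrow(pts), ")")
  }
  box <- cloud$box
  sp <- cloud$spacing
  h0 <- grid_factor * sp
  dims <- pmax(8L, as.integer(round(box / h0)))
  h <- box / dims
  # grid anchored to the circular mean of the cloud: exactly equivariant
  # under rigid translations even when coordinates wrap at the box faces
  ang <- sweep(pts, 2, 2 * pi / box, "*")
  cmean <- atan2(colMeans(sin(ang)), colMeans(cos(ang))) * box / (2 * pi)
  off <- cmean %% h
  sigma <- sigma_factor * sp
  V <- cpp_splat(pts, cloud$normals, dims, off, h, sigma, 2.5 * sigma)
  ntot <- prod(dims)
  Vx <- array(V[1:ntot], dims)
  Vy <- array(V[ntot + 1:ntot], dims)
  Vz <- array(V[2 * ntot + 1:ntot], dims)
  chi <- poisson_indicator(Vx, Vy, Vz, box)
  iso <- mean(trilinear(chi, off, h, pts))
  # roll the periodic field so the extraction cut (the open seam where
  # boundary censoring acts) sits at the antipode of the cloud's circular
  # mean -- through the data-sparse half of the box, never through an
  # interior object -- and moves rigidly with the data, so the boundary
  # censoring is equivariant under translations too
  kroll <- as.integer(round((((cmean + box / 2) %% box) - off) / h)) %% dims
  chi <- chi[((seq_len(dims[1]) - 1 + kroll[1]) %% dims[1]) + 1,
             ((seq_len(dims[2]) - 1 + kroll[2]) %% dims[2]) + 1,
             ((seq_len(dims[3]) - 1 + kroll[3]) %% dims[3]) + 1,
             drop = FALSE]
  off <- off + kroll * h
  mt <- cpp_marching_tetra(as.numeric(chi), dims, off, h, iso)
  if (!nrow(mt$triangles)) {
    stop("reconstruction produced no triangles; decrease grid_factor or ",
         "check normal orientation")
  }

  # drop components not supported by the data or below 1% of the total area
  comp <- mesh_triangle_components(mt$vertices, mt$triangles)
  v <- mt$vertices
  f <- mt$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  areas <- 0.5 * sqrt(rowSums(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                    u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                    u[, 1] * w[, 2] - u[, 2] * w[, 1])^2))
  tot <- sum(areas)
  keep_comp <- vapply(sort(unique(comp)), function(cmp) {
    sel <- comp == cmp
    if (sum(areas[sel]) < 0.01 * tot) return(FALSE)
    vid <- unique(as.vector(f[sel, , drop = FALSE]))
    vs <- v[vid, , drop = FALSE]
    # wrap into the box for distance checks against the (wrapped) cloud
    vs_w <- sweep(vs, 2, box, function(x, L) x - L * floor(x / L))
    nidx <- cpp_nearest(vs_w, pts, max(sp, 1))
    dd <- vs_w - pts[nidx, , drop = FALSE]
    dd <- min_image(dd, box)
    median(sqrt(rowSums(dd^2))) <= 3 * sp
  }, TRUE)
  kept <- sort(unique(comp))[keep_comp]
  if (!length(kept)) {
    stop("all reconstructed components were rejected as unsupported by the ",
         "point data; check normal orientation")
  }
  if (length(kept) < length(unique(comp))) {
    sel <- comp %in% kept
    f <- f[sel, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    f <- matrix(remap[f], ncol = 3)
    v <- v[used, , drop = FALSE]
  }
  mesh <- leaflet_mesh(v, f, box)

  # diagnostics: data support (distance along the local face normal to the
  # nearest tile, a tight surface-distance estimate for smooth meshes) and
  # normal consistency
  mw <- sweep(mesh$midpoints, 2, box, function(x, L) x - L * floor(x / L))
  nidx <- cpp_nearest(pts, mw, max(sp, 1))
  dd <- min_image(pts - mw[nidx, , drop = FALSE], box)
  maxd <- max(abs(rowSums(dd * mesh$face_normals[nidx, , drop = FALSE])))
  if (maxd > max_dist_tol + sp) {
    warning(sprintf("maximum point-to-surface distance %.2f A exceeds %.1f A",
                    maxd, max_dist_tol))
  }
  midw <- sweep(mesh$midpoints, 2, box, function(x, L) x - L * floor(x / L))
  near_pt <- cpp_nearest(midw, pts, max(sp, 1))
  frac_consistent <- mean(rowSums(mesh$face_normals *
                                    cloud$normals[near_pt, , drop = FALSE]) > 0)
  attr(mesh, "max_point_dist") <- maxd
  attr(mesh, "normal_consistency") <- frac_consistent
  mesh$origin <- off   # cover origin: mesh coordinates live in [off, off + L]
  mesh
}
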