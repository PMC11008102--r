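make_plane_cloud <- function(n_side = 20, s = 7.75, z0 = 50, sigma = 0.5,
                             seed = 1, lz = 100) {
  set.seed(seed)
  g <- expand.grid(i = seq_len(n_side) - 0.5, j = seq_len(n_side) - 0.5)
  pts <- cbind(g$i * s, g$j * s, z0) +
    matrix(rnorm(3 * nrow(g), 0, sigma), ncol = 3)
  structure(list(points = pts,
                 normals = matrix(rep(c(0, 0, -1), nrow(pts)), ncol = 3,
                                  byrow = TRUE),
                 residue_id = seq_len(nrow(pts)) - 1L,
                 box = c(n_side * s, n_side * s, lz), spacing = s),
            class = "oriented_cloud")
}

make_sphere_cloud <- function(R = 100, apl = 60, sigma = 0.5, seed = 1,
                              pad = 60) {
  set.seed(seed)
  n <- round(4 * pi * R^2 / apl)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  L <- 2 * (R + pad)
  pts <- sweep(R * dirs, 2, rep(L / 2, 3), "+") +
    matrix(rnorm(3 * n, 0, sigma), ncol = 3)
  structure(list(points = pts, normals = -dirs,  # tails inward
                 residue_id = seq_len(n) - 1L, box = rep(L, 3),
                 spacing = sqrt(apl)),
            class = "oriented_cloud")
}

test_that("a jittered plane reconstructs to the patch area", {
  cl <- make_plane_cloud(sigma = 0.5)
  mesh <- reconstruct_surface(cl)
  patch_area <- cl$box[1] * cl$box[2]
  expect_lt(abs(mesh_area(mesh) - patch_area) / patch_area, 0.05)
  # surface passes near the points
  expect_lt(attr(mesh, "max_point_dist"), 3)
  # mesh-to-true-surface distance below jitter + 1 (mesh coordinates live
  # in the unwrapped periodic cover, so wrap before comparing)
  vz <- mesh$vertices[, 3] %% cl$box[3]
  expect_lt(mean(abs(vz - 50)), 0.5 + 1)
  # normals consistent with the cloud (toward tails, i.e. -z)
  expect_gte(attr(mesh, "normal_consistency"), 0.99)
  expect_lt(mean(mesh$face_normals[, 3]), -0.99)
  # periodic flat patch: boundary band present at the seam
  expect_gt(sum(mesh$boundary), 0)
})

test_that("a spherical cloud reconstructs to the closed-form area", {
  cl <- make_sphere_cloud(R = 100)
  mesh <- reconstruct_surface(cl)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100^2) / (4 * pi * 100^2), 0.05)
  # closed surface: no boundary tiles
  expect_equal(sum(mesh$boundary), 0)
  # radial accuracy within jitter + 1
  vw <- sweep(mesh$vertices, 2, cl$box, function(x, L) x - L * floor(x / L))
  r <- sqrt(rowSums(sweep(vw, 2, cl$box / 2)^2))
  expect_lt(mean(abs(r - 100)), 0.5 + 1)
})

test_that("too few points fail loudly", {
  cl <- make_plane_cloud(n_side = 2)
  expect_error(reconstruct_surface(cl), "at least 10")
})

test_that("remeshing reaches the target density and preserves area", {
  cl <- make_plane_cloud(n_side = 12)
  mesh <- reconstruct_surface(cl)
  fine <- remesh_cvt(mesh, target_edge = 1.0, n_iter = 40)
  e <- defectmesh:::mesh_edge_lengths(fine)
  expect_lt(abs(mean(e) - 1.0), 0.2)
  e0 <- defectmesh:::mesh_edge_lengths(mesh)
  expect_lt(sd(e) / mean(e), sd(e0) / mean(e0))  # more uniform than input
  expect_lt(abs(mesh_area(fine) - mesh_area(mesh)) / mesh_area(mesh), 0.02)
  expect_true(all(fine$areas > 0))

  # an already-uniform mesh is (nearly) a fixed point
  again <- remesh_cvt(fine, target_edge = 1.0, n_iter = 4)
  nidx <- defectmesh:::cpp_nearest(fine$vertices, again$vertices, 2)
  disp <- sqrt(rowSums((fine$vertices - again$vertices[nidx, ])^2))
  expect_lt(mean(disp), 0.1 * 1.0)

  expect_error(remesh_cvt(fine, target_edge = 1e5), "diameter")
})

test_that("sphere area survives remeshing", {
  cl <- make_sphere_cloud(R = 80, apl = 70)
  mesh <- remesh_cvt(reconstruct_surface(cl), target_edge = 1.5)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 80^2) / (4 * pi * 80^2), 0.05)
})

test_that("reconstruction is translation-equivariant across the box seam", {
  cl <- make_plane_cloud(n_side = 12, sigma = 0.3)
  m1 <- reconstruct_surface(cl)
  shift <- c(31.4, -12.9, 7.3)
  cl2 <- cl
  cl2$points <- sweep(cl$points, 2, shift, "+")
  cl2$points <- sweep(cl2$points, 2, cl$box,
                      function(x, L) x - L * floor(x / L))
  m2 <- reconstruct_surface(cl2)
  expect_equal(nrow(m2$triangles), nrow(m1$triangles))
  expect_lt(abs(mesh_area(m2) - mesh_area(m1)) / mesh_area(m1), 1e-6)
})
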