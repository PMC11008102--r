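# edge key helpers: vertex pairs packed into doubles (exact below 2^52)
edge_keys <- function(a, b) pmin(a, b) * 2^26 + pmax(a, b)

#' Build a leaflet mesh object
#'
#' Computes per-triangle areas, midpoints, per-vertex normals (area-weighted
#' average of face normals, oriented by the triangle winding: toward the
#' lipid tails for meshes produced by [reconstruct_surface()]), and boundary
#' flags. Triangles touching an open mesh boundary (an edge with a single
#' incident triangle, e.g. at the periodic box seam) are flagged
#' `boundary`; defect clusters containing such tiles are later removed.
#'
#' Meshes produced by [reconstruct_surface()] live in an unwrapped periodic
#' cover: vertex coordinates span `[origin, origin + box]` (the `origin`
#' field), so triangle geometry is continuous across the box faces; wrap
#' coordinates modulo the box when comparing against in-box positions.
#'
#' @param vertices V x 3 matrix (Angstrom).
#' @param triangles T x 3 integer matrix (1-based vertex indices).
#' @param box optional length-3 box carried along for bookkeeping.
#' @return a `leaflet_mesh` object.
#' @export
leaflet_mesh <- function(vertices, triangles, box = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  areas <- 0.5 * sqrt(rowSums(fn^2))
  keep <- areas > 1e-10
  if (!all(keep)) {
    triangles <- triangles[keep, , drop = FALSE]
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    c3 <- c3[keep, , drop = FALSE]
    fn <- fn[keep, , drop = FALSE]
    areas <- areas[keep]
  }
  if (!nrow(triangles)) stop("mesh has no triangles with positive area")
  mid <- (a + b + c3) / 3
  # vertex normals: area-weighted face normals (fn is already 2*area-weighted)
  vn <- matrix(0, nrow(vertices), 3)
  acc <- rowsum(rbind(fn, fn, fn), as.vector(triangles))
  vn[as.integer(rownames(acc)), ] <- acc
  nrm <- sqrt(rowSums(vn^2))
  nz <- nrm > 1e-12
  vn[nz, ] <- vn[nz, ] / nrm[nz]

  # boundary: triangles touching an edge with a single incident triangle
  boundary <- cpp_mesh_boundary(triangles, nrow(vertices))$triangles

  structure(list(vertices = vertices, triangles = triangles, areas = areas,
                 midpoints = mid, face_normals = fn / (2 * areas),
                 vertex_normals = vn, boundary = boundary, box = box),
            class = "leaflet_mesh")
}

#' @export
print.leaflet_mesh <- function(x, ...) {
  cat(sprintf("<leaflet_mesh> %d vertices, %d triangles, area %.1f A^2 (%d boundary tiles)\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas),
              sum(x$boundary)))
  invisible(x)
}

#' Total mesh area
#' @param mesh a `leaflet_mesh`.
#' @return total area in square Angstrom.
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

mesh_edge_lengths <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  ek <- edge_keys(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
  first <- !duplicated(ek)
  i <- c(f[, 1], f[, 2], f[, 3])[first]
  j <- c(f[, 2], f[, 3], f[, 1])[first]
  sqrt(rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2))
}

# boundary vertex flags (vertices on an open edge)
mesh_boundary_vertices <- function(vertices, triangles) {
  cpp_mesh_boundary(triangles, nrow(vertices))$vertices
}

# connected components over triangles sharing a vertex (labels per triangle)
mesh_triangle_components <- function(vertices, triangles) {
  nv <- nrow(vertices)
  g <- igraph::graph_from_edgelist(
    rbind(triangles[, 1:2, drop = FALSE], triangles[, 2:3, drop = FALSE]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  memb[triangles[, 1]]
}

#' Remesh to a near-uniform dense tiling
#'
#' The two consecutive steps of the mesh refinement: *division* (long-edge
#' pattern subdivision until no edge exceeds 4/3 of the target length)
#' followed by *smoothing* (iterative centroidal relaxation: every interior
#' vertex moves toward the area-weighted centroid of its incident triangles,
#' with the displacement projected onto the local tangent plane so that the
#' surface shape and total area are preserved). Boundary vertices stay fixed.
#'
#' @param mesh a `leaflet_mesh`.
#' @param target_edge target mean edge length in Angstrom.
#' @param n_iter smoothing iterations.
#' @param lambda relaxation step size in (0, 1].
#' @return a `leaflet_mesh` with near-uniform triangles.
#' @export
remesh_cvt <- function(mesh, target_edge = 1.0, n_iter = 8, lambda = 0.6) {
  stopifnot(target_edge > 0)
  diam <- sqrt(sum((apply(mesh$vertices, 2, max) -
                      apply(mesh$vertices, 2, min))^2))
  if (target_edge >= diam) {
    stop("target_edge (", target_edge, ") exceeds the mesh diameter (",
         round(diam, 2), ")")
  }
  # division: long-edge splits, then shortest-edge collapses down to the
  # vertex count of a uniform equilateral tiling at the target edge length
  target_nv <- max(4L, as.integer(round(mesh_area(mesh) /
                                          (sqrt(3) / 2 * target_edge^2))))
  div <- cpp_subdivide(mesh$vertices, mesh$triangles, 4 / 3 * target_edge,
                       12L)
  bnd <- mesh_boundary_vertices(div$vertices, div$triangles)
  col <- cpp_collapse(div$vertices, div$triangles, bnd, target_edge, 10L,
                      target_nv)
  bnd <- mesh_boundary_vertices(col$vertices, col$triangles)
  v <- cpp_smooth(col$vertices, col$triangles, bnd, as.integer(n_iter),
                  lambda)
  out <- leaflet_mesh(v, col$triangles, mesh$box)
  out$origin <- mesh$origin
  rel <- abs(mesh_area(out) - mesh_area(mesh)) / mesh_area(mesh)
  if (rel > 0.02) {
    warning(sprintf("remeshing changed total area by %.1f%%", 100 * rel))
  }
  out
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh a `leaflet_mesh`.
#' @param path output path.
#' @param face_data optional named list of per-triangle numeric vectors
#'   written as extra face properties (e.g. `d_type`, curvature domain).
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, face_data = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (!is.null(face_data)) {
    for (nm in names(face_data)) {
      stopifnot(length(face_data[[nm]]) == nf)
      hdr <- c(hdr, sprintf("property float %s", nm))
    }
  }
  hdr <- c(hdr, "end_header")
  vtx <- sprintf("%.4f %.4f %.4f", mesh$vertices[, 1], mesh$vertices[, 2],
                 mesh$vertices[, 3])
  f0 <- mesh$triangles - 1L
  fc <- sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
  if (!is.null(face_data)) {
    for (nm in names(face_data)) {
      fc <- paste(fc, sprintf("%.6g", as.numeric(face_data[[nm]])))
    }
  }
  writeLines(c(hdr, vtx, fc), path)
  invisible(path)
}

#' Export a mesh as ASCII OFF
#'
#' @param mesh a `leaflet_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  f0 <- mesh$triangles - 1L
  writeLines(c("OFF", sprintf("%d %d 0", nv, nf),
               sprintf("%.4f %.4f %.4f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])), path)
  invisible(path)
}
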