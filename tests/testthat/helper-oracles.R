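# Independent oracles and small geometry builders used across the tests.

# Regular triangulated plane mesh at z = z0 over [0, nx*s] x [0, ny*s].
# With normal_dir = -1 the winding gives face normals (0, 0, -1), i.e.
# tails below the plane (the upper-leaflet convention).
make_flat_mesh <- function(nx, ny, s = 1, z0 = 0, normal_dir = -1,
                           box = NULL) {
  g <- expand.grid(i = 0:nx, j = 0:ny)
  v <- cbind(g$i * s, g$j * s, z0)
  id <- function(i, j) j * (nx + 1) + i + 1
  tri <- NULL
  for (j in 0:(ny - 1)) {
    i <- 0:(nx - 1)
    tri <- rbind(tri,
                 cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  if (normal_dir < 0) tri <- tri[, c(1, 3, 2)]
  leaflet_mesh(v, tri, box)
}

# Exhaustive projection/overlap oracle mirroring the assignment rules:
# every tile against every bead, winner = largest height, ties by smaller
# radius then smaller residue id. Returns winning bead index per tile (0 =
# untouched).
oracle_assign <- function(mid, foot, radius, height, resid, tol = 1e-6) {
  win <- integer(nrow(mid))
  for (t in seq_len(nrow(mid))) {
    best <- 0L
    for (b in seq_len(nrow(foot))) {
      if (sum((mid[t, ] - foot[b, ])^2) > radius[b]^2) next
      if (best == 0L) { best <- b; next }
      ds <- height[b] - height[best]
      if (ds > tol) best <- b
      else if (ds >= -tol) {
        if (radius[b] < radius[best] - 1e-9) best <- b
        else if (abs(radius[b] - radius[best]) <= 1e-9 &&
                 resid[b] < resid[best]) best <- b
      }
    }
    win[t] <- best
  }
  win
}

# Brute-force BFS connected components of member tiles sharing a vertex.
oracle_cluster <- function(members, triangles) {
  if (!length(members)) return(integer())
  tv <- triangles[members, , drop = FALSE]
  n <- length(members)
  adj <- vector("list", n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && length(intersect(tv[a, ], tv[b, ]))) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# canonical form of a clustering: member sets ordered by smallest element
canonical_partition <- function(membership) {
  sets <- lapply(split(seq_along(membership), membership), sort)
  unname(sets[order(vapply(sets, `[`, 0, 1))])
}

# tiny one-lipid snapshot on a flat upper leaflet (tails below the anchors)
# plus a matching force field; used for projection unit tests
make_micro_snapshot <- function(lipids, box = c(40, 40, 60), extra = NULL) {
  # lipids: data.frame x, y, with head/ref/tails stacked at z offsets
  coords <- NULL; bead <- NULL; resn <- NULL; resid <- NULL
  for (i in seq_len(nrow(lipids))) {
    z0 <- lipids$z0[i]
    coords <- rbind(coords,
                    c(lipids$x[i], lipids$y[i], z0 + 3),
                    c(lipids$x[i], lipids$y[i], z0),
                    c(lipids$x[i], lipids$y[i], z0 - 3),
                    c(lipids$x[i], lipids$y[i], z0 - 6))
    bead <- c(bead, "HD", "GL", "T1", "T2")
    resn <- c(resn, rep("LIPA", 4))
    resid <- c(resid, rep(i - 1L, 4))
  }
  if (!is.null(extra)) {
    coords <- rbind(coords, as.matrix(extra[, c("x", "y", "z")]))
    bead <- c(bead, extra$bead)
    resn <- c(resn, extra$resn)
    resid <- c(resid, extra$resid)
  }
  cg_snapshot(coords, bead, resn, resid, box)
}

micro_ff <- function() fixture_forcefield("LIPA")

# manual leaflet assignment (bypasses clustering) for micro fixtures
manual_assignment <- function(ids, leaflet = 0L) {
  structure(list(residue_id = as.integer(ids),
                 leaflet = rep(as.integer(leaflet), length(ids)),
                 counts = length(ids)),
            class = "leaflet_assignment")
}
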