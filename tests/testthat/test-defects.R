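test_that("depth and chemistry classify into the three tile values", {
  expect_equal(classify_bead("polar", -2), 1)
  expect_equal(classify_bead("polar", 10), 1)
  expect_equal(classify_bead("aliphatic", 2.0), 0.001)
  expect_equal(classify_bead("aliphatic", 6.0), 0)
  expect_equal(classify_bead("aliphatic", 4.5), 0)    # at the threshold
  expect_equal(classify_bead(c("polar", "aliphatic", "aliphatic"),
                             c(0, 1, 9)), c(1, 0.001, 0))
  expect_error(classify_bead("greasy", 1), "unknown chemical class")
  expect_error(classify_bead("polar", NaN), "finite")
})

test_that("a single head bead claims exactly its van der Waals disc", {
  # one lipid over a fine flat mesh; mesh at the anchor plane
  snap <- make_micro_snapshot(data.frame(x = 20, y = 20, z0 = 40))
  mesh <- make_flat_mesh(40, 40, s = 1, z0 = 40, box = snap$box)
  mesh$origin <- c(0, 0, 0)
  asn <- manual_assignment(0L)
  ts <- project_beads(snap, asn, 0, mesh, micro_ff())
  won <- which(!is.na(ts$d_type))
  # all claimed tiles carry the polar value from the outermost (head) bead
  expect_true(all(ts$d_type[won] == 1))
  expect_true(all(ts$winner_bead[won] == "HD"))
  # brute-force: tiles within the head radius of its lateral position
  r <- 2.64
  d2 <- (mesh$midpoints[, 1] - 20)^2 + (mesh$midpoints[, 2] - 20)^2
  expect_setequal(won, which(d2 <= r^2))
})

test_that("exposed aliphatic beads make shallow or deep defects by depth", {
  # lipid 0 intact (polar coverage); lipid 1: head gone and polar backbone
  # displaced sideways, tail raised to 2 A below the reference level
  # (shallow); lipid 2: only its second tail bead remains at the site,
  # 6 A below the reference (deep)
  snap <- make_micro_snapshot(data.frame(x = c(10, 25, 40, 10, 25, 40),
                                         y = c(10, 10, 10, 25, 25, 40),
                                         z0 = 40),
                              box = c(50, 50, 80))
  gl1 <- which(snap$residue_id == 1L & snap$bead_name == "GL")
  t1 <- which(snap$residue_id == 1L & snap$bead_name == "T1")
  gl2 <- which(snap$residue_id == 2L & snap$bead_name == "GL")
  snap$coords[gl1, 2] <- 16          # polar backbone moved off the site
  snap$coords[t1, 3] <- 40 - 2       # shallow exposure depth
  snap$coords[gl2, 2] <- 16
  drop_rows <- which(snap$residue_id %in% c(1L, 2L) &
                       snap$bead_name == "HD" |
                     snap$residue_id == 2L & snap$bead_name == "T1")
  snap2 <- defectmesh:::snapshot_subset(
    snap, setdiff(seq_along(snap$bead_name), drop_rows))
  mesh <- make_flat_mesh(50, 50, s = 1, z0 = 40, box = snap2$box)
  mesh$origin <- c(0, 0, 0)
  asn <- manual_assignment(0:5)
  ts <- project_beads(snap2, asn, 0, mesh, micro_ff())

  near <- function(x, y, r = 2) {
    which((mesh$midpoints[, 1] - x)^2 + (mesh$midpoints[, 2] - y)^2 <= r^2)
  }
  expect_true(all(ts$d_type[near(25, 10)] == 0.001))  # shallow exposure
  expect_true(all(ts$d_type[near(40, 10)] == 0))      # deep exposure
  expect_true(all(ts$d_type[near(10, 10)] == 1))      # covered by a head
  expect_equal(unique(ts$winner_bead[near(40, 10)]), "T2")
  # bead-free region is unassigned, not a defect
  expect_true(all(is.na(ts$d_type[near(45, 45, 3)])))
})

test_that("vertex-shared clustering matches additivity and the BFS oracle", {
  mesh <- make_flat_mesh(10, 10, s = 1, box = c(10, 10, 50))
  nt <- nrow(mesh$triangles)
  # two adjacent deep tiles sharing a vertex
  ts <- list(d_type = rep(NA_real_, nt))
  ts$d_type[c(1, 2)] <- 0
  cl <- cluster_defects(ts, mesh, "overall")
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$area, sum(mesh$areas[1:2]))

  # far-apart tiles stay separate
  ts$d_type <- rep(NA_real_, nt)
  ts$d_type[c(1, nt)] <- 0
  expect_equal(nrow(cluster_defects(ts, mesh, "overall")$clusters), 2)

  # random tile states against the brute-force connectivity oracle
  for (seed in 1:20) {
    set.seed(seed)
    d <- rep(NA_real_, nt)
    hot <- sample(nt, 30)
    d[hot] <- sample(c(0, 0.001), 30, replace = TRUE)
    cl <- cluster_defects(list(d_type = d), mesh, "overall")
    got <- integer(0)
    memb <- integer(nt)
    for (k in seq_along(cl$members)) memb[cl$members[[k]]] <- k
    oracle <- oracle_cluster(sort(hot), mesh$triangles)
    expect_identical(canonical_partition(memb[sort(hot)]),
                     canonical_partition(oracle))
    # unassigned tiles never act as connectors
    expect_true(all(unlist(cl$members) %in% hot))
  }
})

test_that("deep and shallow clusters partition the overall defect tiles", {
  mesh <- make_flat_mesh(12, 12, s = 1, box = c(12, 12, 50))
  nt <- nrow(mesh$triangles)
  set.seed(9)
  d <- rep(NA_real_, nt)
  d[sample(nt, 60)] <- sample(c(0, 0.001, 1), 60, replace = TRUE)
  ts <- list(d_type = d)
  ov <- cluster_defects(ts, mesh, "overall")
  dp <- cluster_defects(ts, mesh, "deep")
  sh <- cluster_defects(ts, mesh, "shallow")
  expect_setequal(unlist(ov$members),
                  c(unlist(dp$members), unlist(sh$members)))
  expect_equal(sum(ov$clusters$area),
               sum(dp$clusters$area) + sum(sh$clusters$area))
})

test_that("boundary-touching clusters are removed, interior ones kept", {
  mesh <- make_flat_mesh(10, 10, s = 1, box = c(10, 10, 50))
  nt <- nrow(mesh$triangles)
  ts <- list(d_type = rep(NA_real_, nt))
  bnd_tile <- which(mesh$boundary)[1]
  # interior tile far from the chosen boundary tile (no shared vertex)
  ctr_d2 <- rowSums(sweep(mesh$midpoints[, 1:2], 2, c(5, 5))^2)
  interior_tile <- which(!mesh$boundary)[which.min(ctr_d2[!mesh$boundary])]
  ts$d_type[c(bnd_tile, interior_tile)] <- 0
  cl <- cluster_defects(ts, mesh, "overall")
  flt <- filter_clusters(cl)
  expect_equal(attr(flt, "n_removed"), 1)
  expect_equal(nrow(flt$clusters), 1)
  expect_equal(flt$clusters$area, mesh$areas[interior_tile])

  # a mesh with no boundary flags passes through unchanged
  mesh$boundary[] <- FALSE
  cl2 <- cluster_defects(ts, mesh, "overall")
  flt2 <- filter_clusters(cl2)
  expect_equal(nrow(flt2$clusters), nrow(cl2$clusters))
})

test_that("assignment arbitration matches the exhaustive oracle", {
  mesh <- make_flat_mesh(12, 12, s = 1, box = c(12, 12, 50))
  for (seed in 1:20) {
    set.seed(seed)
    nb <- 20
    foot <- cbind(runif(nb, 0, 12), runif(nb, 0, 12), 0)
    radius <- runif(nb, 0.8, 3)
    height <- round(runif(nb, 0, 5), 2)  # rounded values force ties
    resid <- sample(100, nb)
    got <- defectmesh:::cpp_assign_tiles(mesh$midpoints, foot, radius,
                                         height, as.integer(resid))
    want <- oracle_assign(mesh$midpoints, foot, radius, height, resid)
    expect_identical(as.integer(got), as.integer(want))
  }
})
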