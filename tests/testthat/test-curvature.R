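# reconstruct + remesh one leaflet of a fixture
fixture_mesh <- function(spec, leaf = 0, target_edge = 1.5) {
  fx <- generate_fixture(spec)
  snap <- fx$frames[[1]]
  asn <- assign_leaflets(snap, fx$ff,
                         n_leaflets = if (spec$leaflets == "bilayer") 2
                                      else NULL)
  cl <- make_oriented_cloud(snap, asn, leaf, fx$ff)
  remesh_cvt(reconstruct_surface(cl), target_edge)
}

test_that("a flat leaflet is classified as one flat domain", {
  mesh <- fixture_mesh(fixture_spec(n_lipids = 800, seed = 2))
  map <- bin_and_classify(mesh, axis = "y")
  expect_true(all(map$bin_label == "J0"))
  expect_true(all(map$label == "J0"))
  # every non-boundary triangle is binned
  expect_equal(length(map$bin), nrow(mesh$triangles))
})

test_that("buckle bins match the analytic curvature-sign map", {
  spec <- fixture_spec(geometry = "buckle", n_lipids = 3000,
                       amplitude = 30, seed = 3)
  mesh <- fixture_mesh(spec)
  map <- bin_and_classify(mesh, axis = "y")
  expect_equal(map$profile_axis, "x")
  expect_true(map$circular)
  expect_true(all(c("J+", "J-", "J0") %in% map$bin_label))

  # analytic map: turning of the outward-normal angle over one bin width,
  # same threshold as the classifier; upper leaflet of z = A sin(kx)
  L <- mesh$box[1]
  A <- 30
  k <- 2 * pi / L
  w <- L / map$n_bins
  ana <- vapply(map$bin_centre[, 1], function(xc) {
    a1 <- atan(A * k * cos(k * (xc - w / 2)))
    a2 <- atan(A * k * cos(k * (xc + w / 2)))
    ang <- (a2 - a1) * 180 / pi
    if (abs(ang) <= map$angle_threshold) "J0"
    else if (ang < 0) "J+" else "J-"   # crest: slope decreasing, convex up
  }, "")
  expect_gte(mean(map$bin_label == ana), 0.9)
})

test_that("the outer leaflet of a cylinder is uniformly J+", {
  spec <- fixture_spec(geometry = "cylinder", leaflets = "monolayer",
                       radius = 80, n_lipids = 2000, seed = 4)
  mesh <- fixture_mesh(spec)
  map <- bin_and_classify(mesh, axis = "y")
  expect_equal(map$profile_axis, "angular")
  expect_gte(mean(map$bin_label == "J+"), 0.95)
})

test_that("clusters are split by majority area with curved-tie preference", {
  mesh <- make_flat_mesh(10, 10, s = 1, box = c(10, 10, 50))
  nt <- nrow(mesh$triangles)
  # synthetic domain map: triangles left of x = 5 are J+, right J0
  lab <- ifelse(mesh$midpoints[, 1] < 5, "J+", "J0")
  map <- structure(list(bin = rep(1L, nt), label = lab), class =
                     "curvature_domains")
  d <- rep(NA_real_, nt)
  left <- which(lab == "J+")[1:6]
  right <- which(lab == "J0")[1:2]
  d[c(left, right)] <- 0
  cl <- cluster_defects(list(d_type = d), mesh, "overall")
  doms <- vapply(cl$members, defectmesh:::split_cluster_domain, "",
                 mesh = mesh, map = map)
  # majority rule per cluster
  for (kk in seq_along(cl$members)) {
    m <- cl$members[[kk]]
    aplus <- sum(mesh$areas[m][lab[m] == "J+"])
    a0 <- sum(mesh$areas[m][lab[m] == "J0"])
    want <- if (aplus > a0) "J+" else if (a0 > aplus) "J0" else "J+"
    expect_equal(doms[kk], want)
  }

  # exact 50/50 tie goes to the curved domain
  two <- which(lab == "J+")[10]
  pair <- which(lab == "J0")[10]
  expect_equal(defectmesh:::split_cluster_domain(c(two, pair), mesh, map),
               "J+")

  # per-domain lists cover every cluster exactly once
  split <- split_areas_by_domain(cl, mesh, map)
  expect_equal(sum(lengths(split)), nrow(cl$clusters))
  expect_equal(sum(unlist(split)), sum(cl$clusters$area))
})
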