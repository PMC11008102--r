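test_that("fixtures are bit-reproducible from their seed", {
  spec <- fixture_spec(n_lipids = 200, planted_pi = 20,
                       patches_per_frame = 3, seed = 42)
  f1 <- generate_fixture(spec, n_frames = 2)
  f2 <- generate_fixture(spec, n_frames = 2)
  expect_identical(f1$frames[[1]]$coords, f2$frames[[1]]$coords)
  expect_identical(f1$frames[[2]]$coords, f2$frames[[2]]$coords)
  expect_identical(f1$truth$patches, f2$truth$patches)

  # a frozen frame replays identically
  f3 <- generate_fixture(spec, n_frames = 3, vary_frames = FALSE)
  expect_identical(f3$frames[[1]]$coords, f3$frames[[3]]$coords)
  # varying frames differ
  expect_false(identical(f1$frames[[1]]$coords, f1$frames[[2]]$coords))
})

test_that("the exponential area sampler has the requested mean", {
  a <- sample_exponential_areas(20, 1e5, seed = 7)
  expect_lt(abs(mean(a) - 20) / 20, 0.01)
  expect_true(all(a > 0))
  expect_length(sample_exponential_areas(20, 1), 1)
  expect_false(identical(sample_exponential_areas(20, 10, seed = 1),
                         sample_exponential_areas(20, 10, seed = 2)))
})

test_that("planted areas pass a one-sample exponentiality check", {
  spec <- fixture_spec(n_lipids = 400, planted_pi = 20,
                       patches_per_frame = 8, seed = 13)
  fx <- generate_fixture(spec, n_frames = 80)
  a <- fx$truth$patches$area_drawn
  expect_gte(length(a), 1000)
  ks <- stats::ks.test(a, "pexp", rate = 1 / mean(a))
  expect_gte(ks$p.value, 0.01)
})

test_that("fixture generation is fast enough for routine testing", {
  spec <- fixture_spec(n_lipids = 3000, planted_pi = 20, seed = 1)
  el <- system.time(generate_fixture(spec, n_frames = 1))[["elapsed"]]
  expect_lt(el, 5)
})

test_that("recovered cluster areas track the planted ground truth", {
  spec <- fixture_spec(n_lipids = 800, planted_pi = 20,
                       patches_per_frame = 6, seed = 7)
  fx <- generate_fixture(spec, n_frames = 4)
  res <- NULL
  for (fi in seq_along(fx$frames)) {
    snap <- fx$frames[[fi]]
    asn <- assign_leaflets(snap, fx$ff, n_leaflets = 2)
    for (leaf in 0:1) {
      cl <- make_oriented_cloud(snap, asn, leaf, fx$ff)
      mesh <- remesh_cvt(reconstruct_surface(cl), 1.0)
      ts <- project_beads(snap, asn, leaf, mesh, fx$ff)
      cls <- filter_clusters(cluster_defects(ts, mesh, "overall"))
      tr <- subset(fx$truth$patches,
                   frame == snap$frame_index & leaflet == leaf & interior)
      if (!nrow(tr) || !nrow(cls$clusters)) next
      cent <- t(vapply(cls$members, function(m) {
        colMeans(mesh$midpoints[m, , drop = FALSE])
      }, numeric(3)))
      cent <- sweep(cent, 2, snap$box, function(x, L) x - L * floor(x / L))
      for (p in seq_len(nrow(tr))) {
        dd <- defectmesh:::min_image(
          cbind(cent[, 1] - tr$cx[p], cent[, 2] - tr$cy[p],
                cent[, 3] - tr$cz[p]), snap$box)
        d2 <- rowSums(dd^2)
        res <- rbind(res, data.frame(target = tr$area_target[p],
                                     realized =
                                       cls$clusters$area[which.min(d2)]))
      }
    }
  }
  expect_gte(nrow(res), 30)
  slope <- coef(lm(realized ~ 0 + target, res))[[1]]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("oversized patch budgets are rejected", {
  spec <- fixture_spec(n_lipids = 60, planted_pi = 100,
                       patches_per_frame = 10, seed = 1)
  expect_error(generate_fixture(spec), "30%")
})

test_that("the square-grid reference recovers the planted patch count", {
  # no per-bead noise: the only defects are the planted patches
  spec <- fixture_spec(n_lipids = 1000, planted_pi = 25,
                       patches_per_frame = 5, jitter = 0.3,
                       bead_jitter = 0, seed = 21)
  fx <- generate_fixture(spec)
  snap <- fx$frames[[1]]
  for (lf in c("upper", "lower")) {
    leaf <- if (lf == "upper") 0 else 1
    tr <- subset(fx$truth$patches, leaflet == leaf)
    cm <- reference_grid_defects(snap, fx$ff, cell = 1, leaflet = lf)
    # every measurable cluster is a planted patch (no spurious defects),
    # and all but at most one cut-censored patch is recovered at its size
    matched <- vapply(tr$area_target, function(a) {
      any(abs(cm$area - a) / a < 0.25)
    }, TRUE)
    expect_gte(sum(matched), nrow(tr) - 1)
    big <- cm$area[cm$area >= 15]
    expect_true(all(vapply(big, function(a) {
      any(abs(tr$area_target - a) / a < 0.3)
    }, TRUE)))
  }
  # non-planar input is rejected
  sph <- generate_fixture(fixture_spec(geometry = "sphere", radius = 80,
                                       seed = 2))
  expect_error(reference_grid_defects(sph$frames[[1]], sph$ff),
               "quasi-planar")
})
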