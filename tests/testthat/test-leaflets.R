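test_that("flat bilayer splits into the construction leaflets", {
  spec <- fixture_spec(n_lipids = 400, seed = 2, jitter = 0.3)
  fx <- generate_fixture(spec)
  snap <- fx$frames[[1]]
  asn <- assign_leaflets(snap, fx$ff, n_leaflets = 2)
  expect_length(asn$counts, 2)
  truth <- fx$truth$lipids
  got <- asn$leaflet[match(truth$residue_id, asn$residue_id)]
  agree <- max(mean(got == truth$leaflet), mean(got != truth$leaflet))
  expect_equal(agree, 1)
})

test_that("vesicle leaflets separate with the outer one more populous", {
  spec <- fixture_spec(geometry = "sphere", radius = 100, seed = 3)
  fx <- generate_fixture(spec)
  asn <- assign_leaflets(fx$frames[[1]], fx$ff, n_leaflets = 2)
  expect_length(asn$counts, 2)
  # leaflet 0 is the larger (outer) pool
  expect_gt(asn$counts[1], asn$counts[2])
  truth <- fx$truth$lipids
  got <- asn$leaflet[match(truth$residue_id, asn$residue_id)]
  expect_equal(mean(got == truth$leaflet), 1)
})

test_that("a monolayer yields a single leaflet and empty input errors", {
  spec <- fixture_spec(n_lipids = 200, leaflets = "monolayer", seed = 4)
  fx <- generate_fixture(spec)
  asn <- assign_leaflets(fx$frames[[1]], fx$ff)
  expect_length(asn$counts, 1)
  expect_equal(asn$counts[1], length(unique(fx$frames[[1]]$residue_id)))
})

test_that("leaflet assignment is deterministic and rigid-motion invariant", {
  spec <- fixture_spec(n_lipids = 300, seed = 8)
  fx <- generate_fixture(spec)
  snap <- fx$frames[[1]]
  a1 <- assign_leaflets(snap, fx$ff, n_leaflets = 2)
  a2 <- assign_leaflets(snap, fx$ff, n_leaflets = 2)
  expect_identical(a1, a2)

  # translation (wrapped into the box)
  shift <- c(13.7, -5.1, 8.9)
  moved <- snap
  moved$coords <- sweep(snap$coords, 2, shift, "+")
  moved$coords <- sweep(moved$coords, 2, snap$box,
                        function(x, L) x - L * floor(x / L))
  a3 <- assign_leaflets(moved, fx$ff, n_leaflets = 2)
  expect_equal(a3$leaflet, a1$leaflet)

  # bead storage order: reverse whole residues
  ids <- rev(unique(snap$residue_id))
  ord <- order(match(snap$residue_id, ids))
  perm <- cg_snapshot(snap$coords[ord, ], snap$bead_name[ord],
                      snap$residue_name[ord], snap$residue_id[ord],
                      snap$box)
  a4 <- assign_leaflets(perm, fx$ff, n_leaflets = 2)
  m <- match(a1$residue_id, a4$residue_id)
  agree <- max(mean(a4$leaflet[m] == a1$leaflet),
               mean(a4$leaflet[m] != a1$leaflet))
  expect_equal(agree, 1)

  # pools partition the lipid set
  expect_setequal(a1$residue_id, unique(snap$residue_id))
  expect_equal(sum(a1$counts), length(unique(snap$residue_id)))
})

test_that("periodic ghosting augments only near faces", {
  box <- c(100, 100, 100)
  pts <- rbind(c(5, 50, 50), c(50, 50, 50), c(98, 2, 50))
  aug <- handle_periodicity(pts, box, margin = 10)
  expect_true(all(aug$source[!aug$is_ghost] == 1:3))
  # point 2 is interior: never ghosted
  expect_false(2 %in% aug$source[aug$is_ghost])
  # corner point 3 is ghosted across x, y and the xy corner
  expect_equal(sum(aug$source[aug$is_ghost] == 3), 3)

  expect_identical(nrow(handle_periodicity(pts, box, margin = 0)$points),
                   3L)
  far <- matrix(rep(50, 3), 1)
  expect_equal(sum(handle_periodicity(far, box, 10)$is_ghost), 0)
})
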