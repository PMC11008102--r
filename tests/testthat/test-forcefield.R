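test_that("descriptor parsing recovers the full bead table", {
  path <- system.file("extdata", "martini_lipids.yaml",
                      package = "defectmesh")
  ff <- load_forcefield(path)
  expect_s3_class(ff, "forcefield_spec")
  dppc <- ff$residues$DPPC
  expect_equal(dppc$anchor_bead, "GL2")
  expect_equal(nrow(dppc$beads), 12)
  expect_true(all(dppc$beads$radius > 0))
  expect_setequal(unique(dppc$beads$class), c("polar", "aliphatic"))
  expect_length(dppc$tail_beads, 8)
})

test_that("descriptor validation names the offending residue", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("POPC:", "  anchor: GL2", "  beads:",
               "    GL2: {radius: 2.6, class: polar}", "  tails: [GL2]"),
             tmp)
  expect_error(load_forcefield(tmp), "POPC.*reference")

  writeLines(c("DPPC:", "  anchor: GL2", "  reference: GL2", "  beads:",
               "    GL2: {radius: -1, class: polar}", "  tails: [GL2]"),
             tmp)
  expect_error(load_forcefield(tmp), "positive")

  writeLines(c("DPPC:", "  anchor: XX", "  reference: XX", "  beads:",
               "    GL2: {radius: 2.6, class: polar}", "  tails: [GL2]"),
             tmp)
  expect_error(load_forcefield(tmp), "anchor")
})

test_that("bead radii are namespaced by (residue, bead)", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "AAA:", "  anchor: C1", "  reference: C1", "  beads:",
    "    C1: {radius: 2.0, class: polar}",
    "    T1: {radius: 2.0, class: aliphatic}", "  tails: [T1]",
    "BBB:", "  anchor: C1", "  reference: C1", "  beads:",
    "    C1: {radius: 3.0, class: polar}",
    "    T1: {radius: 3.0, class: aliphatic}", "  tails: [T1]"), tmp)
  ff <- load_forcefield(tmp)
  tab <- defectmesh:::ff_bead_table(ff, c("AAA", "BBB", "AAA"),
                                    c("C1", "C1", "T1"))
  expect_equal(tab$radius, c(2, 3, 2))
})

test_that("descriptor round-trips through write_forcefield", {
  ff <- fixture_forcefield(c("LIPA", "LIPB"))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_forcefield(ff, tmp)
  ff2 <- load_forcefield(tmp)
  expect_equal(names(ff2$residues), names(ff$residues))
  expect_equal(ff2$residues$LIPA$beads$radius, ff$residues$LIPA$beads$radius)
  expect_equal(ff2$residues$PTCH$tail_beads, "PA")
})
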