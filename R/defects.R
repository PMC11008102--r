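#' Classify a bead into a defect type value
#'
#' Tile values follow the established grid convention: `1` marks no defect
#' (polar coverage), `0` a deep defect and `0.001` a shallow defect.
#' Aliphatic beads deeper than `deep_threshold` below the reference
#' glycerol-level bead (measured along the outward normal, positive toward
#' the tails) are deep; shallower aliphatic exposure is a shallow defect;
#' polar beads always map to 1.
#'
#' @param chem_class character vector, `"polar"` or `"aliphatic"`.
#' @param depth numeric vector, signed depth in Angstrom relative to the
#'   reference bead (positive = deeper into the membrane).
#' @param deep_threshold depth separating shallow from deep defects
#'   (default 4.5 Angstrom).
#' @return numeric vector of d_type values in {1, 0.001, 0}.
#' @export
classify_bead <- function(chem_class, depth, deep_threshold = 4.5) {
  if (any(!is.finite(depth))) stop("bead depth must be finite")
  bad <- setdiff(unique(chem_class), c("polar", "aliphatic"))
  if (length(bad)) stop("unknown chemical class: ", bad[1])
  ifelse(chem_class == "polar", 1,
         ifelse(depth >= deep_threshold, 0, 0.001))
}

# map coordinates into the unwrapped cover [off, off + L) used by the mesh
to_cover <- function(x, off, box) {
  sweep(sweep(sweep(x, 2, off), 2, box, function(v, L) v - L * floor(v / L)),
        2, off, "+")
}

# ghost-augment points (given in cover coordinates) across the cover seam
ghost_cover <- function(points, off, box, margin) {
  aug <- handle_periodicity(sweep(points, 2, off), box, margin)
  aug$points <- sweep(aug$points, 2, off, "+")
  aug
}

#' Project lipid beads onto a leaflet mesh and assign tile defect values
#'
#' Every bead of every lipid in the leaflet is projected along the lipid's
#' local (averaged) surface normal onto the mesh; each tile whose midpoint
#' lies within the bead's van der Waals radius of the projected footprint
#' centre is touched. Among all beads touching a tile, the most
#' solvent-proximal one (largest height above the surface along the outward
#' normal) wins and sets the tile's d_type via [classify_bead()]; ties within
#' 1e-6 Angstrom go to the smaller radius, then the smaller residue id.
#' Tiles touched by no bead stay unassigned (`NA`) and are disregarded
#' downstream, so membrane inclusions never masquerade as large defects.
#'
#' @param snapshot a [cg_snapshot()].
#' @param assignment a `leaflet_assignment`.
#' @param leaflet leaflet label.
#' @param mesh the (remeshed) `leaflet_mesh` of that leaflet.
#' @param ff force-field specification.
#' @param normal_radius radius (Angstrom) for averaging mesh vertex normals
#'   into the per-lipid projection normal.
#' @param deep_threshold passed to [classify_bead()].
#' @return a `tile_state`: list with per-tile `d_type` (NA = unassigned),
#'   `winner_residue`, `winner_bead`, `depth` (of the winning bead), plus the
#'   number of beads projected.
#' @export
project_beads <- function(snapshot, assignment, leaflet, mesh, ff,
                          normal_radius = 5, deep_threshold = 4.5) {
  ids <- leaflet_members(assignment, leaflet)
  if (!length(ids)) stop("leaflet ", leaflet, " is empty")
  box <- snapshot$box
  # cover origin: mesh coordinates live in [off, off + L] (see
  # reconstruct_surface); meshes built directly in the box use off = 0
  off <- if (is.null(mesh$origin)) c(0, 0, 0) else mesh$origin

  rows <- which(snapshot$residue_id %in% ids)
  sub <- snapshot_subset(snapshot, rows)
  bt <- ff_bead_table(ff, sub$residue_name, sub$bead_name)

  anchors <- bead_positions(snapshot, ids, ff, "anchor")
  refs <- bead_positions(snapshot, ids, ff, "reference")

  # per-lipid local projection normal: average vertex normals within
  # normal_radius of the anchor (fallback: nearest vertex normal)
  vaug <- ghost_cover(mesh$vertices, off, box, normal_radius + 1)
  vn_aug <- mesh$vertex_normals[vaug$source, , drop = FALSE]
  anch_cov <- to_cover(anchors, off, box)
  n_tail <- cpp_radius_mean(anch_cov, vaug$points, vn_aug, normal_radius)
  zero <- sqrt(rowSums(n_tail^2)) < 1e-9
  if (any(zero)) {
    nearest <- cpp_nearest(anch_cov[zero, , drop = FALSE], vaug$points,
                           max(normal_radius, 2))
    n_tail[zero, ] <- vn_aug[nearest, , drop = FALSE]
  }
  n_tail <- n_tail / sqrt(rowSums(n_tail^2))

  lip <- match(sub$residue_id, ids)
  nb <- n_tail[lip, , drop = FALSE]           # per-bead lipid tail normal
  bead_cov <- to_cover(sub$coords, off, box)

  # footprint centre: drop the normal component relative to the nearest
  # surface point; height above the surface along the outward normal scores
  # the winning-bead arbitration (outermost bead wins)
  cs <- max(2, stats::median(sqrt(mesh$areas)) * 4)
  maug <- ghost_cover(mesh$midpoints, off, box, 3)
  qidx <- cpp_nearest(bead_cov, maug$points, cs)
  qpts <- maug$points[qidx, , drop = FALSE]
  rel <- bead_cov - qpts
  reln <- rowSums(rel * nb)
  foot <- bead_cov - reln * nb
  height <- -reln                              # along outward normal (-tail)

  # depth relative to the same lipid's reference bead, positive toward tails
  refb <- refs[lip, , drop = FALSE]
  depth <- rowSums(min_image(sub$coords - refb, box) * nb)
  dval <- classify_bead(bt$class, depth, deep_threshold)

  # assignment with seam ghosts for the beads
  rmax <- max(bt$radius)
  baug <- ghost_cover(foot, off, box, rmax + 0.5)
  bsrc <- baug$source
  win_aug <- cpp_assign_tiles(mesh$midpoints, baug$points,
                              bt$radius[bsrc], height[bsrc],
                              as.integer(sub$residue_id[bsrc]))
  winner <- ifelse(win_aug > 0L, bsrc[pmax(win_aug, 1L)], NA_integer_)

  structure(list(
    d_type = ifelse(is.na(winner), NA_real_, dval[pmax(winner, 1L)]),
    winner_residue = ifelse(is.na(winner), NA_integer_,
                            sub$residue_id[pmax(winner, 1L)]),
    winner_bead = ifelse(is.na(winner), NA_character_,
                         sub$bead_name[pmax(winner, 1L)]),
    depth = ifelse(is.na(winner), NA_real_, depth[pmax(winner, 1L)]),
    n_beads = nrow(sub$coords)
  ), class = "tile_state")
}

#' Cluster connected defect tiles
#'
#' Connected components over tiles with d_type < 1 that share a mesh vertex.
#' Unassigned tiles are never members and never act as connectors.
#'
#' @param tilestate a `tile_state` from [project_beads()].
#' @param mesh the matching `leaflet_mesh`.
#' @param kind `"overall"` (all d_type < 1), `"deep"` (d_type = 0) or
#'   `"shallow"` (d_type = 0.001).
#' @return a `defect_clusters` object: list with `clusters` (data.frame
#'   `cluster`, `area`, `touches_boundary`, `n_tiles`) and `members` (list of
#'   member tile indices per cluster), plus `kind`.
#' @export
cluster_defects <- function(tilestate, mesh,
                            kind = c("overall", "deep", "shallow")) {
  kind <- match.arg(kind)
  d <- tilestate$d_type
  members <- switch(kind,
    overall = which(!is.na(d) & d < 1),
    deep = which(!is.na(d) & d == 0),
    shallow = which(!is.na(d) & d == 0.001)
  )
  if (!length(members)) {
    return(structure(list(
      clusters = data.frame(cluster = integer(), area = numeric(),
                            touches_boundary = logical(),
                            n_tiles = integer()),
      members = list(), kind = kind), class = "defect_clusters"))
  }
  tv <- mesh$triangles[members, , drop = FALSE]
  # star edges within each vertex's incident member tiles give connectivity
  vert <- as.vector(tv)
  tile <- rep(seq_along(members), 3)
  ord <- order(vert)
  vert <- vert[ord]; tile <- tile[ord]
  runs <- rle(vert)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  multi <- which(runs$lengths > 1)
  if (length(multi)) {
    efrom <- unlist(lapply(multi, function(m) {
      rep(tile[starts[m]], runs$lengths[m] - 1)
    }))
    eto <- unlist(lapply(multi, function(m) {
      tile[(starts[m] + 1):ends[m]]
    }))
    g <- igraph::make_empty_graph(n = length(members), directed = FALSE)
    g <- igraph::add_edges(g, rbind(efrom, eto))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(members)
  }
  labs <- sort(unique(memb))
  area <- as.numeric(rowsum(mesh$areas[members], memb)[as.character(labs), 1])
  bnd <- as.logical(rowsum(as.integer(mesh$boundary[members]),
                           memb)[as.character(labs), 1] > 0)
  ntile <- as.integer(table(memb)[as.character(labs)])
  mem_list <- split(members, memb)[as.character(labs)]
  structure(list(
    clusters = data.frame(cluster = seq_along(labs), area = area,
                          touches_boundary = bnd, n_tiles = ntile),
    members = unname(mem_list), kind = kind), class = "defect_clusters")
}

#' Remove defect clusters touching the simulation-box boundary
#'
#' Clusters containing at least one boundary tile suffer from the open mesh
#' seam at the periodic faces and are removed; the removal count is recorded
#' in the `n_removed` attribute.
#'
#' @param clusters a `defect_clusters` object.
#' @return a filtered `defect_clusters`.
#' @export
filter_clusters <- function(clusters) {
  keep <- !clusters$clusters$touches_boundary
  out <- structure(list(
    clusters = clusters$clusters[keep, , drop = FALSE],
    members = clusters$members[keep], kind = clusters$kind),
    class = "defect_clusters")
  out$clusters$cluster <- seq_len(nrow(out$clusters))
  attr(out, "n_removed") <- sum(!keep)
  out
}
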