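#' Build an oriented point cloud for one leaflet
#'
#' Each lipid is represented by its anchor-bead position and a unit normal
#' estimated from the local surface spanned by its k nearest anchor
#' neighbours (local plane fit / PCA; the normal is the direction of least
#' variance). Normals are flipped where needed so that they point toward the
#' lipid tails (centroid of the tail beads). Periodic ghost copies of anchors
#' within `pbc_margin` of a box face are used for the neighbourhoods so that
#' normals are unbiased at the box seam.
#'
#' @param snapshot a [cg_snapshot()].
#' @param assignment a `leaflet_assignment` from [assign_leaflets()].
#' @param leaflet leaflet label to extract.
#' @param ff force-field specification.
#' @param k_neighbors neighbourhood size for the local plane fit (>= 3).
#' @param pbc_margin ghost margin in Angstrom for periodic neighbourhoods.
#' @return an `oriented_cloud`: list with `points` (n x 3), `normals`
#'   (n x 3, unit, toward tails), `residue_id`, `box`, and `spacing`
#'   (mean nearest-neighbour anchor distance).
#' @export
make_oriented_cloud <- function(snapshot, assignment, leaflet, ff,
                                k_neighbors = 12, pbc_margin = 10) {
  ids <- leaflet_members(assignment, leaflet)
  if (!length(ids)) stop("leaflet ", leaflet, " is empty")
  if (k_neighbors < 3) stop("k_neighbors must be >= 3")
  k_neighbors <- min(k_neighbors, length(ids) - 1L)
  anchors <- bead_positions(snapshot, ids, ff, "anchor")
  # first pass: nearest-neighbour spacing estimate, then ghost out to the
  # full k-neighbourhood radius so neighbourhoods are min-image complete
  # (and therefore invariant under rigid translation with box wrapping)
  if (nrow(anchors) > 2) {
    nn0 <- cpp_knn(anchors, nrow(anchors), 1L, 8)
    sp0 <- stats::median(sqrt(rowSums((anchors[nn0[, 1], , drop = FALSE] -
                                         anchors)^2)))
  } else {
    sp0 <- 8
  }
  margin <- max(pbc_margin, ceiling((sqrt(k_neighbors) + 2) * sp0))
  aug <- handle_periodicity(anchors, snapshot$box, margin)
  nn <- cpp_knn(aug$points, nrow(anchors), k_neighbors, max(sp0, 2))
  spacing <- mean(sqrt(rowSums((aug$points[nn[, 1], , drop = FALSE] -
                                  anchors) ^ 2)))

  normals <- matrix(0, nrow(anchors), 3)
  for (i in seq_len(nrow(anchors))) {
    nbr <- aug$points[c(i, nn[i, ]), , drop = FALSE]
    cc <- sweep(nbr, 2, colMeans(nbr))
    ev <- eigen(crossprod(cc), symmetric = TRUE)
    if (ev$values[2] < 1e-9 * max(ev$values[1], 1e-300)) {
      # collinear neighbourhood: widen k and retry once
      k2 <- min(2 * k_neighbors, nrow(aug$points) - 1L)
      warning("degenerate neighbourhood for lipid ", ids[i],
              "; retrying with k = ", k2)
      nn2 <- cpp_knn(aug$points, nrow(anchors), k2, cs)
      nbr <- aug$points[c(i, nn2[i, ]), , drop = FALSE]
      cc <- sweep(nbr, 2, colMeans(nbr))
      ev <- eigen(crossprod(cc), symmetric = TRUE)
    }
    normals[i, ] <- ev$vectors[, 3]
  }

  # orient toward tails
  rn <- residue_names(snapshot, ids)
  tailvec <- matrix(0, length(ids), 3)
  for (i in seq_along(ids)) {
    res <- ff_residue(ff, rn[i])
    rows <- which(snapshot$residue_id == ids[i] &
                    snapshot$bead_name %in% res$tail_beads)
    tc <- colMeans(snapshot$coords[rows, , drop = FALSE])
    tailvec[i, ] <- min_image(matrix(tc - anchors[i, ], 1), snapshot$box)
  }
  dt <- rowSums(normals * tailvec)
  flip <- dt < 0
  normals[flip, ] <- -normals[flip, ]
  # zero tail vectors (single-bead residues): orient with the local majority
  undef <- sqrt(rowSums(tailvec^2)) < 1e-6
  if (any(undef)) {
    for (i in which(undef)) {
      nbr_idx <- aug$source[nn[i, ]]
      ref <- colSums(normals[setdiff(nbr_idx, which(undef)), , drop = FALSE])
      if (sum(normals[i, ] * ref) < 0) normals[i, ] <- -normals[i, ]
    }
  }
  normals <- normals / sqrt(rowSums(normals^2))
  structure(list(points = anchors, normals = normals, residue_id = ids,
                 box = snapshot$box, spacing = spacing),
            class = "oriented_cloud")
}

#' @export
print.oriented_cloud <- function(x, ...) {
  cat(sprintf("<oriented_cloud> %d lipids, mean anchor spacing %.2f A\n",
              nrow(x$points), x$spacing))
  invisible(x)
}
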