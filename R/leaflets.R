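#' Split lipids into leaflet pools
#'
#' Clusters lipids into leaflets via connected components of the anchor-bead
#' proximity graph (minimum-image distances under the periodic box). For a
#' flat or buckled bilayer the two leaflets are well separated at the default
#' 15 Angstrom cutoff; for a closed vesicle the inner and outer leaflets form
#' two distinct components. Leaflet labels are deterministic: components are
#' ordered by decreasing size, ties broken by the smallest member residue id
#' (so for a vesicle leaflet 0 is the outer, more populous leaflet).
#'
#' @param snapshot a [cg_snapshot()].
#' @param ff a [forcefield_spec()] describing every residue in the snapshot.
#' @param cutoff anchor-anchor proximity cutoff in Angstrom.
#' @param n_leaflets if non-NULL, merge the smallest components (by centroid
#'   distance) until this many leaflets remain, e.g. 2 for a declared bilayer.
#' @return a `leaflet_assignment`: list with `residue_id` (per-lipid ids),
#'   `leaflet` (labels 0, 1, ...), and `counts` per leaflet.
#' @export
assign_leaflets <- function(snapshot, ff, cutoff = 15, n_leaflets = NULL) {
  ids <- snapshot_residues(snapshot)
  if (!length(ids)) stop("snapshot contains no lipids")
  anchors <- bead_positions(snapshot, ids, ff, "anchor")
  n <- length(ids)
  if (n == 1L) {
    comp <- 1L
  } else {
    pairs <- cpp_pairs_within(anchors, cutoff, snapshot$box)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)$membership
  }
  # merge singletons / undersized components into the nearest leaflet
  sizes <- tabulate(comp)
  main <- which(sizes >= 3L)
  if (!length(main)) main <- which.max(sizes)
  stray <- which(!(comp %in% main))
  if (length(stray)) {
    warning(length(stray),
            " isolated lipid(s) assigned to the nearest leaflet by anchor distance")
    for (i in stray) {
      cand <- which(comp %in% main)
      d <- min_image(sweep(anchors[cand, , drop = FALSE], 2, anchors[i, ]),
                     snapshot$box)
      comp[i] <- comp[cand[which.min(rowSums(d^2))]]
    }
  }
  # merge down to a declared leaflet count by centroid distance
  if (!is.null(n_leaflets)) {
    repeat {
      labs <- sort(unique(comp))
      if (length(labs) <= n_leaflets) break
      sizes <- vapply(labs, function(l) sum(comp == l), 0L)
      small <- labs[which.min(sizes)]
      cent <- vapply(labs, function(l) colMeans(anchors[comp == l, , drop = FALSE]),
                     numeric(3))
      sc <- cent[, labs == small]
      others <- labs[labs != small]
      dd <- vapply(others, function(l) {
        d <- min_image(matrix(cent[, labs == l] - sc, 1), snapshot$box)
        sum(d^2)
      }, 0)
      comp[comp == small] <- others[which.min(dd)]
    }
  }
  # deterministic relabeling: size desc, then smallest residue id
  labs <- sort(unique(comp))
  sizes <- vapply(labs, function(l) sum(comp == l), 0L)
  first <- vapply(labs, function(l) min(ids[comp == l]), 0L)
  ord <- order(-sizes, first)
  newlab <- integer(max(labs))
  newlab[labs[ord]] <- seq_along(labs) - 1L
  leaflet <- newlab[comp]
  structure(list(residue_id = ids, leaflet = leaflet,
                 counts = tabulate(leaflet + 1L)),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat("<leaflet_assignment>", length(x$counts), "leaflet(s):",
      paste(x$counts, collapse = " + "), "lipids\n")
  invisible(x)
}

leaflet_members <- function(assignment, leaflet) {
  assignment$residue_id[assignment$leaflet == leaflet]
}

#' Augment a point set with periodic ghost copies
#'
#' Points within `margin` of a periodic box face are replicated across that
#' face so that surface reconstruction spans the box seamlessly. With
#' `margin = 0` no ghosts are added.
#'
#' @param points N x 3 matrix (Angstrom); assumed wrapped into the box.
#' @param box length-3 box.
#' @param margin ghost margin in Angstrom.
#' @param periodic logical length 3; which dimensions are periodic.
#' @return list with `points` ((N + G) x 3, originals first), `source`
#'   (1-based row of the originating point for every row) and `is_ghost`.
#' @export
handle_periodicity <- function(points, box, margin = 10,
                               periodic = c(TRUE, TRUE, TRUE)) {
  points <- as.matrix(points)
  out <- points
  src <- seq_len(nrow(points))
  if (margin > 0) {
    near_lo <- lapply(1:3, function(d) points[, d] < margin)
    near_hi <- lapply(1:3, function(d) points[, d] > box[d] - margin)
    shifts <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
    for (s in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[s, ]) * ifelse(periodic, 1, 0)
      if (all(sh == 0)) next
      keep <- rep(TRUE, nrow(points))
      for (d in 1:3) {
        if (sh[d] > 0) keep <- keep & near_lo[[d]]
        if (sh[d] < 0) keep <- keep & near_hi[[d]]
      }
      if (any(keep)) {
        out <- rbind(out, sweep(points[keep, , drop = FALSE], 2, sh * box,
                                "+"))
        src <- c(src, which(keep))
      }
    }
  }
  list(points = out, source = src,
       is_ghost = c(rep(FALSE, nrow(points)),
                    rep(TRUE, length(src) - nrow(points))))
}
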