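#' Partition a leaflet mesh into curvature-sign domains
#'
#' For geometries whose curvature does not change along one Cartesian
#' direction (e.g. a buckle invariant along y), the surface is binned along
#' the profile direction orthogonal to the invariant axis, normals are
#' area-averaged per bin, and the signed turning angle between neighbouring
#' bin normals classifies each bin: |angle| at or below the threshold gives
#' a flat domain (J0); turning that bends the surface convex toward the
#' solvent side of the leaflet gives J+ (positive curvature), the opposite
#' J-. Only the sign of the curvature is distinguished. Isolated single-bin
#' labels are absorbed by their neighbours.
#'
#' The signed turning between bins i and i+1 is computed as
#' `dot(n_out(i+1) - n_out(i), t)` with `t` the unit step between the bins'
#' area-weighted centres and `n_out` the outward (solvent-side) normal, i.e.
#' the discrete curvature of the profile curve: positive for a surface
#' convex toward the solvent (a crest of the upper leaflet).
#'
#' For closed cross-sections (a cylinder seen along its axis) the profile
#' coordinate is the angle about the invariant axis instead of a Cartesian
#' coordinate; this is detected automatically (the mesh encircles its
#' centroid) or forced with `profile = "angular"`.
#'
#' @param mesh a `leaflet_mesh` (normals toward the tails).
#' @param axis invariant axis: `"x"`, `"y"` or `"z"`.
#' @param n_bins number of bins along the profile direction; NULL picks a
#'   bin width of about 10 Angstrom.
#' @param angle_threshold flat-domain threshold on the per-neighbour turning
#'   angle, in degrees.
#' @param profile_axis optional profile direction; by default the coordinate
#'   (distinct from `axis`) with the largest midpoint spread.
#' @param profile `"auto"`, `"linear"` or `"angular"`.
#' @return a `curvature_domains` object: per-triangle `bin` and `label`
#'   (`"J+"`, `"J-"`, `"J0"`), per-bin `bin_label`, `bin_normal`,
#'   `turning_deg`, plus bookkeeping fields.
#' @export
bin_and_classify <- function(mesh, axis = "y", n_bins = NULL,
                             angle_threshold = 2, profile_axis = NULL,
                             profile = c("auto", "linear", "angular")) {
  profile <- match.arg(profile)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of x, y, z")
  others <- setdiff(1:3, ax)

  w0 <- mesh$areas
  if (profile != "linear") {
    # does the cross-section encircle its centroid? (closed tube profile)
    ctr2 <- c(sum(mesh$midpoints[, others[1]] * w0),
              sum(mesh$midpoints[, others[2]] * w0)) / sum(w0)
    a2 <- mesh$midpoints[, others[1]] - ctr2[1]
    b2 <- mesh$midpoints[, others[2]] - ctr2[2]
    rad <- sqrt(a2^2 + b2^2)
    phi <- atan2(b2, a2)
    occ_bin <- findInterval(phi, seq(-pi, pi, length.out = 25),
                            rightmost.closed = TRUE)
    occupied <- tabulate(occ_bin, 24) > 0
    ring_ok <- all(occupied) &&
      min(tapply(rad, occ_bin, stats::median)) > 0.5 * stats::median(rad)
    if (profile == "angular" || (profile == "auto" && ring_ok)) {
      coord <- phi
      if (is.null(n_bins)) {
        n_bins <- max(3L, round(2 * pi * stats::median(rad) / 10))
      }
      edges <- seq(-pi - 1e-9, pi + 1e-9, length.out = n_bins + 1)
      bin <- findInterval(coord, edges, rightmost.closed = TRUE)
      bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
      return(classify_bins(mesh, bin, n_bins, angle_threshold,
                           invariant = ax, prof = NA_integer_,
                           circular = TRUE))
    }
  }

  if (is.null(profile_axis)) {
    spread <- vapply(others, function(d) diff(range(mesh$midpoints[, d])), 0)
    prof <- others[which.max(spread)]
  } else {
    prof <- match(profile_axis, c("x", "y", "z"))
    if (is.na(prof) || prof == ax) stop("invalid profile_axis")
  }
  coord <- mesh$midpoints[, prof]
  rng <- range(coord)
  if (is.null(n_bins)) n_bins <- max(3L, round(diff(rng) / 10))
  if (n_bins < 3) stop("n_bins must be at least 3")
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  bin <- findInterval(coord, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  circ <- !is.null(mesh$box) && diff(rng) > 0.9 * mesh$box[prof]
  classify_bins(mesh, bin, n_bins, angle_threshold, invariant = ax,
                prof = prof, circular = circ)
}

# shared second stage: per-bin averaged normals, signed turning, labels
classify_bins <- function(mesh, bin, n_bins, angle_threshold, invariant,
                          prof, circular) {
  # merge empty bins into their lower neighbour
  present <- sort(unique(bin))
  if (length(present) < n_bins) {
    message(n_bins - length(present), " empty bin(s) merged with neighbours")
  }
  remap <- cumsum(seq_len(n_bins) %in% present)
  remap[remap < 1] <- 1
  bin <- remap[bin]
  nb <- max(bin)
  if (nb < 3) stop("fewer than 3 non-empty bins along the profile direction")

  w <- mesh$areas
  fo <- -mesh$face_normals       # outward = opposite of tail-side normals
  bn <- matrix(0, nb, 3)
  bc <- matrix(0, nb, 3)
  for (j in 1:3) {
    bn[, j] <- rowsum(fo[, j] * w, bin)[, 1]
    bc[, j] <- rowsum(mesh$midpoints[, j] * w, bin)[, 1] /
      rowsum(w, bin)[, 1]
  }
  bn <- bn / sqrt(rowSums(bn^2))

  pair_next <- if (circular) c(2:nb, 1) else c(2:nb, NA)
  turning <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    j <- pair_next[i]
    if (is.na(j)) next
    step <- bc[j, ] - bc[i, ]
    if (circular && i == nb && !is.na(prof)) {
      step[prof] <- step[prof] + mesh$box[prof]   # wrap across the box
    }
    tt <- step / sqrt(sum(step^2))
    dn <- bn[j, ] - bn[i, ]
    mag <- acos(pmin(1, pmax(-1, sum(bn[i, ] * bn[j, ])))) * 180 / pi
    turning[i] <- sign(sum(dn * tt)) * mag
  }
  # per-bin angle: mean of the turnings on the two flanks
  flank <- cbind(turning, turning[if (circular) c(nb, 1:(nb - 1)) else
    c(NA, 1:(nb - 1))])
  bin_angle <- rowMeans(flank, na.rm = TRUE)
  lab <- ifelse(abs(bin_angle) <= angle_threshold, "J0",
                ifelse(bin_angle > 0, "J+", "J-"))
  # absorb isolated single-bin labels
  if (nb >= 3) {
    for (i in 2:(nb - 1)) {
      if (lab[i] != lab[i - 1] && lab[i] != lab[i + 1] &&
          lab[i - 1] == lab[i + 1]) {
        lab[i] <- lab[i - 1]
      }
    }
  }
  structure(list(bin = bin, label = lab[bin], bin_label = lab,
                 bin_normal = bn, bin_centre = bc, turning_deg = turning,
                 invariant_axis = c("x", "y", "z")[invariant],
                 profile_axis = if (is.na(prof)) "angular" else
                   c("x", "y", "z")[prof],
                 n_bins = nb, circular = circular,
                 angle_threshold = angle_threshold),
            class = "curvature_domains")
}

#' @export
print.curvature_domains <- function(x, ...) {
  cat("<curvature_domains>", x$n_bins, "bins along", x$profile_axis,
      "(invariant", paste0(x$invariant_axis, "):"),
      paste(sprintf("%s=%d", c("J+", "J-", "J0"),
                    c(sum(x$bin_label == "J+"), sum(x$bin_label == "J-"),
                      sum(x$bin_label == "J0"))), collapse = " "), "\n")
  invisible(x)
}

# majority-area domain of one cluster (member triangle indices)
split_cluster_domain <- function(members, mesh, map) {
  a <- rowsum(mesh$areas[members], map$label[members])
  labs <- rownames(a)
  mx <- max(a[, 1])
  top <- labs[a[, 1] >= mx - 1e-9]
  if (length(top) > 1) {
    # exact tie: prefer the curved domain over flat, then J+ over J-
    pref <- c("J+" = 1, "J-" = 2, "J0" = 3)
    top <- top[order(pref[top])]
  }
  top[1]
}

#' Split defect areas by curvature-sign domain
#'
#' Each cluster is assigned to the domain containing the majority of its
#' area (exact ties go to the curved domain over the flat one).
#'
#' @param clusters a `defect_clusters` object.
#' @param mesh the matching `leaflet_mesh`.
#' @param map a `curvature_domains` from [bin_and_classify()].
#' @return named list of numeric area vectors, one per domain label.
#' @export
split_areas_by_domain <- function(clusters, mesh, map) {
  if (!nrow(clusters$clusters)) {
    return(list(`J+` = numeric(), `J-` = numeric(), J0 = numeric()))
  }
  dom <- vapply(clusters$members, split_cluster_domain, "", mesh = mesh,
                map = map)
  out <- split(clusters$clusters$area, dom)
  for (l in c("J+", "J-", "J0")) if (is.null(out[[l]])) out[[l]] <- numeric()
  out[c("J+", "J-", "J0")]
}
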