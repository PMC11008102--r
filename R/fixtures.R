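# Fixture geometry constants: a minimal 4-bead lipid exercising every
# classification rule. Offsets are along the local outward normal from the
# reference (glycerol-level) bead; the head sits above it, two aliphatic
# tail beads below. Planted patch beads sit just above the head level so
# they are the most solvent-proximal beads wherever they overlap.
FIX_HEAD_OFF <- 3
FIX_TAIL1_OFF <- -3
FIX_TAIL2_OFF <- -6
FIX_LEAFLET_SEP <- 15     # reference surface offset from the midsurface
FIX_BEAD_RADIUS <- 2.64   # Martini-style regular bead VdW radius
FIX_PATCH_RADIUS <- 1.4   # small patch bead radius
FIX_PATCH_RAISE <- FIX_HEAD_OFF + 2.0  # clear of jittered head beads

#' Describe a synthetic membrane fixture
#'
#' The generator's defaults define the study conditions used throughout the
#' tests: quasi-planar or curved bead lattices at a typical coarse-grained
#' areal density (60 square Angstrom per lipid), small thermal jitter, and
#' planted hydrophobic patches whose target areas are drawn from the
#' exponential defect-size law with a known constant.
#'
#' @param geometry `"flat"`, `"buckle"`, `"sphere"` or `"cylinder"`.
#' @param n_lipids total lipid count (split over both leaflets of a
#'   bilayer); for spheres the count follows from the radius and the area
#'   per lipid.
#' @param area_per_lipid areal density, square Angstrom per lipid.
#' @param leaflets `"bilayer"` or `"monolayer"`.
#' @param amplitude,wavelength buckle shape (Angstrom); `wavelength = NULL`
#'   uses one period per box length.
#' @param radius sphere/cylinder midsurface radius (Angstrom).
#' @param planted_pi defect constant of the planted patch areas (square
#'   Angstrom); NULL plants nothing.
#' @param patches_per_frame planted patches per leaflet per frame.
#' @param jitter per-lipid rigid Gaussian displacement sigma (Angstrom);
#'   the whole molecule moves together, as in thermal diffusion.
#' @param bead_jitter additional independent per-bead noise sigma
#'   (Angstrom); this is what exposes thin tail slivers and generates the
#'   small-defect background population.
#' @param box_height box extent normal to a flat/buckled membrane.
#' @param mix optional list(types = c(a, b), fraction = f, arrangement =
#'   "random" or "demixed") assigning two residue type labels for mixing
#'   statistics.
#' @param seed RNG seed (mandatory for reproducible fixtures).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(geometry = "flat", n_lipids = 3000,
                         area_per_lipid = 60, leaflets = "bilayer",
                         amplitude = 30, wavelength = NULL, radius = 100,
                         planted_pi = NULL, patches_per_frame = 8,
                         jitter = 0.5, bead_jitter = 0.2, box_height = 100,
                         mix = NULL, seed = 1) {
  geometry <- match.arg(geometry, c("flat", "buckle", "sphere", "cylinder"))
  leaflets <- match.arg(leaflets, c("bilayer", "monolayer"))
  stopifnot(n_lipids > 0, area_per_lipid > 0, jitter >= 0, bead_jitter >= 0,
            is.null(planted_pi) || planted_pi > 0)
  structure(list(geometry = geometry, n_lipids = n_lipids,
                 area_per_lipid = area_per_lipid, leaflets = leaflets,
                 amplitude = amplitude, wavelength = wavelength,
                 radius = radius, planted_pi = planted_pi,
                 patches_per_frame = patches_per_frame, jitter = jitter,
                 bead_jitter = bead_jitter,
                 box_height = box_height, mix = mix, seed = seed),
            class = "fixture_spec")
}

#' Force field for the synthetic fixture lipids
#'
#' @param types residue type names for the 4-bead lipid (all identical in
#'   geometry); a patch residue `PTCH` is always included.
#' @return a `forcefield_spec`.
#' @export
fixture_forcefield <- function(types = "LIPA") {
  beads <- data.frame(
    bead = c("HD", "GL", "T1", "T2"),
    radius = rep(FIX_BEAD_RADIUS, 4),
    class = c("polar", "polar", "aliphatic", "aliphatic"),
    stringsAsFactors = FALSE)
  res <- lapply(types, function(t) {
    list(anchor_bead = "GL", reference_bead = "GL", beads = beads,
         tail_beads = c("T1", "T2"))
  })
  names(res) <- types
  # planted-patch pseudo-residue: PA anchors the patch on the reference
  # surface (tiny radius, never wins a tile); PB beads carry the exposed
  # hydrophobic area just above the head level
  res$PTCH <- list(
    anchor_bead = "PA", reference_bead = "PA",
    beads = data.frame(bead = c("PA", "PB"),
                       radius = c(0.1, FIX_PATCH_RADIUS),
                       class = c("aliphatic", "aliphatic"),
                       stringsAsFactors = FALSE),
    tail_beads = "PA")
  forcefield_spec(res)
}

#' Sample exponential defect areas
#'
#' Direct sampler of the single-exponential defect-size law with constant
#' `pi` (mean area `pi` square Angstrom).
#'
#' @param pi defect constant (square Angstrom).
#' @param n number of draws.
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored).
#' @return numeric vector of `n` positive areas.
#' @export
sample_exponential_areas <- function(pi, n, seed = NULL) {
  stopifnot(pi > 0, n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  stats::rexp(n, rate = 1 / pi)
}

# ring layout of patch beads covering a disc of radius rt (>= r0): bead
# centres on concentric rings so the union of their r0-discs is the disc of
# radius rt. Returns a 2-column matrix of in-plane offsets.
patch_bead_layout <- function(rt, r0 = FIX_PATCH_RADIUS, ring_dr = 1.0,
                              arc = 1.0) {
  rt <- max(rt, r0)
  rho <- seq(rt - r0, 0, by = -ring_dr)
  rho <- rho[rho > 1e-9]
  offs <- matrix(0, 1, 2)  # centre bead
  for (r in rho) {
    m <- max(3, ceiling(2 * base::pi * r / arc))
    th <- stats::runif(1, 0, 2 * base::pi) + 2 * base::pi * (0:(m - 1)) / m
    offs <- rbind(offs, cbind(r * cos(th), r * sin(th)))
  }
  offs
}

# geometry parameterizations: return functions mapping lattice/param coords
# to base point + outward normal + tangent frame for one leaflet.
fixture_geometry <- function(spec) {
  apl <- spec$area_per_lipid
  s <- sqrt(apl)
  n_leaf <- if (spec$leaflets == "bilayer") 2L else 1L
  geom <- spec$geometry
  if (geom %in% c("flat", "buckle")) {
    n_per <- round(spec$n_lipids / n_leaf)
    nx <- max(4L, round(sqrt(n_per)))
    ny <- max(4L, round(n_per / nx))
    amp <- if (geom == "buckle") spec$amplitude else 0
    box <- c(nx * s, ny * s, spec$box_height + 2 * amp)
    mid <- box[3] / 2
    wav <- if (is.null(spec$wavelength)) box[1] else spec$wavelength
    k <- 2 * base::pi / wav
    surf <- function(u, v, leaflet) {
      z <- mid + amp * sin(k * u)
      dz <- amp * k * cos(k * u)
      nrm <- sqrt(1 + dz^2)
      m <- cbind(-dz, 0, 1) / nrm   # upper midsurface normal
      sgn <- if (leaflet == 0) 1 else -1
      p <- cbind(u, v, z) + FIX_LEAFLET_SEP * sgn * m
      e1 <- cbind(1, 0, dz) / nrm
      list(p = p, n = sgn * m, e1 = e1,
           e2 = matrix(rep(c(0, 1, 0), each = length(u)), ncol = 3))
    }
    lattice <- function(leaflet) {
      g <- expand.grid(i = seq_len(nx) - 0.5, j = seq_len(ny) - 0.5)
      list(u = g$i * s, v = g$j * s)
    }
    domain_of <- function(u) {
      if (amp == 0) return(rep("J0", length(u)))
      sv <- sin(k * u)
      ifelse(abs(sv) <= 0.2, "J0", ifelse(sv > 0, "J+", "J-"))
    }
    area_leaf <- function(leaflet) nx * ny * apl
    rand_param <- function() c(stats::runif(1, 0, box[1]),
                               stats::runif(1, 0, box[2]))
    interior <- function(u, v, rt, margin = 2) {
      u - rt > margin & u + rt < box[1] - margin &
        v - rt > margin & v + rt < box[2] - margin
    }
    list(box = box, n_leaflets = n_leaf, surf = surf, lattice = lattice,
         domain_of = domain_of, area_leaf = area_leaf,
         rand_param = rand_param, interior = interior, periodic_param = TRUE)
  } else if (geom == "sphere") {
    pad <- 40
    R <- spec$radius
    radii <- if (n_leaf == 2) c(R + FIX_LEAFLET_SEP, R - FIX_LEAFLET_SEP)
             else R
    box <- rep(2 * (max(radii) + pad), 3)
    ctr <- box / 2
    surf <- function(u, v, leaflet) {
      # u, v: unit direction encoded as rows of a matrix passed via attr
      stop("sphere uses direct lattice points")
    }
    lattice_pts <- function(leaflet) {
      Rl <- radii[leaflet + 1]
      n <- max(50L, round(4 * base::pi * Rl^2 / apl))
      i <- seq_len(n) - 0.5
      phi <- acos(1 - 2 * i / n)
      theta <- base::pi * (1 + sqrt(5)) * i
      dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
      sgn <- if (leaflet == 0) 1 else -1   # outer leaflet solvent = outside
      list(p = sweep(Rl * dirs, 2, ctr, "+"), n = sgn * dirs)
    }
    list(box = box, n_leaflets = n_leaf, lattice_pts = lattice_pts,
         radii = radii, centre = ctr, periodic_param = FALSE)
  } else { # cylinder, axis y (periodic)
    pad <- 40
    R <- spec$radius
    radii <- if (n_leaf == 2) c(R + FIX_LEAFLET_SEP, R - FIX_LEAFLET_SEP)
             else R
    n_per <- round(spec$n_lipids / n_leaf)
    Ly <- max(4 * s, round(n_per * apl / (2 * base::pi * R)))
    box <- c(2 * (max(radii) + pad), Ly, 2 * (max(radii) + pad))
    ctr <- c(box[1] / 2, 0, box[3] / 2)
    lattice_pts <- function(leaflet) {
      Rl <- radii[leaflet + 1]
      ntheta <- max(8L, round(2 * base::pi * Rl / s))
      nyl <- max(4L, round(Ly / s))
      g <- expand.grid(t = seq_len(ntheta) - 0.5, j = seq_len(nyl) - 0.5)
      th <- 2 * base::pi * g$t / ntheta
      y <- g$j * (Ly / nyl)
      dirs <- cbind(cos(th), 0, sin(th))
      sgn <- if (leaflet == 0) 1 else -1
      list(p = cbind(ctr[1] + Rl * cos(th), y, ctr[3] + Rl * sin(th)),
           n = sgn * dirs)
    }
    list(box = box, n_leaflets = n_leaf, lattice_pts = lattice_pts,
         radii = radii, centre = ctr, periodic_param = FALSE)
  }
}

#' Generate synthetic membrane snapshots with known ground truth
#'
#' Every lipid gets a polar head bead, a polar reference (glycerol-level)
#' bead and two aliphatic tail beads stacked along the local inward normal,
#' with independent Gaussian jitter. Planted hydrophobic patches are
#' realized as rings of small aliphatic beads placed just above the head
#' level over a disc whose radius matches the drawn exponential target area,
#' so the exposed (measured) defect area reproduces the drawn area; draws
#' below the minimum realizable patch (one bead, ~6 square Angstrom) pile up
#' at that size, below the standard 15 square Angstrom fitting floor.
#'
#' @param spec a [fixture_spec()].
#' @param n_frames number of frames to generate.
#' @param vary_frames redraw jitter and patches per frame (TRUE) or replay
#'   one identical frame (FALSE).
#' @return list with `frames` (list of [cg_snapshot()]), `truth` (list with
#'   `patches` data.frame, `lipids` data.frame with leaflet and type per
#'   lipid), and `ff` (the matching [forcefield_spec()]).
#' @export
generate_fixture <- function(spec, n_frames = 1, vary_frames = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"), n_frames >= 1)
  set.seed(spec$seed)
  geo <- fixture_geometry(spec)
  types <- if (!is.null(spec$mix)) spec$mix$types else "LIPA"
  ff <- fixture_forcefield(types)

  # static lattice: base positions and outward normals per leaflet
  leaf_pts <- list()
  for (leaf in seq_len(geo$n_leaflets) - 1L) {
    if (!is.null(geo$lattice_pts)) {
      leaf_pts[[leaf + 1]] <- geo$lattice_pts(leaf)
    } else {
      lat <- geo$lattice(leaf)
      sf <- geo$surf(lat$u, lat$v, leaf)
      leaf_pts[[leaf + 1]] <- list(p = sf$p, n = sf$n, u = lat$u, v = lat$v)
    }
  }
  n_per <- vapply(leaf_pts, function(l) nrow(l$p), 0L)
  n_lip <- sum(n_per)
  lip_leaf <- rep(seq_len(geo$n_leaflets) - 1L, n_per)

  # mixing labels
  lip_type <- rep(types[1], n_lip)
  if (!is.null(spec$mix)) {
    f <- spec$mix$fraction
    if (identical(spec$mix$arrangement, "demixed")) {
      xs <- do.call(rbind, lapply(leaf_pts, function(l) l$p))[, 1]
      lip_type <- ifelse(xs < stats::quantile(xs, f), types[1], types[2])
    } else {
      lip_type <- ifelse(stats::runif(n_lip) < f, types[1], types[2])
    }
  }

  # patch-area budget guard: dilute, noninteracting defects only
  if (!is.null(spec$planted_pi)) {
    budget <- spec$patches_per_frame * spec$planted_pi
    leaf_area <- if (!is.null(geo$area_leaf)) geo$area_leaf(0) else
      n_per[1] * spec$area_per_lipid
    if (budget > 0.3 * leaf_area) {
      stop("requested patch areas exceed 30% of the leaflet area; ",
           "the dilute-defect assumption would be violated")
    }
  }

  make_frame <- function(fi) {
    coords <- list(); bead <- list(); resn <- list(); resid <- list()
    rid <- 0L
    for (leaf in seq_len(geo$n_leaflets) - 1L) {
      lp <- leaf_pts[[leaf + 1]]
      nl <- nrow(lp$p)
      offs <- c(FIX_HEAD_OFF, 0, FIX_TAIL1_OFF, FIX_TAIL2_OFF)
      pos <- lp$p[rep(seq_len(nl), each = 4), ] +
        lp$n[rep(seq_len(nl), each = 4), ] * rep(offs, nl)
      # rigid per-lipid displacement plus small independent per-bead noise
      lipj <- matrix(stats::rnorm(3 * nl, 0, spec$jitter), ncol = 3)
      pos <- pos + lipj[rep(seq_len(nl), each = 4), ] +
        matrix(stats::rnorm(length(pos), 0, spec$bead_jitter), ncol = 3)
      coords[[length(coords) + 1]] <- pos
      bead[[length(bead) + 1]] <- rep(c("HD", "GL", "T1", "T2"), nl)
      idx <- which(lip_leaf == leaf)
      resn[[length(resn) + 1]] <- rep(lip_type[idx], each = 4)
      resid[[length(resid) + 1]] <- rep(rid + seq_len(nl) - 1L, each = 4)
      rid <- rid + nl
    }
    patches <- NULL
    if (!is.null(spec$planted_pi) && spec$patches_per_frame > 0) {
      prid <- n_lip
      for (leaf in seq_len(geo$n_leaflets) - 1L) {
        lp <- leaf_pts[[leaf + 1]]
        accepted <- list()
        for (kp in seq_len(spec$patches_per_frame)) {
          a_drawn <- stats::rexp(1, 1 / spec$planted_pi)
          rt <- max(sqrt(a_drawn / base::pi), FIX_PATCH_RADIUS)
          # rejection sampling for disjoint centres
          placed <- FALSE
          for (try in 1:50) {
            ci <- sample.int(nrow(lp$p), 1)
            ok <- TRUE
            for (acc in accepted) {
              if (sqrt(sum((lp$p[ci, ] - lp$p[acc$ci, ])^2)) <
                  rt + acc$rt + 6) { ok <- FALSE; break }
            }
            if (ok) { placed <- TRUE; break }
          }
          if (!placed) next
          # tangent frame at the centre lipid
          n0 <- lp$n[ci, ]
          ref <- if (abs(n0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- ref - sum(ref * n0) * n0
          e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(n0[2] * e1[3] - n0[3] * e1[2],
                  n0[3] * e1[1] - n0[1] * e1[3],
                  n0[1] * e1[2] - n0[2] * e1[1])
          lay <- patch_bead_layout(rt)
          pb <- sweep(outer(lay[, 1], e1) + outer(lay[, 2], e2), 2,
                      lp$p[ci, ] + FIX_PATCH_RAISE * n0, "+")
          coords[[length(coords) + 1]] <- rbind(lp$p[ci, ], pb)
          bead[[length(bead) + 1]] <- c("PA", rep("PB", nrow(pb)))
          resn[[length(resn) + 1]] <- rep("PTCH", nrow(pb) + 1)
          resid[[length(resid) + 1]] <- rep(prid, nrow(pb) + 1)
          # interior: the whole disc stays clear of the periodic param seam
          interior <- if (!is.null(geo$interior)) {
            u <- lp$u[ci]; v <- lp$v[ci]
            geo$interior(u, v, rt)
          } else TRUE
          dom <- if (!is.null(geo$domain_of)) geo$domain_of(lp$u[ci])
                 else "J0"
          accepted[[length(accepted) + 1]] <- list(ci = ci, rt = rt)
          patches <- rbind(patches, data.frame(
            frame = fi, leaflet = leaf, residue_id = prid,
            area_drawn = a_drawn, area_target = base::pi * rt^2,
            interior = interior, domain = dom,
            cx = lp$p[ci, 1], cy = lp$p[ci, 2], cz = lp$p[ci, 3]))
          prid <- prid + 1L
        }
      }
    }
    xyz <- do.call(rbind, coords)
    xyz <- sweep(xyz, 2, geo$box, function(x, L) x - L * floor(x / L))
    snap <- cg_snapshot(xyz, unlist(bead), unlist(resn), unlist(resid),
                        geo$box, frame_index = fi)
    list(snap = snap, patches = patches)
  }

  frames <- vector("list", n_frames)
  patch_truth <- NULL
  if (vary_frames) {
    for (fi in seq_len(n_frames)) {
      fr <- make_frame(fi - 1L)
      frames[[fi]] <- fr$snap
      patch_truth <- rbind(patch_truth, fr$patches)
    }
  } else {
    fr <- make_frame(0L)
    for (fi in seq_len(n_frames)) {
      frames[[fi]] <- fr$snap
      frames[[fi]]$frame_index <- fi - 1L
      if (!is.null(fr$patches)) {
        pp <- fr$patches
        pp$frame <- fi - 1L
        patch_truth <- rbind(patch_truth, pp)
      }
    }
  }
  list(frames = frames,
       truth = list(patches = patch_truth,
                    lipids = data.frame(residue_id = seq_len(n_lip) - 1L,
                                        leaflet = lip_leaf,
                                        type = lip_type)),
       ff = ff)
}

#' Square-grid reference defect analysis for quasi-planar membranes
#'
#' An independent implementation of the same defect rules on a regular
#' square lattice with orthogonal projection (the cubic-mesh convention of
#' the established planar tool): cells within a bead's van der Waals radius
#' of its (x, y) position are touched, the most solvent-proximal bead wins,
#' d_type follows [classify_bead()], defect cells are clustered with
#' 8-connectivity (cells sharing an edge or corner), and clusters touching
#' the grid edge are removed. So that the triangular-vs-square comparison
#' isolates the tiling (and not the censoring location), the grid edges are
#' anchored to the antipode of the leaflet's lateral circular mean -- the
#' same data-anchored cut the triangulated path uses for its open seam.
#' Used as the mesh-equivalence oracle.
#'
#' @param snapshot a quasi-planar [cg_snapshot()].
#' @param ff force-field specification.
#' @param cell grid cell size in Angstrom.
#' @param leaflet `"upper"` or `"lower"` (split by anchor height).
#' @param kind defect kind as in [cluster_defects()].
#' @param deep_threshold shallow/deep split depth.
#' @return data.frame with `frame`, `leaflet`, `kind`, `area` per surviving
#'   cluster.
#' @export
reference_grid_defects <- function(snapshot, ff, cell = 1,
                                   leaflet = "upper", kind = "overall",
                                   deep_threshold = 4.5) {
  ids <- snapshot_residues(snapshot)
  anchors <- bead_positions(snapshot, ids, ff, "anchor")
  zmid <- mean(range(anchors[, 3]))
  upper <- leaflet == "upper"
  sel_ids <- ids[if (upper) anchors[, 3] > zmid else anchors[, 3] <= zmid]
  az <- anchors[match(sel_ids, ids), 3]
  if (stats::sd(az) > 5) {
    stop("reference_grid_defects requires a quasi-planar leaflet ",
         "(anchor height spread too large)")
  }
  rows <- which(snapshot$residue_id %in% sel_ids)
  sub <- snapshot_subset(snapshot, rows)
  # shift laterally so the grid edge (the censoring cut) sits at the
  # antipode of the leaflet's anchor circular mean, mirroring the mesh path
  box <- snapshot$box
  la <- anchors[match(sel_ids, ids), 1:2, drop = FALSE]
  ang <- sweep(la, 2, 2 * pi / box[1:2], "*")
  cmx <- atan2(colMeans(sin(ang)), colMeans(cos(ang))) * box[1:2] / (2 * pi)
  cut <- (cmx + box[1:2] / 2) %% box[1:2]
  sub$coords[, 1:2] <- sweep(sub$coords[, 1:2, drop = FALSE], 2, cut)
  sub$coords[, 1:2] <- sweep(sub$coords[, 1:2, drop = FALSE], 2, box[1:2],
                             function(x, L) x - L * floor(x / L))
  bt <- ff_bead_table(ff, sub$residue_name, sub$bead_name)
  refs <- bead_positions(snapshot, sel_ids, ff, "reference")
  refz <- refs[match(sub$residue_id, sel_ids), 3]
  sgn <- if (upper) 1 else -1
  depth <- sgn * (refz - sub$coords[, 3])
  dval <- classify_bead(bt$class, depth, deep_threshold)
  height <- sgn * sub$coords[, 3]

  nx <- max(4L, round(box[1] / cell))
  ny <- max(4L, round(box[2] / cell))
  csx <- box[1] / nx
  csy <- box[2] / ny

  # candidate (cell, bead) pairs by brute stencil per bead
  span <- ceiling(max(bt$radius) / min(csx, csy)) + 1L
  st <- expand.grid(di = -span:span, dj = -span:span)
  nb <- nrow(sub$coords)
  bi <- rep(seq_len(nb), each = nrow(st))
  ci <- floor(sub$coords[bi, 1] / csx) + rep(st$di, nb)
  cj <- floor(sub$coords[bi, 2] / csy) + rep(st$dj, nb)
  inside <- ci >= 0 & ci < nx & cj >= 0 & cj < ny
  bi <- bi[inside]; ci <- ci[inside]; cj <- cj[inside]
  cxc <- (ci + 0.5) * csx
  cyc <- (cj + 0.5) * csy
  hit <- (cxc - sub$coords[bi, 1])^2 + (cyc - sub$coords[bi, 2])^2 <=
    bt$radius[bi]^2
  bi <- bi[hit]; ci <- ci[hit]; cj <- cj[hit]
  if (!length(bi)) {
    return(data.frame(frame = integer(), leaflet = character(),
                      kind = character(), area = numeric()))
  }
  cellid <- cj * nx + ci
  ord <- order(cellid, -height[bi], bt$radius[bi], sub$residue_id[bi])
  first <- !duplicated(cellid[ord])
  win_cell <- cellid[ord][first]
  win_bead <- bi[ord][first]
  d <- dval[win_bead]

  member <- switch(kind,
    overall = d < 1, deep = d == 0, shallow = d == 0.001)
  mc <- win_cell[member]
  if (!length(mc)) {
    return(data.frame(frame = integer(), leaflet = character(),
                      kind = character(), area = numeric()))
  }
  # 8-connectivity clustering over defect cells
  mi <- mc %% nx
  mj <- mc %/% nx
  idx <- seq_along(mc)
  edges <- NULL
  key <- mj * nx + mi
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  for (srow in seq_len(nrow(shifts))) {
    ni <- mi + shifts$di[srow]
    nj <- mj + shifts$dj[srow]
    valid <- ni >= 0 & ni < nx & nj >= 0 & nj < ny
    nk <- nj * nx + ni
    hitn <- match(nk, key)
    ok <- valid & !is.na(hitn)
    if (any(ok)) edges <- rbind(edges, cbind(idx[ok], hitn[ok]))
  }
  g <- igraph::make_empty_graph(n = length(mc), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  on_edge <- mi == 0 | mi == nx - 1 | mj == 0 | mj == ny - 1
  bad <- unique(memb[on_edge])
  counts <- table(memb)
  keep <- setdiff(as.integer(names(counts)), bad)
  if (!length(keep)) {
    return(data.frame(frame = integer(), leaflet = character(),
                      kind = character(), area = numeric()))
  }
  areas <- as.numeric(counts[as.character(keep)]) * csx * csy
  data.frame(frame = snapshot$frame_index, leaflet = leaflet, kind = kind,
             area = areas)
}
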