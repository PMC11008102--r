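#' Load a force-field descriptor
#'
#' Reads a YAML descriptor with one stanza per lipid residue type, giving the
#' anchor bead used as the lipid's point position for surface reconstruction
#' (the glycerol-backbone bead, e.g. \code{GL2}), the reference bead defining
#' the depth origin for defect classification, a bead table with van der
#' Waals radii (in Angstrom) and chemical class (\code{polar} or
#' \code{aliphatic}), and the list of tail beads.
#'
#' Descriptor format, per residue:
#' \preformatted{
#' DPPC:
#'   anchor: GL2
#'   reference: GL2
#'   beads:
#'     NC3: {radius: 2.64, class: polar}
#'     C1A: {radius: 2.64, class: aliphatic}
#'   tails: [C1A, C2A]
#' }
#'
#' Radii are force-field specific; the bundled example descriptor
#' (\code{system.file("extdata", "martini_lipids.yaml", package =
#' "defectmesh")}) carries approximate Martini-style values for
#' DPPC/POPC/DLiPC/cholesterol.
#'
#' @param path path to the YAML descriptor file.
#' @return A \code{forcefield_spec} object: a named list of residue
#'   descriptions, each with \code{anchor_bead}, \code{reference_bead},
#'   \code{beads} (data.frame \code{bead}, \code{radius}, \code{class}) and
#'   \code{tail_beads}.
#' @export
load_forcefield <- function(path) {
  if (!file.exists(path)) stop("force-field descriptor not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty force-field descriptor: ", path)
  residues <- lapply(names(raw), function(res) {
    st <- raw[[res]]
    for (field in c("anchor", "reference", "beads", "tails")) {
      if (is.null(st[[field]])) {
        stop("residue ", res, ": descriptor is missing the '", field,
             "' field")
      }
    }
    beads <- data.frame(
      bead = names(st$beads),
      radius = vapply(st$beads, function(b) as.numeric(b$radius), 0),
      class = vapply(st$beads, function(b) as.character(b$class), ""),
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (any(!is.finite(beads$radius)) || any(beads$radius <= 0)) {
      stop("residue ", res, ": all bead radii must be positive")
    }
    bad <- setdiff(beads$class, c("polar", "aliphatic"))
    if (length(bad)) {
      stop("residue ", res, ": unknown chemical class '", bad[1],
           "' (expected polar or aliphatic)")
    }
    if (!st$anchor %in% beads$bead) {
      stop("residue ", res, ": anchor bead '", st$anchor,
           "' is not in the bead table")
    }
    if (!st$reference %in% beads$bead) {
      stop("residue ", res, ": reference bead '", st$reference,
           "' is not in the bead table")
    }
    tails <- as.character(unlist(st$tails))
    if (!length(tails)) stop("residue ", res, ": tail bead list is empty")
    missing_tails <- setdiff(tails, beads$bead)
    if (length(missing_tails)) {
      stop("residue ", res, ": tail bead '", missing_tails[1],
           "' is not in the bead table")
    }
    list(anchor_bead = st$anchor, reference_bead = st$reference,
         beads = beads, tail_beads = tails)
  })
  names(residues) <- names(raw)
  structure(list(residues = residues), class = "forcefield_spec")
}

#' @export
print.forcefield_spec <- function(x, ...) {
  cat("<forcefield_spec>", length(x$residues), "residue type(s):",
      paste(names(x$residues), collapse = ", "), "\n")
  invisible(x)
}

#' Build a force-field specification in code
#'
#' Programmatic constructor used by the synthetic fixture generator and
#' tests; validates the same invariants as [load_forcefield()].
#'
#' @param residues named list; each element a list with `anchor_bead`,
#'   `reference_bead`, `beads` (data.frame `bead`, `radius`, `class`) and
#'   `tail_beads`.
#' @return a `forcefield_spec`.
#' @export
forcefield_spec <- function(residues) {
  for (res in names(residues)) {
    r <- residues[[res]]
    stopifnot(is.data.frame(r$beads))
    if (any(r$beads$radius <= 0)) {
      stop("residue ", res, ": all bead radii must be positive")
    }
    if (!r$anchor_bead %in% r$beads$bead) {
      stop("residue ", res, ": anchor bead missing from bead table")
    }
    if (!r$reference_bead %in% r$beads$bead) {
      stop("residue ", res, ": reference bead missing from bead table")
    }
    if (!length(r$tail_beads)) stop("residue ", res, ": tail beads empty")
  }
  structure(list(residues = residues), class = "forcefield_spec")
}

#' Write a force-field specification to a YAML descriptor
#'
#' @param ff a `forcefield_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "forcefield_spec"))
  out <- lapply(ff$residues, function(r) {
    beads <- lapply(seq_len(nrow(r$beads)), function(i) {
      list(radius = r$beads$radius[i], class = r$beads$class[i])
    })
    names(beads) <- r$beads$bead
    list(anchor = r$anchor_bead, reference = r$reference_bead,
         beads = beads, tails = as.list(r$tail_beads))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# (residue, bead) lookup helpers ---------------------------------------------

ff_residue <- function(ff, resname) {
  r <- ff$residues[[resname]]
  if (is.null(r)) stop("residue '", resname,
                       "' is not described by the force field")
  r
}

# vectorised per-bead radius/class lookup; errors on unknown residue or bead
ff_bead_table <- function(ff, resnames, beadnames) {
  key <- paste(resnames, beadnames)
  all_tab <- do.call(rbind, lapply(names(ff$residues), function(res) {
    b <- ff$residues[[res]]$beads
    data.frame(key = paste(res, b$bead), radius = b$radius, class = b$class,
               stringsAsFactors = FALSE)
  }))
  # duplicated bead names within a residue: keep first occurrence
  all_tab <- all_tab[!duplicated(all_tab$key), ]
  idx <- match(key, all_tab$key)
  if (anyNA(idx)) {
    miss <- key[which(is.na(idx))[1]]
    stop("bead not described by force field: ", miss)
  }
  data.frame(radius = all_tab$radius[idx], class = all_tab$class[idx],
             stringsAsFactors = FALSE)
}
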