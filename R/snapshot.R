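#' Coarse-grained membrane snapshot
#'
#' A single frame of bead coordinates with residue/bead metadata and an
#' orthorhombic box. Coordinates and box lengths are in Angstrom throughout
#' the package (GRO files, which are in nm, are converted on load).
#'
#' @param coords numeric N x 3 matrix of bead coordinates (Angstrom).
#' @param bead_name character vector of bead names, length N.
#' @param residue_name character vector of residue names, length N.
#' @param residue_id integer vector grouping beads into lipids (0-based,
#'   contiguous per lipid), length N.
#' @param box numeric length-3 orthorhombic box lengths (Angstrom).
#' @param frame_index 0-based frame index.
#' @return a `cg_snapshot` object.
#' @export
cg_snapshot <- function(coords, bead_name, residue_name, residue_id, box,
                        frame_index = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3, length(bead_name) == n,
            length(residue_name) == n, length(residue_id) == n,
            length(box) == 3)
  if (!all(is.finite(coords))) stop("snapshot coordinates must be finite")
  if (any(box <= 0)) stop("box lengths must be positive")
  structure(
    list(coords = coords, bead_name = as.character(bead_name),
         residue_name = as.character(residue_name),
         residue_id = as.integer(residue_id), box = as.numeric(box),
         frame_index = as.integer(frame_index)),
    class = "cg_snapshot"
  )
}

#' @export
print.cg_snapshot <- function(x, ...) {
  cat(sprintf("<cg_snapshot> frame %d: %d beads, %d residues, box %.1f x %.1f x %.1f A\n",
              x$frame_index, nrow(x$coords), length(unique(x$residue_id)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# unique residue ids in order of first appearance
snapshot_residues <- function(snapshot) {
  unique(snapshot$residue_id)
}

# first index of each residue id (assumes contiguous grouping)
residue_first_index <- function(snapshot, ids) {
  match(ids, snapshot$residue_id)
}

# residue_name per residue id
residue_names <- function(snapshot, ids) {
  snapshot$residue_name[match(ids, snapshot$residue_id)]
}

# index rows of a snapshot
snapshot_subset <- function(snapshot, rows) {
  cg_snapshot(snapshot$coords[rows, , drop = FALSE],
              snapshot$bead_name[rows], snapshot$residue_name[rows],
              snapshot$residue_id[rows], snapshot$box, snapshot$frame_index)
}

# positions of a named bead for a set of residue ids; first occurrence per
# residue wins (duplicated bead names are legal in fixtures)
bead_positions <- function(snapshot, ids, ff, which = c("anchor", "reference")) {
  which <- match.arg(which)
  rn <- residue_names(snapshot, ids)
  target <- vapply(rn, function(r) {
    res <- ff_residue(ff, r)
    if (which == "anchor") res$anchor_bead else res$reference_bead
  }, "")
  key <- paste(snapshot$residue_id, snapshot$bead_name)
  idx <- match(paste(ids, target), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("residue ", ids[bad], " (", rn[bad], ") has no ", which,
         " bead '", target[bad], "'")
  }
  snapshot$coords[idx, , drop = FALSE]
}

# minimum-image displacement a - b under an orthorhombic box
min_image <- function(d, box) {
  for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  d
}
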