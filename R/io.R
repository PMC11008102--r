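NM_TO_A <- 10

#' Read a GRO structure file (single or multi-frame)
#'
#' GROMACS GRO coordinates are in nm; they are converted to Angstrom on load.
#' Concatenated frames in one file are returned as a list of snapshots.
#' Velocities, if present, are ignored.
#'
#' @param path path to a .gro file.
#' @return a list of `cg_snapshot` objects (one per frame).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("GRO file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  fi <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    if (pos + 1L > length(lines)) stop("truncated GRO file: ", path)
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms) || natoms <= 0) {
      stop("GRO frame at line ", pos, ": invalid atom count")
    }
    atom_lines <- lines[(pos + 2L):(pos + 1L + natoms)]
    if (length(atom_lines) < natoms || anyNA(atom_lines)) {
      stop("truncated GRO frame at line ", pos)
    }
    box_line <- lines[pos + 2L + natoms]
    resid_file <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    beadname <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("GRO frame at line ", pos, ": unreadable coordinates")
    }
    box <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1:3]
    # residue ids restart at 1 and wrap at 99999: rebuild by change points
    change <- c(TRUE, resid_file[-1] != resid_file[-natoms] |
                  resname[-1] != resname[-natoms])
    rid <- cumsum(change) - 1L
    snap <- cg_snapshot(cbind(x, y, z) * NM_TO_A, beadname, resname, rid,
                        box * NM_TO_A, frame_index = fi)
    snap$residue_id_file <- resid_file
    frames[[fi + 1L]] <- snap
    pos <- pos + 3L + natoms
    fi <- fi + 1L
  }
  if (!length(frames)) stop("no frames found in GRO file: ", path)
  frames
}

#' Write snapshots to a GRO file
#'
#' @param snapshots a `cg_snapshot` or list of them (frames are concatenated).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(snapshots, path) {
  if (inherits(snapshots, "cg_snapshot")) snapshots <- list(snapshots)
  con <- file(path, "w")
  on.exit(close(con))
  for (snap in snapshots) {
    n <- nrow(snap$coords)
    resid <- (snap$residue_id %% 99999L) + 1L
    atomid <- (seq_len(n) - 1L) %% 99999L + 1L
    writeLines(sprintf("frame %d", snap$frame_index), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, substr(snap$residue_name, 1, 5),
                       substr(snap$bead_name, 1, 5), atomid,
                       snap$coords[, 1] / NM_TO_A,
                       snap$coords[, 2] / NM_TO_A,
                       snap$coords[, 3] / NM_TO_A), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", snap$box[1] / NM_TO_A,
                       snap$box[2] / NM_TO_A, snap$box[3] / NM_TO_A), con)
  }
  invisible(path)
}

read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  at <- pdb$atom
  box <- if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3) {
    as.numeric(pdb$cryst1$abc)
  } else {
    apply(xyz, 2, function(v) diff(range(v))) + 20
  }
  change <- c(TRUE, at$resno[-1] != at$resno[-nrow(at)] |
                at$resid[-1] != at$resid[-nrow(at)])
  rid <- cumsum(change) - 1L
  snap <- cg_snapshot(xyz, trimws(at$elety), trimws(at$resid), rid, box, 0L)
  snap$residue_id_file <- at$resno
  snap
}

#' Load trajectory frames
#'
#' Reads a topology (GRO or PDB) and optionally a trajectory (multi-frame GRO
#' or DCD), returning a list of [cg_snapshot()] frames in trajectory order.
#' A topology alone yields a single frame. All coordinates are in Angstrom.
#'
#' @param topology path to a GRO or PDB file.
#' @param trajectory optional path to a multi-frame GRO or DCD file.
#' @param begin,end 0-based first/last frame to keep (inclusive; `end = NULL`
#'   keeps to the last frame).
#' @param stride keep every `stride`-th frame.
#' @return list of `cg_snapshot` objects with `frame_index` set to the
#'   original trajectory frame numbers.
#' @export
load_frames <- function(topology, trajectory = NULL, begin = 0L, end = NULL,
                        stride = 1L) {
  ext <- tolower(tools::file_ext(topology))
  top <- switch(ext,
    gro = read_gro(topology)[[1]],
    pdb = read_pdb_topology(topology),
    stop("unsupported topology format: .", ext)
  )
  frames <- list(top)
  if (!is.null(trajectory)) {
    text <- tolower(tools::file_ext(trajectory))
    if (text %in% c("xtc", "trr")) {
      stop("unsupported trajectory format: .", text,
           " (supported: multi-frame GRO, DCD)")
    }
    if (text == "gro") {
      frames <- read_gro(trajectory)
      nb <- vapply(frames, function(s) nrow(s$coords), 0L)
      if (any(nb != nrow(top$coords))) {
        stop("bead count mismatch between topology (", nrow(top$coords),
             ") and trajectory frame (", nb[which(nb != nrow(top$coords))[1]],
             ")")
      }
      for (i in seq_along(frames)) {
        frames[[i]]$bead_name <- top$bead_name
        frames[[i]]$residue_name <- top$residue_name
        frames[[i]]$residue_id <- top$residue_id
      }
    } else if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
      if (ncol(xyz) != 3L * nrow(top$coords)) {
        stop("bead count mismatch between topology (", nrow(top$coords),
             ") and trajectory frame (", ncol(xyz) / 3, ")")
      }
      frames <- lapply(seq_len(nrow(xyz)), function(i) {
        cg_snapshot(matrix(xyz[i, ], ncol = 3, byrow = TRUE), top$bead_name,
                    top$residue_name, top$residue_id, top$box, i - 1L)
      })
    } else {
      stop("unsupported trajectory format: .", text)
    }
  }
  for (i in seq_along(frames)) frames[[i]]$frame_index <- i - 1L
  nf <- length(frames)
  if (is.null(end)) end <- nf - 1L
  if (begin > min(end, nf - 1L)) stop("frame selection is empty")
  keep <- seq(begin, min(end, nf - 1L), by = stride)
  frames[keep + 1L]
}
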