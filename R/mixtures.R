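#' Concentration-normalized lipid contact fraction
#'
#' For every lipid of `type_a`, neighbours are all other lipids whose anchor
#' beads lie within `cutoff` (minimum image); the fraction of `type_b` among
#' those neighbours, averaged over the `type_a` lipids, is normalized by the
#' global number fraction of `type_b` among potential neighbours. This makes
#' phi = 1 under ideal mixing and phi -> 0 for complete demixing. The
#' default cutoff is the standard 11 Angstrom (1.1 nm) contact distance.
#'
#' @param frames a `cg_snapshot` or list of them.
#' @param ff force-field specification.
#' @param type_a,type_b residue names of the two lipid types (may be equal).
#' @param cutoff contact cutoff in Angstrom.
#' @return a `contact_fraction` object: list with `phi` (mean over frames),
#'   `per_frame`, `cutoff` and the type pair.
#' @export
contact_fraction <- function(frames, ff, type_a, type_b, cutoff = 11) {
  if (inherits(frames, "cg_snapshot")) frames <- list(frames)
  stopifnot(cutoff > 0)
  per_frame <- vapply(frames, function(snap) {
    ids <- snapshot_residues(snap)
    rn <- residue_names(snap, ids)
    if (!any(rn == type_a)) stop("no lipids of type ", type_a)
    if (!any(rn == type_b)) stop("no lipids of type ", type_b)
    anchors <- bead_positions(snap, ids, ff, "anchor")
    pairs <- cpp_pairs_within(anchors, cutoff, snap$box)
    n <- length(ids)
    nb_tot <- numeric(n)
    nb_b <- numeric(n)
    isb <- rn == type_b
    for (col in 1:2) {
      i <- pairs[, col]
      j <- pairs[, 3 - col]
      acc <- rowsum(rep(1, length(i)), i)
      nb_tot[as.integer(rownames(acc))] <- nb_tot[as.integer(rownames(acc))] +
        acc[, 1]
      accb <- rowsum(as.numeric(isb[j]), i)
      nb_b[as.integer(rownames(accb))] <- nb_b[as.integer(rownames(accb))] +
        accb[, 1]
    }
    a_idx <- which(rn == type_a & nb_tot > 0)
    if (!length(a_idx)) return(NA_real_)
    frac <- mean(nb_b[a_idx] / nb_tot[a_idx])
    n_b <- sum(isb)
    expect <- (n_b - as.integer(type_a == type_b)) / (n - 1)
    frac / expect
  }, 0)
  structure(list(phi = mean(per_frame, na.rm = TRUE), per_frame = per_frame,
                 cutoff = cutoff, type_a = type_a, type_b = type_b),
            class = "contact_fraction")
}

#' @export
print.contact_fraction <- function(x, ...) {
  cat(sprintf("phi(%s -> %s) = %.3f (cutoff %.1f A, %d frame(s))\n",
              x$type_a, x$type_b, x$phi, x$cutoff, length(x$per_frame)))
  invisible(x)
}

#' Predict a mixture defect constant by superposition
#'
#' Lipid packing defects are local and noninteracting, so the defect
#' constant of a mixed membrane follows from the pure-component constants.
#' The mixture defect-size density is the fraction-weighted superposition of
#' the component exponentials (equal per-component normalization), and the
#' effective single-exponential constant is matched at a reference area `A0`
#' chosen inside the validity window of the component fits:
#' \deqn{\pi_3 = \frac{\sum_i f_i w_i}{\sum_i f_i w_i / \pi_i}, \quad
#'       w_i = e^{-A_0/\pi_i}}
#' i.e. the inverse local log-slope of the mixture density at `A0`. The
#' result is continuous and monotone in the fractions and always lies
#' between the component constants. Two components are the validated setup;
#' more components are composed pairwise and flagged experimental.
#'
#' @param pi_components numeric vector of pure-system defect constants
#'   (square Angstrom), length >= 2.
#' @param fractions number fractions summing to 1.
#' @param a0 reference area in square Angstrom (default 50).
#' @return the predicted defect constant (square Angstrom).
#' @export
predict_pi_mixture <- function(pi_components, fractions, a0 = 50) {
  stopifnot(length(pi_components) == length(fractions),
            length(pi_components) >= 2)
  if (any(!is.finite(pi_components)) || any(pi_components <= 0)) {
    stop("all component defect constants must be positive")
  }
  if (any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (a0 <= 0) stop("a0 must be positive")
  two <- function(p1, p2, f1, f2) {
    w1 <- exp(-a0 / p1)
    w2 <- exp(-a0 / p2)
    (f1 * w1 + f2 * w2) / (f1 * w1 / p1 + f2 * w2 / p2)
  }
  if (length(pi_components) == 2) {
    return(two(pi_components[1], pi_components[2], fractions[1],
               fractions[2]))
  }
  warning("more than 2 components: composing pairwise (experimental)")
  p <- pi_components[1]
  f <- fractions[1]
  for (i in 2:length(pi_components)) {
    ftot <- f + fractions[i]
    if (ftot <= 0) next
    p <- two(p, pi_components[i], f / ftot, fractions[i] / ftot)
    f <- ftot
  }
  p
}
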