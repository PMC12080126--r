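# Per-residue and per-region structural analytics over weighted ensembles.
# Coordinates are handled internally in Angstrom; reported fluctuation,
# gyration and distance values are in nanometres to match the scales
# usual for disordered-protein ensembles.

# Representative coordinate per residue: the CA atom when present,
# otherwise the first atom of the residue.
residue_coords <- function(conf, residues = NULL) {
  ids <- unique(conf$resid)
  if (is.null(residues)) residues <- ids
  missing <- setdiff(residues, ids)
  if (length(missing) > 0L) {
    stop("residues absent from conformation: ",
         paste(missing, collapse = ", "))
  }
  idx <- vapply(residues, function(r) {
    at <- which(conf$resid == r)
    ca <- at[conf$atom_name[at] == "CA"]
    if (length(ca) > 0L) ca[1L] else at[1L]
  }, integer(1))
  out <- conf$xyz[idx, , drop = FALSE]
  rownames(out) <- residues
  out
}

# Weighted Kabsch superposition of `mobile` onto `target` (both n x 3).
# Returns the transformed mobile coordinates.
kabsch_superpose <- function(mobile, target, w = NULL) {
  n <- nrow(mobile)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(target, 2L, ct)
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(a %*% t(rot), 2L, ct, "+")
}

#' Weighted root-mean-square fluctuation per residue
#'
#' RMSF of each residue's representative (CA) position about the
#' weighted mean position across the ensemble, using the frame weights.
#' Superposition of every frame onto the weighted mean structure prior
#' to the fluctuation calculation is optional and off by default, which
#' is the appropriate convention for highly disordered chains whose
#' global tumbling is itself of interest.
#'
#' @param ensemble a [structural_ensemble()] with at least two frames.
#' @param selection residue ids to report (default: all residues).
#' @param superpose logical; least-squares superpose each frame onto the
#'   weighted mean structure (two refinement passes) before measuring
#'   fluctuations.
#' @return named numeric vector of per-residue RMSF in nm.
#' @export
residue_rmsf <- function(ensemble, selection = NULL, superpose = FALSE) {
  if (length(ensemble$frames) < 2L) {
    stop("RMSF requires an ensemble with at least two frames")
  }
  all_ids <- unique(ensemble$frames[[1L]]$resid)
  if (is.null(selection)) selection <- all_ids
  if (length(selection) == 0L) stop("empty residue selection")
  coords <- lapply(ensemble$frames, residue_coords, residues = selection)
  w <- ensemble$weights
  wmean <- function(cs) Reduce(`+`, Map(`*`, cs, w))
  if (superpose) {
    for (pass in 1:2) {
      ref <- wmean(coords)
      coords <- lapply(coords, kabsch_superpose, target = ref)
    }
  }
  mu <- wmean(coords)
  msf <- Reduce(`+`, Map(function(c, wi) wi * rowSums((c - mu)^2),
                         coords, w))
  out <- sqrt(msf) * ANG_TO_NM
  names(out) <- selection
  out
}

#' Mass-weighted radius of gyration
#'
#' @param conf a [conformation()].
#' @param selection residue ids to include (default all).
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(conf, selection = NULL) {
  if (is.null(selection)) selection <- unique(conf$resid)
  if (length(selection) == 0L) stop("empty residue selection")
  keep <- conf$resid %in% selection
  if (!any(keep)) stop("selection matches no atoms")
  xyz <- conf$xyz[keep, , drop = FALSE]
  m <- atomic_mass(conf$element[keep])
  m <- m / sum(m)
  cm <- colSums(xyz * m)
  sqrt(sum(m * rowSums(sweep(xyz, 2L, cm)^2))) * ANG_TO_NM
}

#' Minimum heavy-atom protein-ligand distance
#'
#' Exhaustive minimum over all protein-atom/ligand-atom pairs of one
#' conformation.
#'
#' @param conf a [conformation()] carrying a ligand block.
#' @return minimum distance in nm.
#' @export
min_ligand_distance <- function(conf) {
  if (is.null(conf$ligand) || nrow(conf$ligand$xyz) == 0L) {
    stop("conformation has no ligand block")
  }
  if (nrow(conf$xyz) == 0L) stop("conformation has no protein atoms")
  p <- conf$xyz
  l <- conf$ligand$xyz
  # |p - l|^2 = |p|^2 + |l|^2 - 2 p.l, vectorised over all pairs
  d2 <- outer(rowSums(p^2), rowSums(l^2), `+`) - 2 * p %*% t(l)
  sqrt(max(0, min(d2))) * ANG_TO_NM
}
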