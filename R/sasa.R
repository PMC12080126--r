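# Solvent-accessible surface area by sphere-point sampling
# (Shrake-Rupley).  Quasi-uniform test points are placed on each atom's
# solvent-expanded sphere; the accessible fraction is the fraction of
# points not buried inside any neighbouring expanded sphere.

# n quasi-uniform points on the unit sphere (Fibonacci / golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param element element symbol per atom (sets the van der Waals radius).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4,
#'   a water molecule).
#' @param n_sphere_points number of test points per atom (>= 32).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, element, probe_radius = 1.4,
                       n_sphere_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 32L) stop("n_sphere_points must be >= 32")
  radii <- vdw_radius(rep_len(element, n)) + probe_radius
  pts <- sphere_points(n_sphere_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    sep <- sweep(xyz, 2L, xyz[i, ])
    d2 <- rowSums(sep^2)
    nb <- which(d2 < (ri + radii)^2 & d2 > 0)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * ri^2
      next
    }
    surf <- pts * ri
    # buried if any neighbour sphere contains the surface point
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(surf[acc, , drop = FALSE], 2L, sep[j, ])
      acc[acc] <- rowSums(dj^2) >= radii[j]^2
    }
    out[i] <- 4 * pi * ri^2 * mean(acc)
  }
  out
}

#' Per-residue solvent-accessible surface area of a conformation
#'
#' Residue SASA is the sum of its atoms' SASA.
#'
#' @param conf a [conformation()].
#' @inheritParams sasa_atoms
#' @return named numeric vector (residue id -> SASA, Angstrom^2).
#' @export
sasa <- function(conf, probe_radius = 1.4, n_sphere_points = 960L) {
  per_atom <- sasa_atoms(conf$xyz, conf$element, probe_radius,
                         n_sphere_points)
  res <- tapply(per_atom, conf$resid, sum)
  out <- as.numeric(res)
  names(out) <- names(res)
  out
}

# Weighted-mean per-residue SASA across an ensemble.
ensemble_sasa <- function(ensemble, probe_radius = 1.4,
                          n_sphere_points = 960L) {
  per_frame <- lapply(ensemble$frames, sasa, probe_radius = probe_radius,
                      n_sphere_points = n_sphere_points)
  Reduce(`+`, Map(`*`, per_frame, ensemble$weights))
}

#' Holo/apo solvent-exposure ratio per region
#'
#' For each named region, computes the ratio of the weighted-mean region
#' SASA in the holo (ligand-bound) ensemble over the apo ensemble, plus
#' the unweighted mean ratio over regions.  Region SASA is the sum of
#' the weighted-mean per-residue SASA over the region's residues.
#' Ratios below 1 indicate solvent shielding of the region by the bound
#' ligand.
#'
#' @param holo,apo [structural_ensemble()] objects with identical residue
#'   numbering.
#' @param regions a [region_set()].
#' @inheritParams sasa_atoms
#' @return list with `ratios` (named per-region vector; NA where the apo
#'   region SASA is zero), `mean_ratio` (mean over defined ratios) and
#'   `excluded` (names of regions with zero apo SASA).
#' @export
region_sasa_ratio <- function(holo, apo, regions, probe_radius = 1.4,
                              n_sphere_points = 960L) {
  rh <- unique(holo$frames[[1L]]$resid)
  ra <- unique(apo$frames[[1L]]$resid)
  need <- unique(unlist(lapply(names(regions$regions),
                               region_residues, rs = regions)))
  if (!all(need %in% rh) || !all(need %in% ra)) {
    stop("all region residues must be present, with shared numbering, ",
         "in both the holo and apo ensembles")
  }
  sh <- ensemble_sasa(holo, probe_radius, n_sphere_points)
  sa <- ensemble_sasa(apo, probe_radius, n_sphere_points)
  ratios <- vapply(names(regions$regions), function(nm) {
    res <- as.character(region_residues(regions, nm))
    num <- sum(sh[res])
    den <- sum(sa[res])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  excluded <- names(ratios)[is.na(ratios)]
  if (length(excluded) > 0L) {
    warning("regions with zero apo SASA excluded from mean: ",
            paste(excluded, collapse = ", "))
  }
  list(ratios = ratios,
       mean_ratio = mean(ratios, na.rm = TRUE),
       excluded = excluded)
}

#' Write per-region SASA ratios as CSV
#'
#' @param ratio_result result of [region_sasa_ratio()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_ratios_csv <- function(ratio_result, path) {
  df <- data.frame(region = names(ratio_result$ratios),
                   sasa_ratio = as.numeric(ratio_result$ratios))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
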