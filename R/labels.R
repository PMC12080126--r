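# Percentile-based activity labelling of docking energies and
# multibinding hit-rate analysis.

#' Binarise an energy matrix into per-site activity labels
#'
#' For each site the threshold is set so that the compounds with the
#' lowest `percentile` percent of energies are labelled active: with n
#' non-missing energies, k = floor(n * percentile / 100) and the
#' threshold is the (k+1)-th lowest energy; a compound is active iff
#' its energy is strictly below the threshold.  On tie-free energies
#' with n divisible by 100/percentile this yields exactly
#' n * percentile / 100 actives per site; ties at the threshold are
#' inactive.  Missing energies give NA labels and are excluded from the
#' per-site denominators.
#'
#' @param energy compounds x sites numeric matrix (kcal/mol), NA for
#'   missing entries.
#' @param percentile active percentile in (0, 100) (default 5).
#' @param min_per_site minimum non-missing energies required per site.
#' @return object of class `label_matrix`: list with `labels` (0/1/NA
#'   integer matrix), `thresholds` (per-site, kcal/mol), `percentile`.
#' @export
build_labels <- function(energy, percentile = 5, min_per_site = 20L) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)")
  }
  energy <- as.matrix(unclass(energy))
  thresholds <- apply(energy, 2L, function(e) {
    ok <- e[!is.na(e)]
    n <- length(ok)
    if (n == 0L) stop("site with all energies missing")
    if (n < min_per_site) {
      stop(sprintf("site has %d energies; need >= %d", n, min_per_site))
    }
    k <- floor(n * percentile / 100)
    if (k >= n) return(Inf)
    sort(ok, partial = k + 1L)[k + 1L]
  })
  labels <- matrix(NA_integer_, nrow(energy), ncol(energy),
                   dimnames = dimnames(energy))
  for (s in seq_len(ncol(energy))) {
    e <- energy[, s]
    labels[!is.na(e), s] <- as.integer(e[!is.na(e)] < thresholds[s])
  }
  structure(list(labels = labels, thresholds = thresholds,
                 percentile = percentile),
            class = "label_matrix")
}

#' Multibinding hit histogram
#'
#' Counts, for each number of sites, the compounds active at exactly
#' that many sites, plus the number of compounds active at strictly
#' more than `min_sites` sites.
#'
#' @param labels a [build_labels()] result or a 0/1 matrix.
#' @param min_sites strict lower bound on the number of active sites.
#' @return list with `histogram` (named counts over 1..n_sites;
#'   compounds with zero active sites are not part of it), `n_above`
#'   (compounds active at > `min_sites` sites), `hit_rate` (`n_above`
#'   over all compounds), `min_sites`.
#' @export
multibinding_hit_histogram <- function(labels, min_sites = 30L) {
  m <- if (inherits(labels, "label_matrix")) labels$labels else labels
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L, NA))) stop("labels must be binary")
  rs <- rowSums(m == 1L, na.rm = TRUE)
  k <- ncol(m)
  hist <- vapply(seq_len(k), function(j) sum(rs == j), integer(1))
  names(hist) <- seq_len(k)
  list(histogram = hist,
       n_above = sum(rs > min_sites),
       hit_rate = sum(rs > min_sites) / nrow(m),
       min_sites = as.integer(min_sites))
}
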