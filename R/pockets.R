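# Binding-site selection: ingest detected cavities, apply the
# physicochemical and dynamics filters, cluster the surviving sites by
# residue sharing and emit docking boxes.
#
# Cavity detection itself is delegated to an external grid-based
# detector through an adapter; a fixture backend injects pre-specified
# cavities so the rest of the pipeline is testable without the detector.

#' Construct a cavity record
#'
#' @param frame_id ensemble frame index where the cavity was detected.
#' @param residues integer vector of residue ids lining the cavity.
#' @param volume cavity volume (Angstrom^3).
#' @param area cavity area (Angstrom^2).
#' @param avg_hydropathy mean Eisenberg-Weiss hydropathy of the lining
#'   residues; computed from `resnames` when omitted.
#' @param max_depth,avg_depth cavity depth statistics (Angstrom).
#' @param resnames optional three-letter residue names of the lining
#'   residues (used to compute hydropathy when not given).
#' @param cavity_id optional detector-assigned id.
#' @return object of class `cavity`.
#' @export
cavity <- function(frame_id, residues, volume, area,
                   avg_hydropathy = NULL, max_depth = 0, avg_depth = 0,
                   resnames = NULL, cavity_id = NULL) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L) stop("cavity residue set must be non-empty")
  if (volume < 0 || area < 0 || max_depth < 0 || avg_depth < 0) {
    stop("volume, area and depths must be >= 0")
  }
  if (is.null(avg_hydropathy)) {
    if (is.null(resnames)) stop("give avg_hydropathy or resnames")
    avg_hydropathy <- eisenberg_weiss_hydropathy(resnames)
  }
  structure(list(frame_id = as.integer(frame_id), residues = residues,
                 volume = volume, area = area,
                 max_depth = max_depth, avg_depth = avg_depth,
                 avg_hydropathy = avg_hydropathy,
                 resnames = resnames, cavity_id = cavity_id),
            class = "cavity")
}

#' Binding-site filter configuration
#'
#' Defaults follow the selection rules for sticky, hydrophobic,
#' reasonably large transient pockets: strictly more than
#' `min_residues` lining residues, mean hydropathy at or below
#' `max_hydropathy`, area within `area_bounds`, volume at least
#' `min_volume`, and mean residue RMSF strictly below `max_mean_rmsf`.
#'
#' @param min_residues residue-count threshold (strict >; default 5).
#' @param max_hydropathy upper hydropathy bound (default 0).
#' @param area_bounds lower/upper area bounds in Angstrom^2
#'   (default c(80, 2480), inclusive).
#' @param min_volume lower volume bound in Angstrom^3 (default 120,
#'   inclusive).
#' @param max_mean_rmsf upper bound on the mean RMSF of cavity residues
#'   (strict <; default 4.1, in the units of the supplied RMSF vector).
#' @param rmsf_statistic "mean" (default) or "max" over cavity residues.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_residues = 5L, max_hydropathy = 0,
                          area_bounds = c(80, 2480), min_volume = 120,
                          max_mean_rmsf = 4.1,
                          rmsf_statistic = c("mean", "max")) {
  if (length(area_bounds) != 2L || area_bounds[1L] > area_bounds[2L]) {
    stop("area_bounds must be an ordered pair")
  }
  stopifnot(is.finite(min_residues), is.finite(max_hydropathy),
            all(is.finite(area_bounds)), is.finite(min_volume),
            is.finite(max_mean_rmsf))
  structure(list(min_residues = as.integer(min_residues),
                 max_hydropathy = max_hydropathy,
                 area_bounds = area_bounds, min_volume = min_volume,
                 max_mean_rmsf = max_mean_rmsf,
                 rmsf_statistic = match.arg(rmsf_statistic)),
            class = "filter_config")
}

#' Detect cavities on a conformation (adapter)
#'
#' Contract around an external grid-based geometric cavity detector run
#' at its default parameters.  The "fixture" backend returns the
#' cavities supplied in `detector_config$cavities` (restricted to the
#' requested frame when they carry frame ids), so downstream stages can
#' be exercised without the external tool.
#'
#' @param conf a [conformation()] (may be NULL for the fixture backend).
#' @param detector_config list with `backend` ("fixture" or "kvfinder")
#'   and, for the fixture backend, `cavities` (list of [cavity()]).
#' @param frame_id frame index used to tag returned cavities.
#' @return list of [cavity()] objects.
#' @export
detect_cavities <- function(conf, detector_config = list(backend = "fixture"),
                            frame_id = 1L) {
  backend <- detector_config$backend %||% "fixture"
  if (backend == "fixture") {
    cavs <- detector_config$cavities %||% list()
    keep <- vapply(cavs, function(cv) {
      is.null(cv$frame_id) || cv$frame_id == frame_id
    }, logical(1))
    return(cavs[keep])
  }
  stop("cavity-detection backend '", backend, "' is not available here; ",
       "run the external grid detector separately and ingest its report ",
       "with read_cavities_csv(), or use the fixture backend")
}

site_stat <- function(values) c(mean = mean(values), max = max(values))

#' Filter cavities into binding sites
#'
#' A cavity passes when all conditions hold: strictly more than
#' `min_residues` lining residues; mean hydropathy <= `max_hydropathy`;
#' area within `area_bounds`; volume >= `min_volume`; and the RMSF
#' statistic over its residues strictly below `max_mean_rmsf`.
#' Site ids are assigned deterministically in (frame_id, input order).
#'
#' @param cavities list of [cavity()] objects.
#' @param rmsf named per-residue RMSF vector covering all cavity
#'   residues (same units as `config$max_mean_rmsf`).
#' @param config a [filter_config()].
#' @return list of `binding_site` objects (fields: `site_id`, `cavity`).
#' @export
filter_cavities <- function(cavities, rmsf, config = filter_config()) {
  if (length(cavities) == 0L) return(list())
  rmsf_ids <- as.integer(names(rmsf))
  need <- sort(unique(unlist(lapply(cavities, `[[`, "residues"))))
  missing <- setdiff(need, rmsf_ids)
  if (length(missing) > 0L) {
    stop("rmsf missing for residues: ", paste(missing, collapse = ", "))
  }
  pass <- vapply(cavities, function(cv) {
    stat <- site_stat(rmsf[match(cv$residues, rmsf_ids)])[
      config$rmsf_statistic]
    length(cv$residues) > config$min_residues &&
      cv$avg_hydropathy <= config$max_hydropathy &&
      cv$area >= config$area_bounds[1L] &&
      cv$area <= config$area_bounds[2L] &&
      cv$volume >= config$min_volume &&
      stat < config$max_mean_rmsf
  }, logical(1))
  kept <- cavities[pass]
  ord <- order(vapply(kept, `[[`, integer(1), "frame_id"),
               seq_along(kept))
  kept <- kept[ord]
  lapply(seq_along(kept), function(k) {
    structure(list(site_id = k - 1L, cavity = kept[[k]]),
              class = "binding_site")
  })
}

#' Cluster binding sites by residue sharing
#'
#' Sites are connected when their residue-set overlap exceeds the
#' threshold; clusters are the connected components (single linkage).
#' Overlap is the overlap coefficient |A n B| / min(|A|, |B|) by
#' default, which is tolerant to nested pockets of unequal size;
#' Jaccard |A n B| / |A u B| is available as an alternative.
#'
#' @param sites list of `binding_site` (or [cavity()]) objects.
#' @param overlap_threshold sharing threshold in (0, 1\] (strict >;
#'   default 0.6).
#' @param method "overlap" (default) or "jaccard".
#' @return object of class `site_cluster_set`: list with `clusters`
#'   (list of site-id vectors, largest first), `membership` (named
#'   vector site_id -> cluster index) and the threshold/method used.
#' @export
cluster_sites <- function(sites, overlap_threshold = 0.6,
                          method = c("overlap", "jaccard")) {
  if (length(sites) == 0L) stop("at least one site required")
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stop("overlap_threshold must lie in (0, 1]")
  }
  method <- match.arg(method)
  res_sets <- lapply(sites, function(s) {
    if (inherits(s, "binding_site")) s$cavity$residues else s$residues
  })
  ids <- vapply(seq_along(sites), function(k) {
    s <- sites[[k]]
    if (inherits(s, "binding_site")) s$site_id else k - 1L
  }, integer(1))
  n <- length(sites)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      inter <- length(intersect(res_sets[[a]], res_sets[[b]]))
      denom <- switch(method,
        overlap = min(length(res_sets[[a]]), length(res_sets[[b]])),
        jaccard = length(union(res_sets[[a]], res_sets[[b]])))
      adj[a, b] <- adj[b, a] <- (inter / denom) > overlap_threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, numeric(1)))]
  names(clusters) <- NULL
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[match(clusters[[k]], ids)] <- k
  names(membership) <- ids
  structure(list(clusters = clusters, membership = membership,
                 overlap_threshold = overlap_threshold, method = method),
            class = "site_cluster_set")
}

#' @export
print.site_cluster_set <- function(x, ...) {
  multi <- sum(lengths(x$clusters) > 1L)
  cat(sprintf(
    "site_cluster_set: %d clusters (%d multi-member, %d singleton) at %s > %g\n",
    length(x$clusters), multi, length(x$clusters) - multi,
    x$method, x$overlap_threshold))
  invisible(x)
}

#' Docking box around a binding site
#'
#' Axis-aligned bounding box of the cavity residues' representative (CA)
#' coordinates, expanded by `padding` on every side.
#'
#' @param site a `binding_site` (or [cavity()]) object.
#' @param conf the [conformation()] providing coordinates (typically the
#'   frame the cavity was detected on).
#' @param padding box padding in Angstrom (default 5).
#' @return object of class `docking_box`: list with `center` (xyz,
#'   Angstrom) and `size` (edge lengths, Angstrom).
#' @export
site_to_box <- function(site, conf, padding = 5) {
  residues <- if (inherits(site, "binding_site")) site$cavity$residues
              else site$residues
  coords <- residue_coords(conf, residues)
  lo <- apply(coords, 2L, min) - padding
  hi <- apply(coords, 2L, max) + padding
  size <- hi - lo
  if (any(size <= 0)) {
    warning("degenerate docking box (zero edge); increase padding")
  }
  structure(list(center = unname((lo + hi) / 2), size = unname(size),
                 site_id = if (inherits(site, "binding_site")) site$site_id
                           else NA_integer_),
            class = "docking_box")
}

# ---------------------------------------------------------------- I/O --

#' Read cavity records from CSV
#'
#' Expected columns: `frame_id`, `residues` (';'-separated ids),
#' `volume`, `area`, `avg_hydropathy`, and optionally `max_depth`,
#' `avg_depth`, `cavity_id`.
#'
#' @param path input CSV.
#' @return list of [cavity()] objects.
#' @export
read_cavities_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(r) {
    cavity(frame_id = df$frame_id[r],
           residues = as.integer(strsplit(df$residues[r], ";")[[1L]]),
           volume = df$volume[r], area = df$area[r],
           avg_hydropathy = df$avg_hydropathy[r],
           max_depth = df$max_depth[r] %||% 0,
           avg_depth = df$avg_depth[r] %||% 0,
           cavity_id = df$cavity_id[r] %||% NULL)
  })
}

#' Write cavity records as CSV
#'
#' @param cavities list of [cavity()] objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cavities_csv <- function(cavities, path) {
  df <- data.frame(
    frame_id = vapply(cavities, `[[`, integer(1), "frame_id"),
    residues = vapply(cavities, function(cv)
      paste(cv$residues, collapse = ";"), character(1)),
    volume = vapply(cavities, `[[`, numeric(1), "volume"),
    area = vapply(cavities, `[[`, numeric(1), "area"),
    max_depth = vapply(cavities, `[[`, numeric(1), "max_depth"),
    avg_depth = vapply(cavities, `[[`, numeric(1), "avg_depth"),
    avg_hydropathy = vapply(cavities, `[[`, numeric(1), "avg_hydropathy"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write docking boxes as CSV
#'
#' @param boxes list of [site_to_box()] results.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_boxes_csv <- function(boxes, path) {
  df <- data.frame(
    site_id = vapply(boxes, `[[`, integer(1), "site_id"),
    center_x = vapply(boxes, function(b) b$center[1L], numeric(1)),
    center_y = vapply(boxes, function(b) b$center[2L], numeric(1)),
    center_z = vapply(boxes, function(b) b$center[3L], numeric(1)),
    size_x = vapply(boxes, function(b) b$size[1L], numeric(1)),
    size_y = vapply(boxes, function(b) b$size[2L], numeric(1)),
    size_z = vapply(boxes, function(b) b$size[3L], numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a docking-engine config block for one box
#'
#' @param box a [site_to_box()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_box_config <- function(box, path) {
  writeLines(c(
    sprintf("center_x = %.3f", box$center[1L]),
    sprintf("center_y = %.3f", box$center[2L]),
    sprintf("center_z = %.3f", box$center[3L]),
    sprintf("size_x = %.3f", box$size[1L]),
    sprintf("size_y = %.3f", box$size[2L]),
    sprintf("size_z = %.3f", box$size[3L])), path)
  invisible(path)
}
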