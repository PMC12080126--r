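# Selection of AlphaFold-derived inter-residue distance restraints and
# evaluation of the metainference restraint energy on an ensemble.
#
# The data used are the per-residue pLDDT confidence, the pairwise
# predicted aligned error (PAE) and the pairwise predicted distance
# matrix.  Residue pairs become restraints when the prediction is
# confident (PAE below a cutoff) and the pair is not fully inside a
# high-pLDDT structured region, which is restrained by other means in
# the simulation engine and excluded here.

#' Bundle of structure-prediction confidence data
#'
#' @param plddt per-residue confidence in \[0, 1\].
#' @param pae n x n predicted aligned error matrix (Angstrom); may be
#'   asymmetric as produced by the predictor.
#' @param d_af n x n predicted inter-residue distance matrix (Angstrom).
#' @return object of class `prediction_bundle`.
#' @export
prediction_bundle <- function(plddt, pae, d_af) {
  n <- length(plddt)
  if (n == 0L) stop("plddt must be non-empty")
  if (any(plddt < 0 | plddt > 1)) stop("plddt values must lie in [0, 1]")
  pae <- as.matrix(pae); d_af <- as.matrix(d_af)
  if (!all(dim(pae) == n) || !all(dim(d_af) == n)) {
    stop("pae and d_af must be n x n with n = length(plddt)")
  }
  if (any(pae < 0) || any(d_af < 0)) stop("pae and d_af must be >= 0")
  structure(list(plddt = as.numeric(plddt), pae = pae, d_af = d_af),
            class = "prediction_bundle")
}

#' Maximal contiguous high-confidence (structured) regions
#'
#' Residues with pLDDT strictly above the threshold are classed as
#' structured; the function returns the maximal contiguous runs.
#'
#' @param plddt per-residue confidence in \[0, 1\].
#' @param threshold confidence threshold (default 0.75, strict >).
#' @return object of class `structured_regions`: a matrix of intervals
#'   with columns `start`, `end`, plus the threshold as an attribute.
#' @export
#' @examples
#' structured_regions(c(0.9, 0.9, 0.2, 0.8), threshold = 0.75)
structured_regions <- function(plddt, threshold = 0.75) {
  if (length(plddt) == 0L) stop("plddt must be non-empty")
  if (any(plddt < 0 | plddt > 1)) stop("plddt values must lie in [0, 1]")
  high <- plddt > threshold
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  iv <- cbind(start = starts[keep], end = ends[keep])
  structure(iv, threshold = threshold, class = "structured_regions")
}

structured_mask <- function(regions, n) {
  mask <- logical(n)
  if (nrow(regions) > 0L) {
    for (i in seq_len(nrow(regions))) {
      mask[regions[i, "start"]:regions[i, "end"]] <- TRUE
    }
  }
  mask
}

#' Select inter-residue distance restraints from prediction confidence
#'
#' A residue pair (i < j) becomes a restraint when its symmetrised PAE is
#' strictly below `pae_cutoff`, the sequence separation is at least
#' `min_separation`, and the two residues are not both inside a
#' structured region (those contacts are excluded because structured
#' regions are restrained to the predicted structure directly).
#'
#' @param bundle a [prediction_bundle()].
#' @param structured a [structured_regions()] object (or NULL for none).
#' @param pae_cutoff PAE cutoff in Angstrom (default 4, strict <).
#' @param min_separation minimum |i - j| (default 3).
#' @param symmetrize how to combine pae\[i,j\] and pae\[j,i\]: "min"
#'   (lenient, default) or "mean".
#' @return object of class `restraint_set`: data.frame with columns
#'   `i`, `j`, `d_af`, `pae`.
#' @export
select_restraints <- function(bundle, structured = NULL, pae_cutoff = 4,
                              min_separation = 3L,
                              symmetrize = c("min", "mean")) {
  if (pae_cutoff <= 0) stop("pae_cutoff must be positive")
  symmetrize <- match.arg(symmetrize)
  n <- length(bundle$plddt)
  p <- bundle$pae
  ps <- if (symmetrize == "min") pmin(p, t(p)) else (p + t(p)) / 2
  mask <- if (is.null(structured)) logical(n)
          else structured_mask(structured, n)
  idx <- which(upper.tri(ps), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  keep <- ps[idx] < pae_cutoff &
    (j - i) >= min_separation &
    !(mask[i] & mask[j])
  out <- data.frame(i = i[keep], j = j[keep],
                    d_af = bundle$d_af[idx][keep],
                    pae = ps[idx][keep])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Forward-model distances for a restraint set
#'
#' Euclidean distance between the representative (CA) atoms of each
#' restrained residue pair, evaluated on one conformation.
#'
#' @param conf a [conformation()].
#' @param restraints a [select_restraints()] result.
#' @return numeric vector of per-pair distances (Angstrom).
#' @export
forward_model_distances <- function(conf, restraints) {
  res <- sort(unique(c(restraints$i, restraints$j)))
  coords <- tryCatch(residue_coords(conf, res), error = function(e) {
    stop("restraint residues missing from conformation: ",
         conditionMessage(e))
  })
  a <- coords[match(restraints$i, res), , drop = FALSE]
  b <- coords[match(restraints$j, res), , drop = FALSE]
  unname(sqrt(rowSums((a - b)^2)))
}

#' Per-datapoint error model for the metainference score
#'
#' @param sigma_sem per-datapoint error from the finite replica count
#'   (Angstrom); length 1 or one per restraint.
#' @param sigma_b per-replica, per-datapoint error for force-field /
#'   forward-model / data errors (Angstrom); a vector (recycled across
#'   replicas) or a replicas x datapoints matrix.
#' @param range allowed sampling range for every sigma.
#' @return object of class `error_model`.
#' @export
error_model <- function(sigma_sem, sigma_b, range = c(1e-4, 10)) {
  check <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < range[1L]) || any(x > range[2L])) {
      stop(sprintf("%s must lie within [%g, %g]", nm, range[1L], range[2L]))
    }
  }
  check(sigma_sem, "sigma_sem")
  check(sigma_b, "sigma_b")
  structure(list(sigma_sem = sigma_sem, sigma_b = sigma_b, range = range),
            class = "error_model")
}

#' Metainference restraint energy of a replica ensemble
#'
#' Negative log of the Gaussian restraint likelihood, in energy units.
#' For replica r and datapoint i with combined variance
#' sigma^2 = sigma_sem_i^2 + sigma_b_ri^2 and deviation
#' delta_ri = d_i(X_r) - d_af_i:
#'
#'   data_term  = kB T * sum( delta_ri^2 / (2 sigma_ri^2) )
#'   error_term = kB T * sum( log(sigma_ri) + log(2 pi) / 2 )
#'
#' so that total = data_term + error_term is kB T times the full
#' negative log-likelihood.  The molecular-mechanics prior energy of the
#' simulation engine is deliberately not part of this score.
#'
#' @param replica_frames list of [conformation()] objects, one per replica.
#' @param restraints a [select_restraints()] result.
#' @param errors an [error_model()].
#' @param temperature temperature (K).
#' @return list with `data_term`, `error_term`, `total` (kJ/mol),
#'   `temperature`, and the per-replica data-term breakdown.
#' @export
metainference_energy <- function(replica_frames, restraints, errors,
                                 temperature = 298) {
  if (inherits(replica_frames, "conformation")) {
    replica_frames <- list(replica_frames)
  }
  if (length(replica_frames) < 1L) stop("at least one replica required")
  if (!inherits(errors, "error_model")) stop("errors must be an error_model")
  nr <- length(replica_frames)
  nd <- nrow(restraints)
  sem <- rep_len(errors$sigma_sem, nd)
  sb <- errors$sigma_b
  if (is.matrix(sb)) {
    if (nrow(sb) != nr || ncol(sb) != nd) {
      stop("sigma_b matrix must be replicas x datapoints")
    }
  } else {
    sb <- matrix(rep_len(sb, nd), nrow = nr, ncol = nd, byrow = TRUE)
  }
  kbt <- KB_KJ_MOL_K * temperature
  per_replica <- numeric(nr)
  err_sum <- 0
  for (r in seq_len(nr)) {
    d <- forward_model_distances(replica_frames[[r]], restraints)
    s2 <- sem^2 + sb[r, ]^2
    per_replica[r] <- kbt * sum((d - restraints$d_af)^2 / (2 * s2))
    err_sum <- err_sum + sum(0.5 * log(s2) + 0.5 * log(2 * pi))
  }
  data_term <- sum(per_replica)
  error_term <- kbt * err_sum
  list(data_term = data_term, error_term = error_term,
       total = data_term + error_term, temperature = temperature,
       per_replica_data = per_replica)
}

# ---------------------------------------------------------------- I/O --

#' Read a prediction bundle from plain files
#'
#' Either a single JSON file with fields `plddt`, `pae`, `d_af`, or three
#' delimited numeric tables.
#'
#' @param path JSON file path, or NULL when giving the three tables.
#' @param plddt_file,pae_file,d_af_file whitespace/comma-delimited
#'   numeric tables (used when `path` is NULL).
#' @return a [prediction_bundle()].
#' @export
read_prediction_bundle <- function(path = NULL, plddt_file = NULL,
                                   pae_file = NULL, d_af_file = NULL) {
  if (!is.null(path)) {
    x <- jsonlite::fromJSON(path)
    return(prediction_bundle(x$plddt, x$pae, x$d_af))
  }
  read_mat <- function(f) as.matrix(utils::read.table(f))
  prediction_bundle(scan(plddt_file, quiet = TRUE),
                    read_mat(pae_file), read_mat(d_af_file))
}

#' Write a prediction bundle as JSON
#'
#' @param bundle a [prediction_bundle()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prediction_bundle <- function(bundle, path) {
  jsonlite::write_json(list(plddt = bundle$plddt,
                            pae = bundle$pae, d_af = bundle$d_af),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write a restraint set as CSV
#'
#' @param restraints a [select_restraints()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_restraints_csv <- function(restraints, path) {
  utils::write.csv(as.data.frame(restraints), path, row.names = FALSE)
  invisible(path)
}

#' Write a restraint set as a PLUMED-style distance-restraint block
#'
#' Emits one DISTANCE line per pair (CA atoms addressed by residue id)
#' and a RESTRAINT line with the predicted distances as targets, for
#' interoperability with simulation engines.
#'
#' @param restraints a [select_restraints()] result.
#' @param path output file.
#' @param kappa harmonic force constant to print (kJ/mol/nm^2).
#' @return `path`, invisibly.
#' @export
write_restraints_plumed <- function(restraints, path, kappa = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  labels <- sprintf("d_%d_%d", restraints$i, restraints$j)
  writeLines(sprintf(
    "%s: DISTANCE ATOMS=@CA-%d,@CA-%d", labels, restraints$i, restraints$j),
    con)
  writeLines(sprintf(
    "RESTRAINT ARG=%s AT=%s KAPPA=%s",
    paste(labels, collapse = ","),
    paste(sprintf("%.3f", restraints$d_af * ANG_TO_NM), collapse = ","),
    paste(rep(kappa, nrow(restraints)), collapse = ",")), con)
  invisible(path)
}
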