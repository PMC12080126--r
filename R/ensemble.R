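# Ensemble data model and I/O.
#
# A conformation stores one frame at residue (or atomistic) resolution;
# a structural_ensemble stores an ordered list of conformations together
# with normalised statistical weights approximating a Boltzmann
# distribution, and optionally a replica id per frame.

#' Construct a single conformation
#'
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param resid integer residue id per atom; 1-based, non-decreasing and
#'   contiguous at residue level.
#' @param element element symbol per atom.
#' @param resname three-letter residue name per atom.
#' @param atom_name atom name per atom (default "CA" for bead models).
#' @param ligand optional list with fields `xyz` and `element` holding a
#'   bound ligand's heavy atoms.
#' @return an object of class `conformation`.
#' @export
conformation <- function(xyz, resid, element = "C", resname = "ALA",
                         atom_name = "CA", ligand = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  n <- nrow(xyz)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  resid <- as.integer(resid)
  if (length(resid) != n) stop("resid must have one entry per atom")
  if (is.unsorted(resid)) stop("residue ids must be non-decreasing")
  ids <- unique(resid)
  if (any(diff(ids) <= 0L)) stop("residue ids must be strictly increasing")
  element <- rep_len(toupper(element), n)
  resname <- rep_len(toupper(resname), n)
  atom_name <- rep_len(atom_name, n)
  if (!is.null(ligand)) {
    ligand$xyz <- as.matrix(ligand$xyz)
    if (ncol(ligand$xyz) != 3L || !all(is.finite(ligand$xyz))) {
      stop("ligand xyz must be a finite n x 3 matrix")
    }
    ligand$element <- rep_len(toupper(ligand$element %||% "C"),
                              nrow(ligand$xyz))
  }
  structure(list(xyz = xyz, resid = resid, element = element,
                 resname = resname, atom_name = atom_name,
                 ligand = ligand),
            class = "conformation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_residues <- function(conf) length(unique(conf$resid))

#' Construct a structural ensemble
#'
#' @param frames list of [conformation()] objects with identical residue
#'   count and atom naming.
#' @param weights per-frame statistical weights; normalised to sum to 1.
#'   Default uniform.
#' @param replica_id optional integer replica label per frame.
#' @return an object of class `structural_ensemble`.
#' @export
structural_ensemble <- function(frames, weights = NULL, replica_id = NULL) {
  if (length(frames) == 0L) stop("ensemble needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "conformation"))) {
    stop("all frames must be conformation objects")
  }
  ref <- frames[[1L]]
  same <- vapply(frames, function(f) {
    nrow(f$xyz) == nrow(ref$xyz) &&
      identical(f$resid, ref$resid) &&
      identical(f$atom_name, ref$atom_name)
  }, logical(1))
  if (!all(same)) stop("frames differ in residue count or atom naming")
  nf <- length(frames)
  if (is.null(weights)) weights <- rep(1 / nf, nf)
  if (length(weights) != nf) stop("one weight per frame required")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  weights <- weights / s
  if (!is.null(replica_id)) {
    replica_id <- as.integer(replica_id)
    if (length(replica_id) != nf) stop("one replica id per frame required")
  }
  structure(list(frames = frames, weights = weights,
                 replica_id = replica_id),
            class = "structural_ensemble")
}

#' @export
print.structural_ensemble <- function(x, ...) {
  cat(sprintf("structural_ensemble: %d frames, %d residues, %d atoms/frame\n",
              length(x$frames), n_residues(x$frames[[1L]]),
              nrow(x$frames[[1L]]$xyz)))
  if (!is.null(x$replica_id)) {
    cat(sprintf("  replicas: %d\n", length(unique(x$replica_id))))
  }
  invisible(x)
}

#' Named residue regions
#'
#' A region set maps names (e.g. LLPS-prone segments) to one or more
#' 1-based inclusive residue intervals.
#'
#' @param regions named list; each entry a 2-column matrix (or length-2
#'   vector) of `start`, `end` residue ids.
#' @param n_residues total residue count used for bounds checking.
#' @return object of class `region_set`.
#' @export
#' @examples
#' region_set(list(llps = rbind(c(1, 12), c(33, 177))), n_residues = 200)
region_set <- function(regions, n_residues) {
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop("regions must be a fully named list")
  }
  regions <- lapply(regions, function(r) {
    r <- matrix(as.integer(r), ncol = 2L)
    if (any(r[, 1L] < 1L) || any(r[, 2L] > n_residues) ||
        any(r[, 1L] > r[, 2L])) {
      stop("region intervals must satisfy 1 <= start <= end <= n_residues")
    }
    colnames(r) <- c("start", "end")
    r
  })
  structure(list(regions = regions, n_residues = as.integer(n_residues)),
            class = "region_set")
}

region_residues <- function(rs, name) {
  r <- rs$regions[[name]]
  sort(unique(unlist(lapply(seq_len(nrow(r)),
                            function(i) r[i, 1L]:r[i, 2L]))))
}

#' Per-frame bias energies of an enhanced-sampling run
#'
#' @param bias numeric vector, one bias energy per frame (kJ/mol).
#' @param temperature simulation temperature (K).
#' @return object of class `bias_trace`.
#' @export
bias_trace <- function(bias, temperature = 298) {
  bias <- as.numeric(bias)
  if (length(bias) == 0L || any(!is.finite(bias))) {
    stop("bias energies must be a non-empty finite vector")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  structure(list(bias = bias, temperature = temperature),
            class = "bias_trace")
}

#' Torrie-Valleau weights from per-frame bias energies
#'
#' Converts the final metadynamics bias evaluated on each frame of a
#' concatenated trajectory into normalised statistical weights,
#' w_i proportional to exp(V_i / (kB T)).  Adding a constant to every
#' bias leaves the weights unchanged.
#'
#' @param bias a [bias_trace()].
#' @param n_frames optional expected frame count (checked when supplied).
#' @return numeric weight vector, non-negative, summing to 1.
#' @export
#' @examples
#' tv <- bias_trace(c(0, 0.008314462618 * 298 * log(2)), temperature = 298)
#' torrie_valleau_weights(tv)  # 1/3, 2/3
torrie_valleau_weights <- function(bias, n_frames = NULL) {
  if (!inherits(bias, "bias_trace")) bias <- bias_trace(bias)
  if (!is.null(n_frames) && length(bias$bias) != n_frames) {
    stop(sprintf("bias trace has %d frames but ensemble has %d",
                 length(bias$bias), n_frames))
  }
  v <- bias$bias / (KB_KJ_MOL_K * bias$temperature)
  v <- v - max(v)                     # shift invariance, avoids overflow
  w <- exp(v)
  w / sum(w)
}

#' Attach Torrie-Valleau weights from a bias trace to an ensemble
#'
#' @param ensemble a [structural_ensemble()].
#' @param bias a [bias_trace()] with one entry per frame.
#' @return the reweighted ensemble.
#' @export
reweight_ensemble <- function(ensemble, bias) {
  w <- torrie_valleau_weights(bias, n_frames = length(ensemble$frames))
  ensemble$weights <- w
  ensemble
}

# ---------------------------------------------------------------- I/O --

#' Read a structural ensemble from PDB
#'
#' Accepts either a multi-model PDB file or a directory of one-PDB-per-
#' frame files (read in lexicographic order).  Parsing is done with
#' bio3d; only ATOM/HETATM records are used.  HETATM atoms with residue
#' name `lig_resname` become the ligand block of each frame.
#'
#' @param path PDB file or directory of PDB files.
#' @param lig_resname residue name identifying ligand atoms (default "LIG").
#' @return a [structural_ensemble()] with uniform weights.
#' @export
read_ensemble_pdb <- function(path, lig_resname = "LIG") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pdb files in ", path)
    frames <- lapply(files, function(f) {
      pdb <- bio3d::read.pdb(f, verbose = FALSE)
      pdb_to_conformation(pdb$atom, lig_resname)
    })
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nm <- max(1L, dim(pdb$xyz)[1L])
    frames <- lapply(seq_len(nm), function(m) {
      at <- pdb$atom
      coords <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
      at$x <- coords[, 1L]; at$y <- coords[, 2L]; at$z <- coords[, 3L]
      pdb_to_conformation(at, lig_resname)
    })
  }
  structural_ensemble(frames)
}

pdb_to_conformation <- function(atom, lig_resname) {
  elem <- atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(atom$elety), 1L, 1L)
  }
  is_lig <- toupper(atom$resid) == toupper(lig_resname)
  lig <- NULL
  if (any(is_lig)) {
    lig <- list(xyz = cbind(atom$x, atom$y, atom$z)[is_lig, , drop = FALSE],
                element = elem[is_lig])
  }
  p <- !is_lig
  conformation(cbind(atom$x, atom$y, atom$z)[p, , drop = FALSE],
               resid = atom$resno[p], element = elem[p],
               resname = atom$resid[p], atom_name = trimws(atom$elety[p]),
               ligand = lig)
}

#' Write a structural ensemble as a multi-model PDB file
#'
#' Emits standard MODEL/ATOM/HETATM/ENDMDL records; ligand atoms are
#' written as HETATM with residue name "LIG".
#'
#' @param ensemble a [structural_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$frames)) {
    f <- ensemble$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(f$xyz)), substr(f$atom_name, 1L, 4L),
      substr(f$resname, 1L, 3L), f$resid,
      f$xyz[, 1L], f$xyz[, 2L], f$xyz[, 3L], f$element)
    writeLines(lines, con)
    if (!is.null(f$ligand)) {
      off <- nrow(f$xyz)
      lres <- max(f$resid) + 1L
      lines <- sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        off + seq_len(nrow(f$ligand$xyz)), f$ligand$element, "LIG", lres,
        f$ligand$xyz[, 1L], f$ligand$xyz[, 2L], f$ligand$xyz[, 3L],
        f$ligand$element)
      writeLines(lines, con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-frame bias trace from plain text
#'
#' Expects two whitespace- or comma-delimited columns: frame index and
#' bias energy in kJ/mol.  Lines starting with `#` are ignored.
#'
#' @param path input file.
#' @param temperature simulation temperature (K).
#' @return a [bias_trace()].
#' @export
read_bias_trace <- function(path, temperature = 298) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) {
    tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                             sep = ",", stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 2L) stop("bias file needs columns: frame, bias_kj_mol")
  ord <- order(tab[[1L]])
  bias_trace(tab[[2L]][ord], temperature = temperature)
}

#' Write per-residue analytics as CSV
#'
#' @param values named or plain numeric vector, one value per residue.
#' @param path output file.
#' @param value_name column name for the value column.
#' @return `path`, invisibly.
#' @export
write_residue_csv <- function(values, path, value_name = "value") {
  ids <- if (!is.null(names(values))) as.integer(names(values))
         else seq_along(values)
  df <- data.frame(residue_id = ids, value = as.numeric(values))
  names(df)[2L] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
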