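# Topological fingerprints for QSAR featurization.
#
# SMILES are parsed through ChemmineR/OpenBabel into a heavy-atom
# molecular graph; the fingerprint enumerates all simple linear paths of
# 1..max_path bonds, labels each path by its alternating element / bond-
# order string (taking the lexicographically smaller of the two reading
# directions so the label is orientation-free), hashes the label and
# folds it onto a fixed-width bit vector.  The path-label set is a graph
# invariant, so equivalent SMILES of the same molecule give identical
# rows.

# Light syntactic screen applied before handing strings to the parser,
# which silently truncates malformed input instead of failing.
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1L]]
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((chars == pair[1L]) - (chars == pair[2L]))
    if (any(depth < 0) || depth[length(depth)] != 0L) return(FALSE)
  }
  # naive ring-closure pairing on bare digits outside brackets
  outside <- cumsum((chars == "[") - (chars == "]")) == 0L
  digits <- chars[outside & chars %in% as.character(0:9)]
  all(table(digits) %% 2L == 0L)
}

canonical_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) return(smiles)
  one <- function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) s)
    trimws(strsplit(out, "[ \t\n]")[[1L]][1L])
  }
  if (length(smiles) > 1L) {
    # batch conversion; fall back per string if alignment breaks
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN",
                                paste(smiles, collapse = "\n")),
      error = function(e) NULL)
    if (!is.null(out)) {
      lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
      lines <- trimws(vapply(strsplit(lines, "[ \t]"), `[`, character(1), 1L))
      lines <- lines[nzchar(lines)]
      if (length(lines) == length(smiles)) return(lines)
    }
  }
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

sdf_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (nrow(ab) == 0L) return(NULL)
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    matrix(integer(0), ncol = 3L)
  } else {
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  }
  list(elements = elements, bonds = bonds)
}

# Heavy-atom molecular graphs (list(elements, bonds) with bonds as a
# (from, to, order) matrix) for a vector of SMILES; NULL entries mark
# unparseable input.  Parsing is batched through one converter call.
smiles_graphs <- function(smiles) {
  out <- vector("list", length(smiles))
  ok <- vapply(smiles, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (!any(ok)) return(out)
  batch <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles[ok])),
    error = function(e) NULL)
  if (!is.null(batch) && length(batch) == sum(ok)) {
    out[ok] <- lapply(seq_len(length(batch)), function(k) {
      tryCatch(sdf_to_graph(batch[[k]]), error = function(e) NULL)
    })
  } else {
    out[ok] <- lapply(smiles[ok], function(s) {
      sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                      error = function(e) NULL)
      if (is.null(sdf)) NULL
      else tryCatch(sdf_to_graph(sdf[[1L]]), error = function(e) NULL)
    })
  }
  out
}

smiles_graph <- function(smiles) smiles_graphs(smiles)[[1L]]

# Deterministic string hash (compiled; identical across platforms).
# Vectorised over character input.
hash_string <- function(s) hash_strings_cpp(as.character(s))

# Enumerate all simple paths of 1..max_path bonds and return their
# orientation-free label strings.
molecule_paths <- function(graph, max_path = 7L) {
  n <- length(graph$elements)
  if (nrow(graph$bonds) == 0L) return(character(0))
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds[k, 1L]; b <- graph$bonds[k, 2L]
    o <- graph$bonds[k, 3L]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  labels <- character(0)
  walk <- function(path, bond_orders) {
    depth <- length(bond_orders)
    if (depth >= 1L) {
      el <- graph$elements[path]
      fwd <- paste(el, c(bond_orders, ""), sep = "", collapse = "")
      rev_ <- paste(rev(el), c(rev(bond_orders), ""), sep = "", collapse = "")
      labels[[length(labels) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    }
    if (depth == max_path) return(invisible())
    last <- path[length(path)]
    nb <- adj[[last]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      nxt <- nb[k, 1L]
      if (nxt %in% path) next
      walk(c(path, nxt), c(bond_orders, nb[k, 2L]))
    }
  }
  for (a in seq_len(n)) walk(a, integer(0))
  unique(labels)
}

#' Topological fingerprints for a SMILES list
#'
#' Hashed linear-path fingerprints (path lengths 1-7 bonds) folded to
#' `n_bits` columns.  Unparseable SMILES do not abort the run: their
#' rows are all-zero and their identifiers are returned in the
#' `rejected` attribute.
#'
#' @param smiles character vector of SMILES; names (or `ids`) become
#'   row names.
#' @param n_bits fingerprint width (default 1412).
#' @param max_path maximum path length in bonds (default 7).
#' @param ids optional compound identifiers.
#' @return 0/1 integer matrix, `length(smiles)` x `n_bits`, with
#'   attribute `rejected` (character vector of failed ids).
#' @export
#' @examples
#' \donttest{
#' fp <- featurize(c(a = "CCO", b = "OCC"))
#' identical(fp[1, ], fp[2, ])  # TRUE
#' }
featurize <- function(smiles, n_bits = 1412L, max_path = 7L, ids = NULL) {
  if (length(smiles) == 0L) stop("empty SMILES list")
  if (is.null(ids)) {
    ids <- names(smiles) %||% sprintf("cpd_%d", seq_along(smiles))
  }
  smiles <- as.character(smiles)
  # screen syntax before canonicalisation: the converter silently
  # truncates malformed strings instead of failing
  ok <- vapply(smiles, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  smiles[ok] <- canonical_smiles(smiles[ok])
  smiles[!ok] <- NA_character_
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits,
                dimnames = list(ids, NULL))
  uniq <- unique(smiles[ok])
  graphs <- smiles_graphs(uniq)
  bits <- lapply(graphs, function(g) {
    if (is.null(g)) return(NULL)
    paths <- molecule_paths(g, max_path)
    if (length(paths) == 0L) integer(0)
    else unique(hash_string(paths) %% n_bits) + 1L
  })
  rejected <- character(0)
  for (r in seq_along(smiles)) {
    row <- if (is.na(smiles[r])) NULL else bits[[match(smiles[r], uniq)]]
    if (is.null(row)) rejected <- c(rejected, ids[r])
    else out[r, row] <- 1L
  }
  attr(out, "rejected") <- rejected
  out
}

#' Read a SMILES library from a .smi file
#'
#' One molecule per line: SMILES optionally followed by a whitespace-
#' separated identifier.
#'
#' @param path input file.
#' @return named character vector (id -> SMILES).
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) > 1L) parts[[k]][2L] else sprintf("cpd_%d", k)
  }, character(1))
  stats::setNames(smiles, ids)
}

#' Write a SMILES library to a .smi file
#'
#' @param smiles named character vector (id -> SMILES).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_smi <- function(smiles, path) {
  ids <- names(smiles) %||% sprintf("cpd_%d", seq_along(smiles))
  writeLines(paste(smiles, ids), path)
  invisible(path)
}
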