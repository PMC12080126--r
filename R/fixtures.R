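# Synthetic-fixture generators: toy ensembles, prediction bundles,
# energy matrices with planted multibinders, and valid SMILES libraries.
# Every generator is deterministic under its seed and emits objects that
# pass the corresponding module's validators, so the whole pipeline runs
# and is tested with no external data.

# Evaluate expr under a temporary RNG seed, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Fixture specification
#'
#' Collects the knobs shared by the fixture generators.  The defaults
#' define the package's standard synthetic study: a 60-residue chain
#' with a rigid sub-block, 50 frames, 2000 training compounds against
#' 20 sites with 25 planted multibinders boosted by 3 kcal/mol
#' (3 background standard deviations) at 90% of the sites, and a
#' 500-compound screening library containing 50 further planted
#' binders.
#'
#' @param n_residues chain length (>= 5).
#' @param n_frames ensemble frames.
#' @param n_compounds training-library size.
#' @param n_sites number of binding sites.
#' @param n_planted planted multibinders in the training library
#'   (n_compounds > 20 * n_planted enforced).
#' @param delta planted energy boost in kcal/mol (> 0).
#' @param planted_site_fraction fraction of sites at which each planted
#'   compound is boosted, in (0, 1].
#' @param noise_sd background docking-energy standard deviation
#'   (kcal/mol).
#' @param base_mean background docking-energy mean (kcal/mol).
#' @param screen_size screening-library size.
#' @param screen_planted planted multibinders in the screening library.
#' @param rigid_block residue interval emulating a structured domain.
#' @param seed master seed for planted-site draws, energies and noise.
#' @param library_seed seed for the SMILES library draw (kept separate
#'   so replicated experiments can vary `seed` over a fixed library).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 60L, n_frames = 50L,
                         n_compounds = 2000L, n_sites = 20L,
                         n_planted = 25L, delta = 3,
                         planted_site_fraction = 0.9, noise_sd = 1,
                         base_mean = -5, screen_size = 500L,
                         screen_planted = 50L,
                         rigid_block = c(15L, 46L), seed = 42L,
                         library_seed = seed) {
  if (n_residues < 5L) stop("n_residues must be >= 5")
  if (delta < 0) stop("delta must be >= 0")
  if (planted_site_fraction <= 0 || planted_site_fraction > 1) {
    stop("planted_site_fraction must lie in (0, 1]")
  }
  if (n_planted > 0L && n_compounds <= 20L * n_planted) {
    stop("need n_compounds > 20 * n_planted")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 n_compounds = as.integer(n_compounds),
                 n_sites = as.integer(n_sites),
                 n_planted = as.integer(n_planted), delta = delta,
                 planted_site_fraction = planted_site_fraction,
                 noise_sd = noise_sd, base_mean = base_mean,
                 screen_size = as.integer(screen_size),
                 screen_planted = as.integer(screen_planted),
                 rigid_block = as.integer(rigid_block),
                 seed = as.integer(seed),
                 library_seed = as.integer(library_seed)),
            class = "fixture_spec")
}

# One self-avoiding random-walk CA chain (3.8 A virtual bonds) with the
# rigid-block residues pinned to `template` absolute coordinates.
walk_chain <- function(n_res, rigid = NULL, template = NULL,
                       bond = 3.8, min_sep = 3.5) {
  xyz <- matrix(0, n_res, 3L)
  for (i in 2:n_res) {
    if (!is.null(rigid) && i >= rigid[1L] && i <= rigid[2L]) {
      xyz[i, ] <- template[i - rigid[1L] + 1L, ]
      next
    }
    for (try in 1:50) {
      u <- rnorm(3)
      cand <- xyz[i - 1L, ] + bond * u / sqrt(sum(u^2))
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      ok <- i <= 2L ||
        min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_sep
      if (ok) break
    }
    xyz[i, ] <- cand
  }
  xyz
}

#' Generate a toy ensemble with bias trace
#'
#' Self-avoiding random-walk CA chains with fixed 3.8 A virtual bonds.
#' Residues inside `rigid_block` are pinned to one shared template
#' placed at a fixed absolute position (plus 0.1 A jitter), emulating a
#' structured domain: their fluctuations are small by construction while
#' the flanking tails wander freely.  The per-frame bias energies are
#' drawn from N(10, 2^2) kJ/mol at 298 K.
#'
#' @param spec a [fixture_spec()].
#' @return list with `ensemble` (a [structural_ensemble()], uniform
#'   weights) and `bias` (a [bias_trace()]).
#' @export
gen_toy_ensemble <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    rigid <- spec$rigid_block
    n_rigid <- rigid[2L] - rigid[1L] + 1L
    template <- walk_chain(n_rigid)
    template <- sweep(template, 2L, colMeans(template))
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      xyz <- walk_chain(spec$n_residues, rigid = rigid,
                        template = template +
                          matrix(rnorm(3L * n_rigid, sd = 0.1),
                                 n_rigid, 3L))
      conformation(xyz, resid = seq_len(spec$n_residues),
                   element = "C", resname = "GLY", atom_name = "CA")
    })
    bias <- bias_trace(rnorm(spec$n_frames, mean = 10, sd = 2),
                       temperature = 298)
    list(ensemble = structural_ensemble(frames), bias = bias)
  })
}

#' Generate a prediction bundle around a reference conformation
#'
#' The predicted distance matrix is the reference CA distance matrix
#' plus optional Gaussian noise; the PAE is `pae_low` on designated
#' confident pairs and `pae_high` elsewhere; pLDDT is high inside the
#' rigid block and low elsewhere.
#'
#' @param spec a [fixture_spec()].
#' @param reference a [conformation()] (defaults to the first frame of
#'   a freshly generated toy ensemble).
#' @param confident_pairs 2-column matrix of residue pairs with low PAE
#'   (default: all pairs).
#' @param noise_sd distance noise (Angstrom, default 0).
#' @param pae_low,pae_high PAE values for confident / other pairs.
#' @param plddt_high,plddt_low pLDDT inside / outside the rigid block.
#' @return a [prediction_bundle()].
#' @export
gen_prediction_bundle <- function(spec = fixture_spec(),
                                  reference = NULL,
                                  confident_pairs = NULL,
                                  noise_sd = 0, pae_low = 1,
                                  pae_high = 10, plddt_high = 0.9,
                                  plddt_low = 0.3) {
  if (is.null(reference)) {
    reference <- gen_toy_ensemble(spec)$ensemble$frames[[1L]]
  }
  n <- n_residues(reference)
  coords <- residue_coords(reference)
  d <- as.matrix(stats::dist(coords))
  with_seed(spec$seed + 1L, {
    if (noise_sd > 0) {
      noise <- matrix(rnorm(n * n, sd = noise_sd), n, n)
      noise <- (noise + t(noise)) / 2
      d <- pmax(d + noise, 0)
      diag(d) <- 0
    }
    pae <- matrix(pae_high, n, n)
    if (is.null(confident_pairs)) {
      pae[] <- pae_low
    } else {
      pae[confident_pairs] <- pae_low
      pae[confident_pairs[, c(2L, 1L), drop = FALSE]] <- pae_low
    }
    diag(pae) <- 0
    plddt <- rep(plddt_low, n)
    rb <- spec$rigid_block
    plddt[rb[1L]:rb[2L]] <- plddt_high
    prediction_bundle(plddt, pae, d)
  })
}

# Deterministic mock energy matrix over (compounds x sites): background
# N(base_mean, noise_sd^2) noise from the seeded hash, minus delta at
# planted (compound, site) cells.
mock_energy_matrix <- function(compound_ids, site_ids, planted = NULL,
                               seed = 1L, base_mean = -5, noise_sd = 1,
                               delta = 3) {
  keys <- outer(compound_ids, site_ids, function(c_, s_) {
    paste("mockdock", c_, s_, seed, sep = "|")
  })
  u <- (hash_string(as.vector(keys)) + 0.5) / 1000000007
  m <- matrix(base_mean + noise_sd * stats::qnorm(u),
              length(compound_ids), length(site_ids),
              dimnames = list(compound_ids, site_ids))
  for (cid in intersect(names(planted %||% list()), compound_ids)) {
    cols <- intersect(planted[[cid]], site_ids)
    m[cid, cols] <- m[cid, cols] - delta
  }
  class(m) <- c("energy_matrix", class(m))
  m
}

#' Generate an energy matrix with planted multibinders
#'
#' Background energies are i.i.d. N(`base_mean`, `noise_sd`^2) kcal/mol
#' derived from the seeded hash (hence identical to what [dock()] with
#' the mock engine returns for the same ids, planted list and seed).
#' Each planted compound is boosted by `delta` at a seeded random
#' subset of `ceiling(planted_site_fraction * n_sites)` sites.
#'
#' @param spec a [fixture_spec()].
#' @param compound_ids,site_ids identifiers (defaults generated from
#'   the spec sizes).
#' @param planted_ids compounds to plant (default: the first
#'   `n_planted` compound ids).
#' @return list with `energy` (an `energy_matrix`), `planted` (named
#'   list compound id -> boosted site ids) and `spec`.
#' @export
gen_energy_matrix <- function(spec = fixture_spec(),
                              compound_ids = NULL, site_ids = NULL,
                              planted_ids = NULL) {
  compound_ids <- compound_ids %||%
    sprintf("cpd_%04d", seq_len(spec$n_compounds))
  site_ids <- site_ids %||% sprintf("site_%02d", seq_len(spec$n_sites))
  planted_ids <- planted_ids %||% utils::head(compound_ids, spec$n_planted)
  n_boost <- ceiling(spec$planted_site_fraction * length(site_ids))
  planted <- with_seed(spec$seed + 2L, {
    stats::setNames(lapply(planted_ids, function(cid) {
      sort(sample(site_ids, n_boost))
    }), planted_ids)
  })
  energy <- mock_energy_matrix(compound_ids, site_ids, planted,
                               seed = spec$seed,
                               base_mean = spec$base_mean,
                               noise_sd = spec$noise_sd,
                               delta = spec$delta)
  list(energy = energy, planted = planted, spec = spec)
}

# ------------------------------------------------------ SMILES grammar --

# Enumerate acyclic chain molecules: C backbones with optional branches,
# one optional in-chain heteroatom or double bond, and a terminal
# group.  Syntactically valid by construction.
enumerate_aliphatic <- function() {
  out <- character(0)
  branches <- c("", "(C)", "(CC)", "(O)", "(CCC)", "(C)(C)", "(N)")
  terminals <- c("", "O", "N", "OC", "C(=O)O", "Cl", "F", "C#N")
  for (len in 2:10) {
    for (p1 in 0:(len - 2L)) {
      for (b1 in branches) {
        if (p1 == 0L && b1 != "") next
        for (term in terminals) {
          chain <- rep("C", len)
          if (p1 > 0L) chain[p1 + 1L] <- paste0("C", b1)
          out <- c(out, paste0(paste(chain, collapse = ""), term))
        }
      }
    }
  }
  # two branch positions
  for (len in 5:10) {
    for (p1 in 1:(len - 3L)) {
      for (p2 in (p1 + 1L):(len - 2L)) {
        for (b1 in c("(C)", "(O)")) {
          for (b2 in c("(C)", "(O)", "(CC)")) {
            for (term in c("", "O", "N")) {
              chain <- rep("C", len)
              chain[p1 + 1L] <- paste0("C", b1)
              chain[p2 + 1L] <- paste0("C", b2)
              out <- c(out, paste0(paste(chain, collapse = ""), term))
            }
          }
        }
      }
    }
  }
  # one in-chain heteroatom (ether / secondary amine) or a double bond
  for (len in 4:10) {
    for (q in 2:(len - 1L)) {
      for (het in c("O", "N")) {
        for (term in c("", "O", "N")) {
          chain <- rep("C", len)
          chain[q] <- het
          out <- c(out, paste0(paste(chain, collapse = ""), term))
        }
      }
      for (term in c("", "O", "Cl")) {
        chain <- rep("C", len)
        chain[q] <- "C="
        out <- c(out, paste0(paste(chain, collapse = ""), term))
      }
    }
  }
  unique(out)
}

# Deduplicated grammar pools are canonicalisation-heavy; cache them for
# the session (they do not depend on any seed).
.grammar_cache <- new.env(parent = emptyenv())

grammar_pool <- function(kind) {
  if (is.null(.grammar_cache[[kind]])) {
    pool <- switch(kind,
      aliphatic = enumerate_aliphatic(),
      aromatic = enumerate_aromatic(),
      mixed = c(enumerate_aliphatic(), enumerate_aromatic()))
    canon <- canonical_smiles(pool)
    .grammar_cache[[kind]] <- pool[!duplicated(canon)]
  }
  .grammar_cache[[kind]]
}

# Enumerate substituted single aromatic rings.
enumerate_aromatic <- function() {
  subs <- c("C", "CC", "CCC", "O", "OC", "N", "Cl", "F", "C(=O)O", "C#N")
  out <- character(0)
  for (s1 in subs) {
    out <- c(out, paste0(s1, "c1ccccc1"))
    for (s2 in subs) {
      out <- c(out, paste0(s1, "c1ccc(", s2, ")cc1"),
               paste0(s1, "c1cccc(", s2, ")c1"))
    }
  }
  unique(out)
}

#' Generate a library of valid SMILES
#'
#' Combinatorial enumeration over a small scaffold grammar (linear and
#' branched alkane/alcohol/amine chains; substituted single aromatic
#' rings), deduplicated after canonicalisation, then sampled without
#' replacement.  Every emitted string parses in [featurize()].
#'
#' @param n number of molecules (must not exceed grammar capacity).
#' @param seed sampling seed.
#' @param kind "aliphatic", "aromatic" or "mixed".
#' @return named character vector (id -> SMILES).
#' @export
gen_smiles_library <- function(n, seed = 1L,
                               kind = c("mixed", "aliphatic", "aromatic")) {
  kind <- match.arg(kind)
  pool <- grammar_pool(kind)
  if (n > length(pool)) {
    stop(sprintf("requested %d molecules but grammar capacity is %d",
                 n, length(pool)))
  }
  smiles <- with_seed(seed, sample(pool, n))
  stats::setNames(smiles, sprintf("%s_%04d", substr(kind, 1L, 3L),
                                  seq_len(n)))
}

#' Generate fixture cavities for the pocket-selection stage
#'
#' Emits `n_pass` cavities that satisfy every binding-site filter
#' (residue sets drawn inside the rigid block, hydrophobic, mid-sized)
#' plus `n_fail` decoys that each violate exactly one filter condition,
#' so the filtered output of the fixture pipeline has a known size.
#' Passing cavities draw their residues from overlapping ~10-residue
#' windows tiled along the rigid block, giving the site set a non-
#' trivial residue-sharing cluster structure.
#'
#' @param spec a [fixture_spec()].
#' @param n_pass cavities passing all filters (default `spec$n_sites`).
#' @param n_fail decoy cavities (default 20).
#' @return list of [cavity()] objects.
#' @export
gen_fixture_cavities <- function(spec = fixture_spec(),
                                 n_pass = spec$n_sites, n_fail = 20L) {
  rb <- spec$rigid_block
  block <- rb[1L]:rb[2L]
  width <- min(10L, length(block))
  starts <- seq(rb[1L], max(rb[1L], rb[2L] - width + 1L), by = 7L)
  windows <- lapply(starts, function(s) s:min(s + width - 1L, rb[2L]))
  windows <- windows[lengths(windows) >= 8L]
  if (length(windows) == 0L) windows <- list(block)
  with_seed(spec$seed + 3L, {
    good <- lapply(seq_len(n_pass), function(k) {
      win <- windows[[((k - 1L) %% length(windows)) + 1L]]
      cavity(frame_id = ((k - 1L) %% spec$n_frames) + 1L,
             residues = sort(sample(win, min(8L, length(win)))),
             volume = runif(1, 200, 600), area = runif(1, 300, 900),
             avg_hydropathy = runif(1, -1.2, -0.1),
             max_depth = runif(1, 5, 12), avg_depth = runif(1, 2, 6))
    })
    breakers <- list(
      function(cv) { cv$residues <- cv$residues[1:4]; cv },   # too few
      function(cv) { cv$avg_hydropathy <- 0.8; cv },          # hydrophilic
      function(cv) { cv$area <- 40; cv },                     # small area
      function(cv) { cv$area <- 3000; cv },                   # huge area
      function(cv) { cv$volume <- 50; cv })                   # small volume
    bad <- lapply(seq_len(n_fail), function(k) {
      cv <- cavity(frame_id = ((k - 1L) %% spec$n_frames) + 1L,
                   residues = sort(sample(block, 8L)),
                   volume = runif(1, 200, 600),
                   area = runif(1, 300, 900),
                   avg_hydropathy = runif(1, -1.2, -0.1))
      breakers[[((k - 1L) %% length(breakers)) + 1L]](cv)
    })
    c(good, bad)
  })
}

#' Generate the full screening fixture
#'
#' Builds a training library and a screening library in which the
#' planted multibinders are exactly the aromatic-scaffold compounds, so
#' activity is learnable from the fingerprints; mock docking energies
#' boost each planted compound by `delta` at its seeded site subset.
#'
#' @param spec a [fixture_spec()].
#' @return list with `train` (list: `smiles`, `energy`, `planted`),
#'   `screen` (list: `smiles`, `planted`), `site_ids`, `spec`.
#' @export
gen_screening_fixture <- function(spec = fixture_spec()) {
  n_arom <- spec$n_planted + spec$screen_planted
  arom <- gen_smiles_library(n_arom, seed = spec$library_seed,
                             kind = "aromatic")
  n_ali <- (spec$n_compounds - spec$n_planted) +
    (spec$screen_size - spec$screen_planted)
  ali <- gen_smiles_library(n_ali, seed = spec$library_seed,
                            kind = "aliphatic")
  train_smiles <- c(utils::head(arom, spec$n_planted),
                    utils::head(ali, spec$n_compounds - spec$n_planted))
  names(train_smiles) <- sprintf("trn_%04d", seq_along(train_smiles))
  screen_smiles <- c(utils::tail(arom, spec$screen_planted),
                     utils::tail(ali, spec$screen_size - spec$screen_planted))
  names(screen_smiles) <- sprintf("scr_%04d", seq_along(screen_smiles))
  site_ids <- sprintf("site_%02d", seq_len(spec$n_sites))
  train_planted_ids <- names(train_smiles)[seq_len(spec$n_planted)]
  screen_planted_ids <- names(screen_smiles)[seq_len(spec$screen_planted)]
  n_boost <- ceiling(spec$planted_site_fraction * spec$n_sites)
  planted_all <- with_seed(spec$seed + 2L, {
    stats::setNames(lapply(c(train_planted_ids, screen_planted_ids),
                           function(cid) sort(sample(site_ids, n_boost))),
                    c(train_planted_ids, screen_planted_ids))
  })
  energy <- mock_energy_matrix(names(train_smiles), site_ids,
                               planted_all, seed = spec$seed,
                               base_mean = spec$base_mean,
                               noise_sd = spec$noise_sd,
                               delta = spec$delta)
  list(train = list(smiles = train_smiles, energy = energy,
                    planted = planted_all[train_planted_ids]),
       screen = list(smiles = screen_smiles,
                     planted = planted_all[screen_planted_ids]),
       planted_all = planted_all,
       site_ids = site_ids, spec = spec)
}
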