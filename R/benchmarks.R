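# Benchmark runner for the deposited AR-V7 study data.
#
# The deposited archive (structural ensemble, prediction bundle, cavity
# report, docking-energy tables; Zenodo record 10.5281/zenodo.10985337
# plus the study's energy tables) is large, partly binary and not
# redistributable with this package, so these benchmarks only run when
# the user has downloaded and converted the data locally.

#' Benchmark the pipeline against the deposited AR-V7 data
#'
#' Recomputes the study-scale quantities from a local copy of the
#' deposited data.  The expected layout of `dir` is:
#'
#' * `ensemble.pdb` — multi-model CA ensemble (or a `frames/` directory
#'   of per-frame PDBs);
#' * `plddt.txt`, `pae.txt`, `d_af.txt` — prediction bundle tables
#'   (pLDDT scaled to \[0, 1\]);
#' * `cavities.csv` — cavity report in [read_cavities_csv()] format;
#' * `energies_naive.csv` — naive docking energies, long format.
#'
#' @param dir directory holding the converted deposited data.
#' @param sticky_tyrosines residue ids of the NMR-identified sticky
#'   tyrosines.
#' @param rmsf_cutoff_nm stickiness RMSF cutoff (nm).
#' @return list with `n_cavities`, `n_sites`, `n_clusters`,
#'   `n_restraints`, `sticky_low_rmsf` (count below the cutoff),
#'   `naive_hits` (compounds active at > 30 sites).
#' @export
benchmark_deposited <- function(dir,
                                sticky_tyrosines = c(11, 19, 348, 359,
                                  364, 365, 395, 408, 447, 481, 483,
                                  504, 514, 531, 535, 552, 553),
                                rmsf_cutoff_nm = 4.5) {
  if (!dir.exists(dir)) {
    stop("deposited-data directory not found: ", dir,
         "\nDownload the archived study data and convert it to the ",
         "layout documented in ?benchmark_deposited")
  }
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing deposited file: ", p)
    p
  }
  ens_path <- if (dir.exists(file.path(dir, "frames")))
    file.path(dir, "frames") else need("ensemble.pdb")
  ensemble <- read_ensemble_pdb(ens_path)
  rmsf <- residue_rmsf(ensemble)

  bundle <- read_prediction_bundle(plddt_file = need("plddt.txt"),
                                   pae_file = need("pae.txt"),
                                   d_af_file = need("d_af.txt"))
  structured <- structured_regions(bundle$plddt, 0.75)
  restraints <- select_restraints(bundle, structured, pae_cutoff = 4)

  cavities <- read_cavities_csv(need("cavities.csv"))
  sites <- filter_cavities(cavities, rmsf, filter_config())
  clusters <- cluster_sites(sites, 0.6)

  energy <- read_energy_csv(need("energies_naive.csv"))
  labels <- build_labels(energy, 5)
  hits <- multibinding_hit_histogram(labels, min_sites = 30L)

  list(n_cavities = length(cavities), n_sites = length(sites),
       n_clusters = length(clusters$clusters),
       n_restraints = nrow(restraints),
       sticky_low_rmsf = sum(
         rmsf[as.character(sticky_tyrosines)] < rmsf_cutoff_nm),
       naive_hits = hits$n_above)
}
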