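# Stage orchestration: run the full pipeline (ensemble -> analytics ->
# restraints -> pockets -> docking -> labels/training -> screening)
# from one declarative configuration, writing every stage artifact plus
# a manifest with parameters and content hashes.

#' Pipeline configuration
#'
#' All module thresholds default to the package's standard values
#' (pLDDT 0.75, PAE 4 A, the binding-site filter defaults, labelling
#' percentile 5, site-fraction rule 0.70); the fixture spec defines the
#' synthetic inputs and the mock docking engine.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param stages character vector of stages to run, from
#'   `c("ensemble", "analytics", "restraints", "pockets", "dock",
#'   "label", "train", "screen")`; disabled stages are resumed from
#'   artifacts already on disk.
#' @param spec a [fixture_spec()] describing the synthetic inputs.
#' @param plddt_threshold,pae_cutoff restraint-selection thresholds.
#' @param filter a [filter_config()].
#' @param overlap_threshold site-clustering threshold.
#' @param percentile labelling percentile.
#' @param site_fraction screening fraction-of-sites threshold.
#' @param min_sites strict multibinding cutoff (default
#'   `floor(0.70 * n_sites)`).
#' @param engine docking engine ("mock" or "vina").
#' @param model a [model_config()] for the surrogate.
#' @param seed master seed (overrides `spec$seed` and `model$seed`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ensdock_run_"),
                            stages = c("ensemble", "analytics",
                                       "restraints", "pockets", "dock",
                                       "label", "train", "screen"),
                            spec = fixture_spec(),
                            plddt_threshold = 0.75, pae_cutoff = 4,
                            filter = filter_config(),
                            overlap_threshold = 0.6, percentile = 5,
                            site_fraction = 0.70, min_sites = NULL,
                            engine = "mock",
                            model = model_config(hidden = 64L,
                                                 epochs = 8L,
                                                 batch_size = 256L,
                                                 lr = 2e-3),
                            seed = 1L) {
  spec$seed <- as.integer(seed)
  model$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, stages = stages, spec = spec,
                 plddt_threshold = plddt_threshold,
                 pae_cutoff = pae_cutoff, filter = filter,
                 overlap_threshold = overlap_threshold,
                 percentile = percentile, site_fraction = site_fraction,
                 min_sites = min_sites %||% floor(0.70 * spec$n_sites),
                 engine = engine, model = model, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_record <- function(name, params, files, t0) {
  files <- files[file.exists(files)]
  list(stage = name, params = params,
       outputs = as.list(tools::md5sum(files)),
       elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
}

pipeline_need <- function(state, key, stage) {
  if (is.null(state[[key]])) {
    stop(sprintf("missing upstream artifact '%s': enable or re-run the '%s' stage",
                 key, stage), call. = FALSE)
  }
  state[[key]]
}

#' Run the pipeline
#'
#' Executes the enabled stages in order on the fixture inputs, writing
#' plain-text artifacts under `config$out_dir` and a `manifest.json`
#' echoing every parameter and output hash.  With a fixed seed and the
#' mock engine, a re-run reproduces identical artifact hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `config` echo and one
#'   record per executed stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  spec <- config$spec
  state <- new.env(parent = emptyenv())
  manifest <- list()
  on_stage <- function(name) name %in% config$stages

  if (on_stage("ensemble")) {
    t0 <- as.numeric(Sys.time())
    toy <- gen_toy_ensemble(spec)
    state$ensemble <- reweight_ensemble(toy$ensemble, toy$bias)
    write_ensemble_pdb(state$ensemble, out("ensemble.pdb"))
    writeLines(sprintf("%d %.6f", seq_along(toy$bias$bias),
                       toy$bias$bias), out("bias.txt"))
    write_residue_csv(state$ensemble$weights, out("frame_weights.csv"),
                      value_name = "weight")
    manifest$ensemble <- stage_record("ensemble",
      list(n_residues = spec$n_residues, n_frames = spec$n_frames,
           seed = config$seed),
      out(c("ensemble.pdb", "bias.txt", "frame_weights.csv")), t0)
  } else if (file.exists(out("ensemble.pdb"))) {
    state$ensemble <- read_ensemble_pdb(out("ensemble.pdb"))
    state$ensemble <- reweight_ensemble(state$ensemble,
                                        read_bias_trace(out("bias.txt")))
  }

  if (on_stage("analytics")) {
    t0 <- as.numeric(Sys.time())
    ens <- pipeline_need(state, "ensemble", "ensemble")
    state$rmsf <- residue_rmsf(ens)
    write_residue_csv(state$rmsf, out("rmsf.csv"), value_name = "rmsf_nm")
    manifest$analytics <- stage_record("analytics",
      list(superpose = FALSE), out("rmsf.csv"), t0)
  } else if (file.exists(out("rmsf.csv"))) {
    df <- utils::read.csv(out("rmsf.csv"))
    state$rmsf <- stats::setNames(df[[2L]], df[[1L]])
  }

  if (on_stage("restraints")) {
    t0 <- as.numeric(Sys.time())
    ens <- pipeline_need(state, "ensemble", "ensemble")
    bundle <- gen_prediction_bundle(spec, ens$frames[[1L]])
    structured <- structured_regions(bundle$plddt,
                                     config$plddt_threshold)
    state$restraints <- select_restraints(bundle, structured,
                                          pae_cutoff = config$pae_cutoff)
    write_restraints_csv(state$restraints, out("restraints.csv"))
    write_restraints_plumed(state$restraints, out("restraints.plumed"))
    manifest$restraints <- stage_record("restraints",
      list(plddt_threshold = config$plddt_threshold,
           pae_cutoff = config$pae_cutoff,
           n_restraints = nrow(state$restraints)),
      out(c("restraints.csv", "restraints.plumed")), t0)
  }

  if (on_stage("pockets")) {
    t0 <- as.numeric(Sys.time())
    ens <- pipeline_need(state, "ensemble", "ensemble")
    rmsf <- pipeline_need(state, "rmsf", "analytics")
    cavities <- gen_fixture_cavities(spec)
    write_cavities_csv(cavities, out("cavities.csv"))
    sites <- filter_cavities(cavities, rmsf, config$filter)
    clusters <- cluster_sites(sites, config$overlap_threshold)
    boxes <- lapply(sites, function(s)
      site_to_box(s, ens$frames[[s$cavity$frame_id]]))
    write_boxes_csv(boxes, out("boxes.csv"))
    jsonlite::write_json(clusters$clusters, out("clusters.json"))
    state$site_ids <- sprintf("site_%02d",
                              vapply(sites, `[[`, integer(1),
                                     "site_id") + 1L)
    manifest$pockets <- stage_record("pockets",
      list(filter = unclass(config$filter),
           overlap_threshold = config$overlap_threshold,
           n_cavities = length(cavities), n_sites = length(sites),
           n_clusters = length(clusters$clusters)),
      out(c("cavities.csv", "boxes.csv", "clusters.json")), t0)
  } else if (file.exists(out("boxes.csv"))) {
    state$site_ids <- sprintf("site_%02d",
                              utils::read.csv(out("boxes.csv"))$site_id + 1L)
  }

  fx <- NULL
  need_fx <- function() {
    if (is.null(fx)) fx <<- gen_screening_fixture(spec)
    fx
  }

  if (on_stage("dock")) {
    t0 <- as.numeric(Sys.time())
    site_ids <- pipeline_need(state, "site_ids", "pockets")
    if (config$engine != "mock") {
      stop("only the mock engine is wired into the fixture pipeline; ",
           "run an external engine through dock_library() directly")
    }
    f <- need_fx()
    state$energy <- f$train$energy[, site_ids[site_ids %in%
                                               colnames(f$train$energy)],
                                   drop = FALSE]
    write_energy_csv(state$energy, out("energies.csv"))
    write_smi(f$train$smiles, out("train.smi"))
    manifest$dock <- stage_record("dock",
      list(engine = config$engine, n_compounds = nrow(state$energy),
           n_sites = ncol(state$energy), seed = config$seed),
      out(c("energies.csv", "train.smi")), t0)
  } else if (file.exists(out("energies.csv"))) {
    state$energy <- read_energy_csv(out("energies.csv"))
  }

  if (on_stage("label")) {
    t0 <- as.numeric(Sys.time())
    energy <- pipeline_need(state, "energy", "dock")
    state$labels <- build_labels(energy, config$percentile)
    utils::write.csv(data.frame(site_id = colnames(energy),
                                threshold = state$labels$thresholds),
                     out("thresholds.csv"), row.names = FALSE)
    manifest$label <- stage_record("label",
      list(percentile = config$percentile), out("thresholds.csv"), t0)
  }

  if (on_stage("train")) {
    t0 <- as.numeric(Sys.time())
    labels <- pipeline_need(state, "labels", "label")
    f <- need_fx()
    fp <- featurize(f$train$smiles)
    state$model <- train_classifier(fp, labels, config$model)
    save_model(state$model, out("model"))
    write_metrics_json(state$model$report, out("metrics.json"))
    manifest$train <- stage_record("train",
      list(hidden = config$model$hidden, epochs = config$model$epochs,
           best_epoch = state$model$best_epoch,
           test_mean_mcc = state$model$report$mean_mcc),
      out(c("metrics.json", file.path("model", "model.json"))), t0)
  }

  if (on_stage("screen")) {
    t0 <- as.numeric(Sys.time())
    model <- pipeline_need(state, "model", "train")
    labels <- pipeline_need(state, "labels", "label")
    f <- need_fx()
    sel <- screen(model, f$screen$smiles,
                  site_fraction_threshold = config$site_fraction)
    utils::write.csv(data.frame(compound_id = names(sel$fraction),
                                active_site_fraction = sel$fraction,
                                selected = names(sel$fraction) %in%
                                  sel$selected),
                     out("selection.csv"), row.names = FALSE)
    res <- run_enrichment_experiment(f, config$model,
                                     fp_train = featurize(f$train$smiles),
                                     fp_screen = featurize(f$screen$smiles),
                                     min_sites = config$min_sites,
                                     percentile = config$percentile)
    jsonlite::write_json(list(naive_rate = res$naive_rate,
                              screened_rate = res$screened_rate,
                              n_selected = res$n_selected,
                              min_sites = res$min_sites),
                         out("hits.json"), auto_unbox = TRUE, digits = NA)
    state$screen <- res
    manifest$screen <- stage_record("screen",
      list(site_fraction = config$site_fraction,
           min_sites = config$min_sites,
           n_selected = res$n_selected),
      out(c("selection.csv", "hits.json")), t0)
  }

  manifest <- list(config = config_echo(config), stages = manifest)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

config_echo <- function(config) {
  list(out_dir = config$out_dir, stages = config$stages,
       spec = unclass(config$spec),
       plddt_threshold = config$plddt_threshold,
       pae_cutoff = config$pae_cutoff,
       filter = unclass(config$filter),
       overlap_threshold = config$overlap_threshold,
       percentile = config$percentile,
       site_fraction = config$site_fraction,
       min_sites = config$min_sites, engine = config$engine,
       model = unclass(config$model), seed = config$seed,
       package_version = as.character(utils::packageVersion("ensdock")))
}
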