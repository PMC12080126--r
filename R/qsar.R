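# Multilabel QSAR surrogate: oversampling, training with MCC-based
# checkpointing, library screening with the fraction-of-sites rule.

#' Classifier configuration
#'
#' @param hidden hidden-layer widths (default four layers of 1256).
#' @param dropout dropout rate applied to the first and last hidden
#'   layers during training (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs maximum training epochs; the checkpoint is the epoch
#'   with the best validation mean MCC (default 100).
#' @param batch_size minibatch size (default 128).
#' @param split train/validation/test fractions, summing to 1
#'   (default 0.8/0.1/0.1).
#' @param oversample_target target mean per-site active fraction in the
#'   training pool after duplicating active compounds (default 0.25).
#' @param seed integer seed driving the split, oversampling and training.
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden = rep(1256L, 4L), dropout = 0.2,
                         lr = 1e-3, epochs = 100L, batch_size = 128L,
                         split = c(0.8, 0.1, 0.1),
                         oversample_target = 0.25, seed = 1L) {
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-8) {
    stop("split must be three fractions summing to 1")
  }
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 oversample_target = oversample_target,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Oversample compounds with at least one active label
#'
#' Rows with any active label are duplicated (sampled with replacement)
#' and appended until the mean per-site active fraction of the pool
#' reaches `target`; the originals are always retained.  Duplication is
#' capped at `max_factor` times the original pool size.  When the
#' target is unreachable by duplicating actives (their mean per-row
#' active count is already below the target rate, as happens when most
#' actives are single-site), every active row is instead duplicated
#' once, which doubles the representation of actives without blowing up
#' the pool.
#'
#' @param features compounds x bits fingerprint matrix.
#' @param labels compounds x sites binary matrix aligned with `features`.
#' @param target target mean per-site active fraction (default 0.25).
#' @param seed integer seed for the resampling.
#' @param max_factor cap on appended rows relative to the pool size.
#' @return list with `features`, `labels` (augmented) and `origin`
#'   (original row index of every augmented row).
#' @export
oversample_actives <- function(features, labels, target = 0.25,
                               seed = 1L, max_factor = 10) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels)) stop("row counts must match")
  active <- which(rowSums(labels == 1L) > 0L)
  if (length(active) == 0L) {
    warning("no active compounds; oversampling is a no-op")
    return(list(features = features, labels = labels,
                origin = seq_len(nrow(features))))
  }
  n <- nrow(labels); k <- ncol(labels)
  s <- sum(labels == 1L)
  a <- mean(rowSums(labels[active, , drop = FALSE] == 1L))
  extra <- integer(0)
  if (s / (n * k) < target) {
    if (a > target * k) {
      m <- min(ceiling((target * n * k - s) / (a - target * k)),
               ceiling(max_factor * n))
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      extra <- sample(active, m, replace = TRUE)
      # top up one duplicate at a time if sampling fell short of target
      f_now <- function(ex) (s + sum(labels[ex, , drop = FALSE] == 1L)) /
        ((n + length(ex)) * k)
      while (f_now(extra) < target && length(extra) < max_factor * n) {
        extra <- c(extra, sample(active, 1L))
      }
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    } else {
      extra <- active   # unreachable target: one extra copy per active
    }
  }
  origin <- c(seq_len(n), extra)
  list(features = features[origin, , drop = FALSE],
       labels = labels[origin, , drop = FALSE],
       origin = origin)
}

# Train/validation/test indices.  When strata are given (a factor over
# compounds), each stratum is allocated proportionally, so rare classes
# such as multibinders are represented in every partition -- without
# this, a plain random split can leave the validation set with no
# multibinder at all, making MCC-based checkpointing blind.
split_indices <- function(n, split, seed, strata = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (is.null(strata)) strata <- factor(rep(1L, n))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    if (length(idx) == 0L) next
    perm <- idx[sample.int(length(idx))]
    m <- length(perm)
    n_train <- floor(split[1L] * m)
    n_val <- floor(split[2L] * m)
    out$train <- c(out$train, perm[seq_len(n_train)])
    out$val <- c(out$val, perm[n_train + seq_len(n_val)])
    if (n_train + n_val < m) {
      out$test <- c(out$test, perm[(n_train + n_val + 1L):m])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  lapply(out, sort)
}

# Activity strata for splitting: inactive everywhere, active at fewer
# than half the sites, or multibinding (at least half the sites).
activity_strata <- function(y) {
  frac <- rowSums(y == 1L) / ncol(y)
  cut(frac, c(-Inf, 0, 0.5, Inf), labels = c("none", "some", "multi"))
}

#' Train the multilabel classifier
#'
#' Splits compounds into train/validation/test, oversamples active
#' compounds in the training pool, trains the feed-forward network with
#' binary cross-entropy loss, checkpoints the epoch with the best
#' validation mean MCC, and reports final metrics on the held-out test
#' split.
#'
#' @param fingerprints compounds x bits matrix from [featurize()].
#' @param labels a [build_labels()] result or binary matrix aligned
#'   with `fingerprints`.
#' @param config a [model_config()].
#' @return object of class `trained_model`: list with `weights`,
#'   `biases`, `config`, `sites`, `best_epoch`, `val_mcc_trace`,
#'   `train_loss_trace`, `report` (test-split [metrics_report()]) and
#'   `splits`.
#' @export
train_classifier <- function(fingerprints, labels,
                             config = model_config()) {
  x <- as.matrix(fingerprints)
  y <- if (inherits(labels, "label_matrix")) labels$labels else labels
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("fingerprints and labels must align")
  if (anyNA(y)) stop("labels contain NA; drop incomplete compounds first")
  idx <- split_indices(nrow(x), config$split, config$seed,
                       strata = activity_strata(y))
  aug <- oversample_actives(x[idx$train, , drop = FALSE],
                            y[idx$train, , drop = FALSE],
                            target = config$oversample_target,
                            seed = config$seed)
  fit <- mlp_train_cpp(aug$features, aug$labels,
                       x[idx$val, , drop = FALSE],
                       y[idx$val, , drop = FALSE],
                       config$hidden, config$dropout, config$lr,
                       config$epochs, config$batch_size, config$seed)
  model <- structure(list(
    weights = fit$weights, biases = fit$biases, config = config,
    sites = colnames(y) %||% as.character(seq_len(ncol(y))),
    best_epoch = fit$best_epoch, val_mcc_trace = fit$val_mcc,
    train_loss_trace = fit$train_loss, splits = idx),
    class = "trained_model")
  p_test <- predict(model, x[idx$test, , drop = FALSE])
  model$report <- metrics_report(y[idx$test, , drop = FALSE], p_test)
  model
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model: %d sites, best epoch %d (val mean MCC %.3f)\n",
    length(x$sites), x$best_epoch, max(x$val_mcc_trace, na.rm = TRUE)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Predict per-site activity probabilities
#'
#' @param object a [train_classifier()] model.
#' @param newdata fingerprint matrix.
#' @param ... unused.
#' @return probability matrix (compounds x sites).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  p <- mlp_forward_cpp(object$weights, object$biases, as.matrix(newdata))
  dimnames(p) <- list(rownames(newdata), object$sites)
  p
}

#' Select multibinders from a prediction matrix
#'
#' A compound is selected when the fraction of sites at which it is
#' predicted active is strictly greater than the threshold.
#'
#' @param pred probability or binary prediction matrix (compounds x
#'   sites).
#' @param site_fraction_threshold fraction-of-sites rule (default 0.70,
#'   strict >).
#' @param prob_threshold probability binarisation cutoff (default 0.5).
#' @return object of class `screening_selection`: list with `selected`
#'   (compound ids), `fraction` (per-compound active-site fraction) and
#'   `threshold`.
#' @export
select_multibinders <- function(pred, site_fraction_threshold = 0.70,
                                prob_threshold = 0.5) {
  pred <- as.matrix(pred)
  act <- pred >= prob_threshold
  frac <- rowMeans(act)
  ids <- rownames(pred) %||% as.character(seq_len(nrow(pred)))
  names(frac) <- ids
  structure(list(selected = ids[frac > site_fraction_threshold],
                 fraction = frac,
                 threshold = site_fraction_threshold),
            class = "screening_selection")
}

#' Screen a compound library with the trained classifier
#'
#' Featurizes the library (in batches), predicts per-site activity and
#' applies the strict fraction-of-sites selection rule.
#'
#' @param model a [train_classifier()] model.
#' @param library named character vector of SMILES, or a pre-computed
#'   fingerprint matrix.
#' @param site_fraction_threshold see [select_multibinders()].
#' @param batch_size compounds featurized/predicted per batch.
#' @return a `screening_selection` (see [select_multibinders()]) with an
#'   extra `rejected` field listing unparseable compounds.
#' @export
screen <- function(model, library, site_fraction_threshold = 0.70,
                   batch_size = 5000L) {
  n_bits <- nrow(model$weights[[1L]])
  if (is.character(library)) {
    ids <- names(library) %||% sprintf("cpd_%d", seq_along(library))
    chunks <- split(seq_along(library),
                    ceiling(seq_along(library) / batch_size))
    fps <- vector("list", length(chunks))
    rejected <- character(0)
    for (k in seq_along(chunks)) {
      fp <- featurize(library[chunks[[k]]], n_bits = n_bits,
                      ids = ids[chunks[[k]]])
      rejected <- c(rejected, attr(fp, "rejected"))
      fps[[k]] <- fp
    }
    fp_all <- do.call(rbind, fps)
    keep <- !(rownames(fp_all) %in% rejected)
    if (!any(keep)) stop("no parseable compounds in library")
    fp_all <- fp_all[keep, , drop = FALSE]
  } else {
    fp_all <- as.matrix(library)
    rejected <- character(0)
  }
  sel <- select_multibinders(predict(model, fp_all),
                             site_fraction_threshold)
  sel$rejected <- rejected
  sel
}

#' Save / load a trained model as plain text
#'
#' The weights go into one delimited text file per layer plus a JSON
#' sidecar holding the architecture and configuration.
#'
#' @param model a [train_classifier()] model.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(model$weights)) {
    utils::write.table(model$weights[[l]],
                       file.path(dir, sprintf("W%d.tsv", l)),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    utils::write.table(model$biases[[l]],
                       file.path(dir, sprintf("b%d.tsv", l)),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  jsonlite::write_json(list(
    n_layers = length(model$weights), sites = model$sites,
    best_epoch = model$best_epoch,
    config = unclass(model$config)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  nl <- meta$n_layers
  weights <- lapply(seq_len(nl), function(l) {
    as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", l))))
  })
  biases <- lapply(seq_len(nl), function(l) {
    as.numeric(utils::read.table(file.path(dir, sprintf("b%d.tsv", l)))[[1L]])
  })
  cfg <- meta$config
  structure(list(weights = lapply(weights, unname), biases = biases,
                 config = do.call(model_config, cfg[names(cfg) %in%
                   names(formals(model_config))]),
                 sites = meta$sites, best_epoch = meta$best_epoch),
            class = "trained_model")
}
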