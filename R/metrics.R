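# Evaluation metrics for the multilabel classifier: Matthews
# correlation per site, subset zero-one loss, Hamming loss and binary
# cross-entropy.

#' Matthews correlation coefficient from confusion counts
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); defined as 0
#' when any factor of the denominator is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (vectorised).
#' @return MCC in \[-1, 1\].
#' @export
#' @examples
#' mcc(1, 2, 1, 1)  # 1/6
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be >= 0")
  if (any(tp + tn + fp + fn == 0)) stop("counts must not all be zero")
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

check_shapes <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("y_true and y_pred must have identical shapes")
  }
  list(t = y_true, p = y_pred)
}

#' Subset zero-one loss
#'
#' Fraction of samples (rows) whose full label set is not predicted
#' exactly.
#'
#' @param y_true,y_pred binary matrices of identical shape.
#' @return loss in \[0, 1\].
#' @export
zero_one_loss <- function(y_true, y_pred) {
  m <- check_shapes(y_true, y_pred)
  mean(rowSums(m$t != m$p) > 0)
}

#' Hamming loss
#'
#' Fraction of individual labels (cells) predicted incorrectly.
#'
#' @param y_true,y_pred binary matrices of identical shape.
#' @return loss in \[0, 1\].
#' @export
hamming_loss <- function(y_true, y_pred) {
  m <- check_shapes(y_true, y_pred)
  mean(m$t != m$p)
}

#' Binary cross-entropy loss
#'
#' Mean of -\[y log p + (1-y) log(1-p)\] over all cells, with predicted
#' probabilities clipped to \[clip, 1-clip\].
#'
#' @param y_true binary matrix.
#' @param p_pred probability matrix of identical shape.
#' @param clip clipping bound (default 1e-7).
#' @return mean BCE (nats).
#' @export
bce_loss <- function(y_true, p_pred, clip = 1e-7) {
  m <- check_shapes(y_true, p_pred)
  p <- pmin(pmax(m$p, clip), 1 - clip)
  -mean(m$t * log(p) + (1 - m$t) * log(1 - p))
}

#' Per-site confusion counts and summary metrics
#'
#' @param y_true binary truth matrix (compounds x sites).
#' @param p_pred probability (or binary) prediction matrix.
#' @param prob_threshold binarisation threshold for probabilities.
#' @return object of class `metrics_report`: list with `confusion`
#'   (sites x \{tp, tn, fp, fn\}), `mcc_per_site` (NA where the truth
#'   column is single-class, i.e. MCC undefined), `mean_mcc` (mean over
#'   defined sites), `zero_one`, `hamming`, `bce`.
#' @export
metrics_report <- function(y_true, p_pred, prob_threshold = 0.5) {
  m <- check_shapes(y_true, p_pred)
  y_hat <- (m$p >= prob_threshold) * 1L
  conf <- t(vapply(seq_len(ncol(m$t)), function(s) {
    t_ <- m$t[, s]; h <- y_hat[, s]
    c(tp = sum(t_ == 1 & h == 1), tn = sum(t_ == 0 & h == 0),
      fp = sum(t_ == 0 & h == 1), fn = sum(t_ == 1 & h == 0))
  }, numeric(4)))
  rownames(conf) <- colnames(m$t) %||% seq_len(ncol(m$t))
  defined <- conf[, "tp"] + conf[, "fn"] > 0 &
             conf[, "tn"] + conf[, "fp"] > 0
  mcc_site <- stats::setNames(rep(NA_real_, nrow(conf)), rownames(conf))
  mcc_site[defined] <- mcc(conf[defined, "tp"], conf[defined, "tn"],
                           conf[defined, "fp"], conf[defined, "fn"])
  structure(list(
    confusion = conf,
    mcc_per_site = mcc_site,
    mean_mcc = mean(mcc_site, na.rm = TRUE),
    zero_one = zero_one_loss(m$t, y_hat),
    hamming = hamming_loss(m$t, y_hat),
    bce = bce_loss(m$t, m$p)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report: mean MCC %.3f | zero-one %.3f | Hamming %.3f | BCE %.3f\n",
    x$mean_mcc, x$zero_one, x$hamming, x$bce))
  cat(sprintf("  sites: %d (%d with defined MCC)\n",
              nrow(x$confusion), sum(!is.na(x$mcc_per_site))))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a [metrics_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(
    mean_mcc = report$mean_mcc, zero_one = report$zero_one,
    hamming = report$hamming, bce = report$bce,
    mcc_per_site = report$mcc_per_site,
    confusion = as.data.frame(report$confusion)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
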