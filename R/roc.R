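#' Mann--Whitney AUC
#'
#' Exact AUC as the probability that a random positive scores above a random
#' negative, ties counted 1/2, computed from midranks.  Identical to the area
#' under the stepwise ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary 0/1 labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stepwise ROC curve
#'
#' ROC points swept over all score thresholds, from (0, 0) to (1, 1).  FPR
#' steps are multiples of `1/n_neg` and TPR steps multiples of `1/n_pos`;
#' tied scores produce diagonal segments.
#'
#' @inheritParams auc_mw
#' @return data.frame with columns `threshold` (score at or above which a
#'   case is called positive; `Inf` for the (0,0) point), `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

.roc_result <- function(scores, labels, unit) {
  pts <- roc_points(scores, labels)
  structure(list(unit = unit,
                 fpr = pts$fpr, tpr = pts$tpr,
                 auc = auc_mw(scores, labels),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.4f (%d pos / %d neg)\n",
              x$unit, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Slice-level ROC/AUC
#'
#' One evaluation unit is one slice: each validation patient contributes one
#' score, TPR steps are 1/n_pos (1/6 at the study validation size) and FPR
#' steps 1/n_neg (1/12).
#'
#' @param scores Per-patient scores for one slice.
#' @param labels Per-patient 0/1 labels.
#' @param unit Label for the evaluation unit.
#' @return A `roc_result`: `unit`, `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
auc_slice <- function(scores, labels, unit = "slice") {
  .roc_result(scores, labels, unit)
}

#' Slab-folded ROC/AUC
#'
#' Folds all slices of a slab into one evaluation: every (validation patient,
#' included slice) pair is a classification instance, so the positive count
#' is `n_pos_patients * n_slices` and likewise for negatives.
#'
#' @param prediction_set data.frame for one (replica, projection, slab,
#'   model_kind), with columns `coordinate`, `patient_id`, `true_label`,
#'   `score`.
#' @return A `roc_result` over all (patient, slice) instances.
#' @export
auc_slab_folded <- function(prediction_set) {
  co <- unique(prediction_set$coordinate)
  counts <- table(prediction_set$patient_id)
  if (length(unique(counts)) != 1L || unique(counts) != length(co)) {
    missing <- vapply(split(prediction_set$coordinate,
                            prediction_set$patient_id),
                      function(v) paste(setdiff(co, v), collapse = ","),
                      character(1))
    stop("missing slice scores for coordinate(s): ",
         paste(unique(missing[nzchar(missing)]), collapse = "; "))
  }
  .roc_result(prediction_set$score, prediction_set$true_label,
              unit = sprintf("%s slab %s (folded, %d slices)",
                             prediction_set$projection[1L],
                             prediction_set$slab[1L], length(co)))
}

#' AUC table of an ensemble
#'
#' Slice-level AUC for every (projection, slab, coordinate, replica,
#' model_kind) cell, or slab-folded AUC per (projection, slab, replica,
#' model_kind).
#'
#' @param ensemble A `slice_ensemble` (or its `predictions` data.frame).
#' @param level `"slice"` or `"slab"` (folded).
#' @return data.frame of AUCs, one row per evaluation unit and replica.
#' @export
auc_table <- function(ensemble, level = c("slice", "slab")) {
  level <- match.arg(level)
  preds <- if (inherits(ensemble, "slice_ensemble")) ensemble$predictions
           else ensemble
  dt <- data.table::as.data.table(preds)
  score <- true_label <- projection <- slab <- coordinate <- NULL
  by <- if (level == "slice")
    c("projection", "slab", "coordinate", "replica", "model_kind")
  else c("projection", "slab", "replica", "model_kind")
  out <- dt[, list(auc = auc_mw(score, true_label)), by = by]
  as.data.frame(out)
}

#' Summarize a replica AUC distribution
#'
#' Median, quartiles (linear-interpolation convention) and boxplot outliers
#' beyond 1.5 times the interquartile range from the quartiles.
#'
#' @param aucs Numeric vector of at least 4 AUC values (one per replica).
#' @return List of class `auc_distribution`: `median`, `q25`, `q75`,
#'   `outliers` (indices into `aucs`), `aucs`.
#' @export
summarize_distribution <- function(aucs) {
  if (length(aucs) < 4L)
    stop("need at least 4 AUC values to summarize a distribution")
  q <- stats::quantile(aucs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  out <- which(aucs > q[3L] + 1.5 * iqr | aucs < q[1L] - 1.5 * iqr)
  structure(list(median = q[2L], q25 = q[1L], q75 = q[3L],
                 outliers = out, aucs = aucs),
            class = "auc_distribution")
}

#' @export
print.auc_distribution <- function(x, ...) {
  cat(sprintf("<auc_distribution> n=%d median %.3f [%.3f, %.3f], %d outlier(s)\n",
              length(x$aucs), x$median, x$q25, x$q75, length(x$outliers)))
  invisible(x)
}
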