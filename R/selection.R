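## one (slice, replica) real-vs-null comparison; returns the record fields
.compare_pair <- function(real, null, delta_override, z_crit) {
  ord <- order(real$patient_id)
  real <- real[ord, ]; null <- null[order(null$patient_id), ]
  labels <- real$true_label
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  delta <- if (is.null(delta_override)) auc_granularity(n_pos, n_neg)
           else delta_override
  auc_real <- auc_mw(real$score, labels)
  auc_null <- auc_mw(null$score, labels)
  admissible <- abs(auc_null - 0.5) <= delta + 1e-12
  dl <- tryCatch(delong_test(real$score, null$score, labels),
                 error = function(e) NULL)
  untestable <- is.null(dl)
  z <- if (untestable) NA_real_ else dl$z
  p <- if (untestable) NA_real_ else dl$p_value
  selected <- !untestable && admissible && z > z_crit && auc_real > auc_null
  list(auc_real = auc_real, auc_null = auc_null, delta = delta,
       null_admissible = admissible, z = z, p = p,
       untestable = untestable, selected = selected)
}

#' Real-versus-null selection records for every slice and replica
#'
#' For each (projection, slab, coordinate, replica) cell, compares the real
#' discriminator's slice AUC with its index-matched null twin: the null must
#' be admissible (AUC within `0.5 +/- delta`, where `delta` is the discrete
#' AUC granularity `1/(n_pos * n_neg)` of the validation set), DeLong's
#' paired Z must exceed `z_crit`, and the real AUC must lie on the
#' towards-1 side of the null.  Pairs whose DeLong variance is degenerate are
#' flagged `untestable` and never selected.
#'
#' @param ensemble A `slice_ensemble` (trained with `null_models = TRUE`), or
#'   its `predictions` data.frame.
#' @param z_crit Z threshold (default 1.96, i.e. p < 0.05).
#' @param delta Optional admissibility half-width override; by default the
#'   per-replica validation granularity is used.
#' @return data.frame with one row per (slice, replica):
#'   `projection`, `slab`, `coordinate`, `replica`, `auc_real`, `auc_null`,
#'   `delta`, `null_admissible`, `z`, `p`, `untestable`, `selected`.
#' @export
selection_records <- function(ensemble, z_crit = 1.96, delta = NULL) {
  preds <- if (inherits(ensemble, "slice_ensemble")) ensemble$predictions
           else ensemble
  if (!all(c("real", "null") %in% unique(preds$model_kind)))
    stop("selection requires both real and null model predictions")
  dt <- data.table::as.data.table(preds)
  model_kind <- patient_id <- true_label <- score <- NULL
  out <- dt[, {
    real <- .SD[model_kind == "real"]
    null <- .SD[model_kind == "null"]
    if (nrow(real) && nrow(null))
      .compare_pair(as.data.frame(real), as.data.frame(null), delta, z_crit)
    else NULL
  }, by = c("projection", "slab", "coordinate", "replica")]
  as.data.frame(out)
}

#' Significant (slice, classifier) pairs
#'
#' Filters the selection records to the pairs passing the full criterion and
#' summarizes them per projection, including the classifiers (replicas)
#' significant on more than one slice of the same projection.
#'
#' @param records Output of [selection_records()].
#' @return List of class `slice_selection`: `pairs` (selected records),
#'   `slices` (per-projection sorted unique significant coordinates),
#'   `multi_slice` (per projection, replica ids selected on more than one
#'   slice), `n_pairs`, `n_tests`.
#' @export
select_significant <- function(records) {
  sel <- records[records$selected %in% TRUE, , drop = FALSE]
  projs <- unique(records$projection)
  slices <- lapply(stats::setNames(projs, projs), function(p)
    sort(unique(sel$coordinate[sel$projection == p])))
  multi <- lapply(stats::setNames(projs, projs), function(p) {
    s <- sel[sel$projection == p, ]
    cnt <- table(s$replica)
    as.integer(names(cnt)[cnt > 1L])
  })
  structure(list(pairs = sel, slices = slices, multi_slice = multi,
                 n_pairs = nrow(sel), n_tests = nrow(records)),
            class = "slice_selection")
}

#' @export
print.slice_selection <- function(x, ...) {
  cat(sprintf("<slice_selection> %d significant (slice, classifier) pairs of %d tests\n",
              x$n_pairs, x$n_tests))
  for (p in names(x$slices)) {
    cat(sprintf("  %s: %d slice(s)", p, length(x$slices[[p]])))
    if (length(x$slices[[p]]))
      cat(" at ", paste(x$slices[[p]], collapse = ", "), sep = "")
    if (length(x$multi_slice[[p]]))
      cat(sprintf(" | classifier(s) %s significant on >1 slice",
                  paste(x$multi_slice[[p]], collapse = ", ")))
    cat("\n")
  }
  invisible(x)
}
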