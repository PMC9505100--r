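#' Train one slab discriminator and score its validation slices
#'
#' Second training step for one (replica, projection, slab) cell: the
#' backbone is fit on every included slice of the slab for the replica's
#' training patients, labeled with the patient's progression label, and then
#' scores every (validation patient, slice) pair.  With
#' `shuffle_labels = TRUE` the training labels are permuted across training
#' patients (class counts unchanged) to produce the paired null model; the
#' validation set and every other ingredient stay identical.
#'
#' @param features Output of [slice_features()] for one projection.
#' @param labels Named integer vector of 0/1 progression labels, indexed by
#'   patient id.
#' @param split A `replica_split` from [make_replicas()].
#' @param slab_id Slab 1--4.
#' @param classifier A `slice_classifier` backbone.
#' @param location_model Optional `location_model` whose slab probabilities
#'   are appended to the pixel features (the two-step structure).
#' @param shuffle_labels Train on permuted labels (null model).
#' @param seed Seed for the label permutation.
#' @return data.frame with columns `replica`, `projection`, `slab`,
#'   `coordinate`, `patient_id`, `true_label`, `score`, `model_kind`; one row
#'   per (validation patient, included slice of the slab).
#' @export
train_discriminator <- function(features, labels, split, slab_id, classifier,
                                location_model = NULL, shuffle_labels = FALSE,
                                seed = NULL) {
  stopifnot(inherits(split, "replica_split"),
            inherits(classifier, "slice_classifier"))
  info <- features$info
  in_slab <- which(info$slab == slab_id)
  if (!length(in_slab))
    stop(sprintf("slab %d has no included slices", slab_id))
  x <- .augment_features(features, location_model)
  train_labels <- labels[split$train_ids]
  if (shuffle_labels) {
    if (!is.null(seed)) set.seed(seed)
    train_labels <- stats::setNames(sample(unname(train_labels)),
                                    names(train_labels))
  }
  tr_rows <- in_slab[info$subject_id[in_slab] %in% split$train_ids]
  va_rows <- in_slab[info$subject_id[in_slab] %in% split$val_ids]
  ytr <- factor(train_labels[info$subject_id[tr_rows]], levels = 0:1)
  model <- classifier$fit(x[tr_rows, , drop = FALSE], ytr)
  scores <- classifier$prob(model, x[va_rows, , drop = FALSE])
  data.frame(replica = split$replica_id,
             projection = info$projection[va_rows],
             slab = slab_id,
             coordinate = info$coordinate[va_rows],
             patient_id = info$subject_id[va_rows],
             true_label = unname(labels[info$subject_id[va_rows]]),
             score = as.numeric(scores),
             model_kind = if (shuffle_labels) "null" else "real")
}

#' Fit the slice-level discriminator ensemble
#'
#' The core model-fitting routine: builds the stratified replica splits,
#' pre-trains the slab-location model per projection (first training step),
#' then trains one progression discriminator per (replica, projection, slab)
#' cell together with its label-permutation null twin, recording validation
#' scores for every included slice.
#'
#' @param volumes List of `mri_volume` objects (normalized, MNI grid).
#' @param patients Patient table with `patient_id` and either a `label`
#'   column or `edss_baseline`/`edss_followup` from which labels are derived.
#' @param projs Projections to train (default all three).
#' @param n_replicas Number of ensemble replicas (study design: 100).
#' @param train_fraction Training fraction per replica (default 0.9).
#' @param classifier Backbone, default [ridge_classifier()].
#' @param pretrain Run the slab-location pre-training step (default TRUE).
#' @param feature_dim Pooled pixel grid per slice (default `c(8, 8)`).
#' @param null_models Also train the permuted-label null twin of every
#'   discriminator (default TRUE).
#' @param seed Master seed; replica splits, label permutations and the
#'   pre-training holdout all derive their sub-seeds from it.
#' @return Object of class `slice_ensemble` with elements `predictions`
#'   (long data.frame of validation scores), `replicas`, `location`
#'   (per-projection location models), `labels`, and the call settings.
#' @export
fit_slice_ensemble <- function(volumes, patients, projs = projections(),
                               n_replicas = 100L, train_fraction = 0.9,
                               classifier = ridge_classifier(),
                               pretrain = TRUE, feature_dim = c(8L, 8L),
                               null_models = TRUE, seed = 1L) {
  projs <- vapply(projs, .match_projection, character(1), USE.NAMES = FALSE)
  if (!("label" %in% names(patients))) patients <- label_patients(patients)
  labels <- stats::setNames(as.integer(patients$label),
                            as.character(patients$patient_id))
  replicas <- make_replicas(patients, n_replicas, train_fraction, seed)
  set.seed(seed + 1L)
  shuffle_seeds <- array(sample.int(.Machine$integer.max - 1L,
                                    n_replicas * length(projs) * 4L),
                         dim = c(n_replicas, length(projs), 4L))
  location <- list()
  preds <- list(); k <- 0L
  for (pi in seq_along(projs)) {
    p <- projs[pi]
    feats <- slice_features(volumes, p, feature_dim)
    loc <- NULL
    if (pretrain) {
      loc <- pretrain_location(classifier, feats, seed = seed + 2L)
      feats$features <- .augment_features(feats, loc)  # append once
      location[[p]] <- loc
    }
    for (split in replicas) {
      for (slab_id in 1:4) {
        k <- k + 1L
        preds[[k]] <- train_discriminator(feats, labels, split, slab_id,
                                          classifier)
        if (null_models) {
          k <- k + 1L
          preds[[k]] <- train_discriminator(
            feats, labels, split, slab_id, classifier,
            shuffle_labels = TRUE,
            seed = shuffle_seeds[split$replica_id, pi, slab_id])
        }
      }
    }
  }
  structure(list(predictions = do.call(rbind, preds),
                 replicas = replicas,
                 location = location,
                 labels = labels,
                 projections = projs,
                 n_replicas = n_replicas,
                 classifier = classifier$name,
                 seed = seed),
            class = "slice_ensemble")
}

#' @export
print.slice_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<slice_ensemble> %d replicas x %d projection(s) x 4",
                     " slabs, backbone %s\n"),
              x$n_replicas, length(x$projections), x$classifier))
  if (length(x$location))
    cat(sprintf("  slab-location accuracy: %s\n",
                paste(sprintf("%s %.2f", names(x$location),
                              vapply(x$location, `[[`, numeric(1), "accuracy")),
                      collapse = ", ")))
  cat(sprintf("  %d validation score rows (%s models)\n",
              nrow(x$predictions),
              paste(unique(x$predictions$model_kind), collapse = "/")))
  invisible(x)
}

#' @export
summary.slice_ensemble <- function(object, ...) {
  tab <- auc_table(object)
  agg <- stats::aggregate(auc ~ projection + slab + model_kind, data = tab,
                          FUN = stats::median)
  names(agg)[names(agg) == "auc"] <- "median_auc"
  structure(list(by_slab = agg, n_models = nrow(unique(
    tab[, c("projection", "slab", "replica", "model_kind")]))),
    class = "summary.slice_ensemble")
}

#' @export
print.summary.slice_ensemble <- function(x, ...) {
  cat(sprintf("slice ensemble: %d trained discriminators\n", x$n_models))
  cat("median slice-level AUC by projection/slab:\n")
  print(x$by_slab, row.names = FALSE)
  invisible(x)
}

#' Boxplot of per-slice AUC distributions
#'
#' Mirrors the slice-level AUC summary figure: one box per slice coordinate,
#' built from the replica AUC distribution, with slab boundaries marked.
#'
#' @param x A `slice_ensemble`.
#' @param projection Projection to display (default the first trained one).
#' @param model_kind `"real"` or `"null"`.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the per-slice AUC table used for the plot.
#' @export
plot.slice_ensemble <- function(x, projection = x$projections[1L],
                                model_kind = "real", ...) {
  tab <- auc_table(x)
  tab <- tab[tab$projection == projection & tab$model_kind == model_kind, ]
  graphics::boxplot(auc ~ coordinate, data = tab,
                    xlab = sprintf("%s slice coordinate", projection),
                    ylab = "validation AUC",
                    main = sprintf("%s models, %s projection", model_kind,
                                   projection), ...)
  graphics::abline(h = 0.5, lty = 2)
  for (b in slab_definitions(projection)$lo[-1])
    graphics::abline(v = b - min(tab$coordinate) + 0.5, col = "grey60")
  invisible(tab)
}
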