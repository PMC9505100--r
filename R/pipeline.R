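#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run.  Defaults follow the study
#' design (100 replicas, 90% training fraction, Z threshold 1.96, all three
#' projections); scale `n_replicas` and `projs` down for desk-scale runs.
#'
#' @param input A [generator_config()] for a synthetic cohort, or a
#'   directory written by [write_cohort()].
#' @param projs Projections to analyze.
#' @param n_replicas Ensemble replicas, at least 4 (quartiles must be
#'   computable).
#' @param train_fraction Training fraction per replica.
#' @param classifier Backbone, default [ridge_classifier()].
#' @param pretrain Run the slab-location pre-training step.
#' @param feature_dim Pooled pixel grid per slice.
#' @param z_crit DeLong Z threshold (default 1.96).
#' @param delta Optional admissibility half-width override (default: the
#'   per-replica validation granularity).
#' @param count_rule Voxel counting rule for the 3D map.
#' @param seed Master seed for splits, permutations and pre-training.
#' @param out_dir Optional output directory for tables, report JSON and the
#'   NIfTI mask.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = generator_config(),
                            projs = projections(),
                            n_replicas = 100L,
                            train_fraction = 0.9,
                            classifier = ridge_classifier(),
                            pretrain = TRUE,
                            feature_dim = c(8L, 8L),
                            z_crit = 1.96,
                            delta = NULL,
                            count_rule = "product_of_counts",
                            seed = 1L,
                            out_dir = NULL) {
  if (n_replicas < 4L)
    stop("n_replicas must be at least 4 so that AUC quartiles are computable")
  if (z_crit <= 0) stop("z_crit must be positive")
  if (!is.null(delta) && delta <= 0) stop("delta must be positive")
  structure(list(input = input, projs = projs, n_replicas = as.integer(n_replicas),
                 train_fraction = train_fraction, classifier = classifier,
                 pretrain = pretrain, feature_dim = feature_dim,
                 z_crit = z_crit, delta = delta, count_rule = count_rule,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: cohort input (synthetic generation or a
#' cohort directory), EDSS labeling, volume preparation (normalization and
#' slice geometry), replica-ensemble training with null twins, slice-level
#' ROC/AUC, real-versus-null selection, and the 3D voxel intersection map.
#' Reruns with an identical configuration reproduce every output, since the
#' default backbone is deterministic and all randomness derives from the
#' configured seeds.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: a list with sections `input`,
#'   `labeling`, `prep`, `training`, `roc`, `selection`, `mapping`, plus
#'   `seeds` and the selection table.  When `config$out_dir` is set the
#'   prediction/AUC/selection tables (CSV), a `report.json` and the binary
#'   mask (NIfTI) are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- .stage("input", {
    if (inherits(config$input, "generator_config")) generate_cohort(config$input)
    else read_cohort(config$input)
  })
  patients <- .stage("labeling", {
    p <- label_patients(cohort$patients)
    if (!is.null(cohort$truth) &&
        any(p$label != cohort$truth$labels[p$patient_id]))
      stop("EDSS-derived labels disagree with the cohort truth labels")
    p
  })
  volumes <- .stage("prep", lapply(cohort$volumes, normalize_intensity))
  geometry <- .stage("prep", {
    st <- lapply(config$projs, function(pr) slice_volume(volumes[[1L]], pr))
    data.frame(projection = config$projs,
               n_slices = vapply(st, function(s) nrow(s$info), integer(1)),
               n_included = vapply(st, function(s) sum(s$info$included),
                                   integer(1)))
  })
  ensemble <- .stage("training", fit_slice_ensemble(
    volumes, patients, projs = config$projs, n_replicas = config$n_replicas,
    train_fraction = config$train_fraction, classifier = config$classifier,
    pretrain = config$pretrain, feature_dim = config$feature_dim,
    null_models = TRUE, seed = config$seed))
  aucs <- .stage("roc", auc_table(ensemble, level = "slice"))
  records <- .stage("selection",
                    selection_records(ensemble, z_crit = config$z_crit,
                                      delta = config$delta))
  selection <- .stage("selection", select_significant(records))
  mapping <- .stage("mapping", {
    if (all(c("coronal", "sagittal", "axial") %in% config$projs)) {
      sel <- selection$pairs
      co <- function(p) sel$coordinate[sel$projection == p]
      suppressWarnings(intersect_slices(co("coronal"), co("sagittal"),
                                        co("axial"),
                                        count_rule = config$count_rule))
    } else NULL
  })
  report <- structure(list(
    input = list(n_patients = nrow(patients),
                 source = if (inherits(config$input, "generator_config"))
                   "synthetic" else config$input),
    labeling = list(n_progressed = sum(patients$label),
                    prevalence = mean(patients$label)),
    prep = geometry,
    training = list(n_replicas = config$n_replicas,
                    n_discriminators = nrow(enumerate_discriminators(
                      config$n_replicas, config$projs)),
                    location_accuracy = vapply(ensemble$location, `[[`,
                                               numeric(1), "accuracy")),
    roc = aucs,
    selection = selection,
    records = records,
    mapping = mapping,
    seeds = list(master = config$seed,
                 generator = if (inherits(config$input, "generator_config"))
                   config$input$seed else NA_integer_),
    ensemble = ensemble
  ), class = "pipeline_report")
  if (!is.null(config$out_dir))
    .write_report(report, ensemble, cohort, config)
  report
}

.write_report <- function(report, ensemble, cohort, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ensemble$predictions,
                   file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, file.path(config$out_dir, "auc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$records, file.path(config$out_dir, "selection.csv"),
                   row.names = FALSE)
  sel <- report$selection
  js <- list(
    n_patients = report$input$n_patients,
    n_progressed = report$labeling$n_progressed,
    significant_slices = sel$slices,
    multi_slice_classifiers = sel$multi_slice,
    auc_range = if (nrow(sel$pairs))
      lapply(split(sel$pairs$auc_real, sel$pairs$projection), range)
    else list(),
    n_significant_pairs = sel$n_pairs,
    n_tests = sel$n_tests,
    voxel_count = if (!is.null(report$mapping)) report$mapping$count else NA,
    seeds = report$seeds
  )
  jsonlite::write_json(js, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$mapping) && nrow(report$mapping$voxels))
    export_mask(report$mapping, cohort$volumes[[1L]],
                file.path(config$out_dir, "significant_voxels.nii.gz"))
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("=== slice-ensemble pipeline report ===\n")
  cat(sprintf("cohort: %d patients, %d progressed (%.0f%%)\n",
              x$input$n_patients, x$labeling$n_progressed,
              100 * x$labeling$prevalence))
  cat("slice geometry:\n"); print(x$prep, row.names = FALSE)
  cat(sprintf("training: %d discriminators (+%d null twins)\n",
              x$training$n_discriminators, x$training$n_discriminators))
  if (length(x$training$location_accuracy))
    cat(sprintf("slab-location accuracy: %s\n",
                paste(sprintf("%s %.2f", names(x$training$location_accuracy),
                              x$training$location_accuracy), collapse = ", ")))
  print(x$selection)
  if (!is.null(x$mapping)) print(x$mapping)
  invisible(x)
}
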