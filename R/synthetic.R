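#' Define a cuboidal signal region
#'
#' @param lo,hi Integer triples of 0-based voxel coordinates (x, y, z),
#'   inclusive corners with `lo <= hi` componentwise.
#' @return A `signal_region` list.
#' @export
signal_region <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(hi < lo)) stop("signal_region requires lo <= hi componentwise")
  structure(list(lo = lo, hi = hi), class = "signal_region")
}

.check_region <- function(region, grid_shape) {
  if (any(region$lo < 0L) || any(region$hi > grid_shape - 1L))
    stop(sprintf(
      "signal region [%s]-[%s] lies outside the %s grid",
      paste(region$lo, collapse = ","), paste(region$hi, collapse = ","),
      paste(grid_shape, collapse = "x")))
  invisible(region)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study cohort: 181 patients with a 62/181 (34%)
#' progression prevalence on the 2 mm MNI grid, with one frontal signal box
#' where progressed patients' intensities are elevated by `effect_size`
#' against additive Gaussian noise of s.d. `noise_sd` (both in normalized
#' 0--255 intensity units).
#'
#' @param n_patients Cohort size.
#' @param prevalence Fraction of progressed patients, strictly in (0, 1);
#'   `round(n_patients * prevalence)` must be at least 1.
#' @param grid_shape Voxel grid, default `c(91, 109, 91)`.
#' @param signal_regions List of [signal_region()] boxes carrying class
#'   signal.
#' @param effect_size Intensity offset added inside the signal regions for
#'   progressed patients (normalized units, default 30).
#' @param noise_sd Additive noise s.d. (normalized units, default 20).
#' @param base_intensity Intensity scale of the smooth anatomy-like field
#'   modulating the brain interior (default 120).
#' @param brain_mask_kind `"ellipsoid"` (inscribed in the grid, the
#'   deterministic default) or `"template_like"` (a user-supplied binary
#'   array passed via `mask`).
#' @param mask Binary 3D array, required when
#'   `brain_mask_kind = "template_like"`.
#' @param seed Integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 181L,
                             prevalence = 62 / 181,
                             grid_shape = c(91L, 109L, 91L),
                             signal_regions = list(
                               signal_region(c(30L, 77L, 42L),
                                             c(60L, 95L, 56L))),
                             effect_size = 30,
                             noise_sd = 20,
                             base_intensity = 120,
                             brain_mask_kind = c("ellipsoid", "template_like"),
                             mask = NULL,
                             seed = 1L) {
  brain_mask_kind <- match.arg(brain_mask_kind)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L))
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be strictly between 0 and 1")
  if (round(n_patients * prevalence) < 1)
    stop("round(n_patients * prevalence) must be at least 1")
  lapply(signal_regions, .check_region, grid_shape = grid_shape)
  if (brain_mask_kind == "template_like") {
    if (is.null(mask) || !all(dim(mask) == grid_shape))
      stop("template_like mask must be a binary array matching grid_shape")
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 grid_shape = grid_shape, signal_regions = signal_regions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 base_intensity = base_intensity,
                 brain_mask_kind = brain_mask_kind, mask = mask,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## ellipsoid inscribed in the grid, semi-axes (d-1)/2 about the grid centre
.ellipsoid_mask <- function(grid_shape) {
  cen <- (grid_shape - 1) / 2
  ax <- pmax(cen, 0.5)
  gx <- ((seq_len(grid_shape[1]) - 1 - cen[1]) / ax[1])^2
  gy <- ((seq_len(grid_shape[2]) - 1 - cen[2]) / ax[2])^2
  gz <- ((seq_len(grid_shape[3]) - 1 - cen[3]) / ax[3])^2
  d2 <- outer(outer(gx, gy, `+`), gz, `+`)
  d2 <= 1
}

## smooth, axis-asymmetric intensity field emulating anatomy: low-frequency
## modulation with distinct frequency and phase per axis, so slices from
## different slabs have distinguishable intensity profiles (as real brain
## slices do) while remaining identical across patients
.anatomy_field <- function(grid_shape, base_intensity) {
  u <- function(n) (seq_len(n) - 1) / (n - 1)
  fx <- 0.25 * sin(pi * (1.3 * u(grid_shape[1]) + 0.20))
  fy <- 0.25 * sin(pi * (1.7 * u(grid_shape[2]) + 0.45))
  fz <- 0.25 * sin(pi * (2.3 * u(grid_shape[3]) + 0.80))
  base_intensity * (1 + outer(outer(fx, fy, `+`), fz, `+`))
}

.region_index <- function(region, grid_shape) {
  xs <- (region$lo[1]:region$hi[1]) + 1L
  ys <- (region$lo[2]:region$hi[2]) + 1L
  zs <- (region$lo[3]:region$hi[3]) + 1L
  idx <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx[, 1] + (idx[, 2] - 1L) * grid_shape[1] +
    (idx[, 3] - 1L) * grid_shape[1] * grid_shape[2]
}

## EDSS baselines sampled from the half-point grid excluding 0.5 (the branch
## the progression rule leaves open); follow-up constructed to satisfy or
## violate the baseline-dependent threshold according to the truth label
.sample_edss <- function(labels) {
  pool <- c(0, seq(1, 5, by = 0.5), seq(5.5, 7.5, by = 0.5))
  n <- length(labels)
  base <- sample(pool, n, replace = TRUE)
  thr <- ifelse(base == 0, 1.5, ifelse(base >= 5.5, 0.5, 1.0))
  extra <- sample(c(0, 0.5), n, replace = TRUE)
  up <- pmin(10, base + thr + extra)
  # non-progressing increment strictly below threshold, kept on the grid
  stay_inc <- ifelse(base == 0, sample(c(0, 0.5, 1), n, replace = TRUE),
                     ifelse(base >= 5.5, sample(c(-0.5, 0), n, replace = TRUE),
                            sample(c(-0.5, 0, 0.5), n, replace = TRUE)))
  stay <- pmin(10, pmax(0, base + stay_inc))
  data.frame(edss_baseline = base,
             edss_followup = ifelse(labels == 1L, up, stay))
}

#' Generate a synthetic cohort with planted regional class signal
#'
#' Produces brain-like volumes on the configured grid (zero outside the brain
#' mask, Gaussian intensity noise inside, values generated directly on the
#' normalized 0--255 scale), a patient table whose EDSS pairs reproduce the
#' truth labels under the progression rule, and the ground-truth label and
#' signal-region record.  Progressed patients' intensities are elevated by
#' `effect_size` inside every signal region.  Exactly
#' `round(n_patients * prevalence)` patients are positive.  Deterministic
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: list with `volumes` (list
#'   of `mri_volume`), `patients` (data.frame `patient_id`, `site`,
#'   `edss_baseline`, `edss_followup`), and `truth` (list with `labels` and
#'   `signal_regions`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  gs <- config$grid_shape
  n_pos <- as.integer(round(n * config$prevalence))
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L
  ids <- sprintf("P%03d", seq_len(n))
  edss <- .sample_edss(labels)
  patients <- data.frame(patient_id = ids,
                         site = rep_len(c("site1", "site2"), n),
                         edss)
  mask <- if (config$brain_mask_kind == "ellipsoid") .ellipsoid_mask(gs)
          else config$mask != 0
  idx_mask <- which(mask)
  idx_sig <- lapply(config$signal_regions, .region_index, grid_shape = gs)
  anatomy <- .anatomy_field(gs, config$base_intensity)[idx_mask]
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    arr <- array(0, dim = gs)
    arr[idx_mask] <- pmin(255, pmax(0, anatomy +
                                      stats::rnorm(length(idx_mask),
                                                   sd = config$noise_sd)))
    if (labels[i] == 1L) {
      for (idx in idx_sig) {
        inside <- idx[mask[idx]]
        arr[inside] <- pmin(255, arr[inside] + config$effect_size)
      }
    }
    volumes[[i]] <- as_volume(arr, subject_id = ids[i])
  }
  names(labels) <- ids
  structure(list(volumes = volumes, patients = patients,
                 truth = list(labels = labels,
                              signal_regions = config$signal_regions),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d progressed), grid %s\n",
              length(x$volumes), sum(x$truth$labels),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One NIfTI volume per patient, a CSV patient table
#' (`patient_id,site,edss_baseline,edss_followup`) and a JSON truth manifest.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if missing).
#' @return Manifest list with elements `volumes` (named paths), `patients`
#'   and `truth` (file paths).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  vol_paths <- character(0)
  for (v in cohort$volumes) {
    p <- file.path(directory, paste0(v$subject_id, ".nii.gz"))
    write_volume(v, p)
    vol_paths[v$subject_id] <- p
  }
  csv <- file.path(directory, "patients.csv")
  utils::write.csv(cohort$patients, csv, row.names = FALSE)
  truth <- file.path(directory, "truth.json")
  jsonlite::write_json(
    list(labels = as.list(cohort$truth$labels),
         signal_regions = lapply(cohort$truth$signal_regions,
                                 function(r) list(lo = r$lo, hi = r$hi))),
    truth, auto_unbox = TRUE)
  list(volumes = vol_paths, patients = csv, truth = truth)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory holding the NIfTI volumes, `patients.csv` and
#'   `truth.json`.
#' @return A `synthetic_cohort` (without a generator config).
#' @export
read_cohort <- function(directory) {
  csv <- file.path(directory, "patients.csv")
  if (!file.exists(csv)) stop(sprintf("no patients.csv under '%s'", directory))
  patients <- utils::read.csv(csv, stringsAsFactors = FALSE)
  volumes <- lapply(patients$patient_id, function(id)
    read_volume(file.path(directory, paste0(id, ".nii.gz")), subject_id = id))
  truth <- NULL
  tj <- file.path(directory, "truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj)
    labels <- vapply(raw$labels, as.integer, integer(1))
    truth <- list(labels = labels,
                  signal_regions = lapply(raw$signal_regions, function(r)
                    signal_region(unlist(r$lo), unlist(r$hi))))
  }
  structure(list(volumes = volumes, patients = patients, truth = truth,
                 config = NULL),
            class = "synthetic_cohort")
}
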