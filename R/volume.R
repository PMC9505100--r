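#' Voxel-to-world affine of the 2 mm MNI grid
#'
#' @return 4x4 matrix mapping 0-based voxel indices of the 91x109x91 grid to
#'   MNI millimetre coordinates (RAS world axes, radiological x flip).
#' @export
mni_affine_2mm <- function() {
  aff <- diag(c(-2, 2, 2, 1))
  aff[1:3, 4] <- c(90, -126, -72)
  aff
}

#' Construct a brain volume
#'
#' @param intensities 3D numeric array of non-negative voxel intensities.
#' @param subject_id Subject identifier.
#' @param affine 4x4 voxel-to-mm matrix (default the 2 mm MNI affine).
#' @return An object of class `mri_volume`: a list with elements
#'   `intensities`, `grid_shape`, `affine`, `subject_id`.
#' @export
as_volume <- function(intensities, subject_id = "subject",
                      affine = mni_affine_2mm()) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(intensities = intensities,
                 grid_shape = dim(intensities),
                 affine = affine,
                 subject_id = as.character(subject_id)),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> subject %s, grid %s, intensity range [%.3g, %.3g]\n",
              x$subject_id, paste(x$grid_shape, collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Normalize voxel intensities to a 0--255 range
#'
#' Linear per-volume rescaling so that the maximum intensity equals 255 and
#' zero maps to zero.  Shape and the zero set are preserved; a volume whose
#' maximum already equals 255 is returned unchanged.
#'
#' @param volume An `mri_volume` with non-negative intensities and a positive
#'   maximum.
#' @return The volume with rescaled intensities.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "mri_volume"))
  mx <- max(volume$intensities)
  if (mx <= 0)
    stop(sprintf("cannot normalize all-zero volume for subject %s",
                 volume$subject_id))
  volume$intensities <- volume$intensities * (255 / mx)
  volume
}

.slice_pixels <- function(arr, projection, coordinate) {
  idx <- coordinate + 1L  # 0-based MNI voxel coordinate -> R index
  switch(projection,
         sagittal = arr[idx, , ],
         coronal  = arr[, idx, ],
         axial    = arr[, , idx])
}

#' Cut a volume into analysis slices along one projection
#'
#' Extracts one slice per coordinate of the projection's analysis range
#' (79 coronal, 64 sagittal, 62 axial), assigns each to its slab, and flags
#' inclusion: a slice enters the analysis when at least 10% of its pixels are
#' non-zero.
#'
#' @param volume A normalized `mri_volume` on the standard 91x109x91 grid
#'   (any grid large enough to contain the analysis ranges is accepted).
#' @param projection One of `"coronal"`, `"sagittal"`, `"axial"`.
#' @param min_nonzero Minimum fraction of non-zero pixels for inclusion
#'   (default 0.10).
#' @return An object of class `slice_stack`: list with `pixels` (list of 2D
#'   matrices) and `info` (data.frame `subject_id`, `projection`,
#'   `coordinate`, `slab`, `included`).
#' @export
slice_volume <- function(volume, projection, min_nonzero = 0.10) {
  stopifnot(inherits(volume, "mri_volume"))
  projection <- .match_projection(projection)
  ax <- .projection_axis(projection)
  rng <- analysis_range(projection)
  if (volume$grid_shape[ax] < rng[2L] + 1L) {
    stop(sprintf(
      "grid extent %d along the %s axis cannot host the analysis range [%d, %d]",
      volume$grid_shape[ax], projection, rng[1L], rng[2L]))
  }
  coords <- rng[1L]:rng[2L]
  pixels <- lapply(coords, function(co)
    .slice_pixels(volume$intensities, projection, co))
  included <- vapply(pixels, function(p) mean(p != 0) >= min_nonzero, logical(1))
  info <- data.frame(subject_id = volume$subject_id,
                     projection = projection,
                     coordinate = coords,
                     slab = assign_slab(projection, coords),
                     included = included)
  structure(list(pixels = pixels, info = info), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %s, %d slices (%d included), subject %s\n",
              x$info$projection[1L], nrow(x$info), sum(x$info$included),
              x$info$subject_id[1L]))
  invisible(x)
}

## bilinear resize of a matrix to nr x nc (used for the 224x224 image export
## and for classifier feature pooling)
.resize_bilinear <- function(m, nr, nc) {
  .interp_weights <- function(n_in, n_out) {
    # sample positions at pixel centres
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    lo <- pmax(1L, pmin(n_in, floor(pos)))
    hi <- pmin(n_in, lo + 1L)
    w <- pos - lo
    w[hi == lo] <- 0
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo)] <- 1 - w
    W[cbind(seq_len(n_out), hi)] <- W[cbind(seq_len(n_out), hi)] + w
    W
  }
  Wr <- .interp_weights(nrow(m), nr)
  Wc <- .interp_weights(ncol(m), nc)
  Wr %*% m %*% t(Wc)
}

## linear contrast stretch to the full 0-255 range
.contrast_stretch <- function(m) {
  r <- range(m)
  if (r[2L] > r[1L]) (m - r[1L]) * (255 / (r[2L] - r[1L])) else m * 0
}

#' Export slices to files
#'
#' Writes one file per slice, named `<subject>_<projection>_<coordinate>`.
#' `"array"` writes the raw pixel matrix as tab-separated text (lossless; the
#' analysis path consumes arrays).  `"png"` writes an 8-bit grayscale image
#' upsampled to 224x224 pixels with a linear contrast stretch, the form
#' consumed by image-classification backbones.
#'
#' @param slices A `slice_stack`.
#' @param directory Output directory (created if missing).
#' @param format `"array"` or `"png"`.
#' @param included_only Export only slices passing the inclusion filter
#'   (default TRUE).
#' @param image_size Pixel size of exported images (png only, default 224).
#' @return Manifest data.frame: `subject_id`, `projection`, `coordinate`,
#'   `slab`, `included`, `path`.
#' @export
export_slices <- function(slices, directory, format = c("array", "png"),
                          included_only = TRUE, image_size = 224L) {
  stopifnot(inherits(slices, "slice_stack"))
  format <- match.arg(format)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  keep <- if (included_only) which(slices$info$included) else seq_len(nrow(slices$info))
  info <- slices$info[keep, , drop = FALSE]
  ext <- if (format == "array") ".tsv" else ".png"
  paths <- file.path(directory, sprintf("%s_%s_%03d%s", info$subject_id,
                                        info$projection, info$coordinate, ext))
  for (k in seq_along(keep)) {
    p <- slices$pixels[[keep[k]]]
    if (format == "array") {
      utils::write.table(p, paths[k], sep = "\t",
                         row.names = FALSE, col.names = FALSE)
    } else {
      img <- .contrast_stretch(.resize_bilinear(p, image_size, image_size))
      png::writePNG(img / 255, paths[k])
    }
  }
  info$path <- paths
  rownames(info) <- NULL
  info
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param subject_id Identifier (default the file name without extension).
#' @return An `mri_volume`.
#' @export
read_volume <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  as_volume(arr, subject_id = subject_id, affine = aff)
}

#' Write a volume to a NIfTI file
#'
#' @param volume An `mri_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mri_volume"))
  img <- RNifti::asNifti(volume$intensities)
  aff <- volume$affine
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 4L))
  RNifti::pixdim(img) <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
  RNifti::writeNifti(img, path)
  invisible(path)
}
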