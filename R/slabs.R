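#' @keywords internal
"_PACKAGE"

## Slab geometry on the 2 mm MNI grid (91 x 109 x 91 voxels, 0-based indices).
## Coordinates are voxel indices along the axis perpendicular to the slice
## plane: x for sagittal, y for coronal, z for axial.

.projections <- c("coronal", "sagittal", "axial")

## inclusive [lo, hi] per slab, four contiguous slabs per projection
.slab_ranges <- list(
  coronal  = cbind(lo = c(17L, 37L, 52L, 77L), hi = c(36L, 51L, 76L, 95L)),
  sagittal = cbind(lo = c(14L, 30L, 46L, 62L), hi = c(29L, 45L, 61L, 77L)),
  axial    = cbind(lo = c(12L, 27L, 42L, 57L), hi = c(26L, 41L, 56L, 73L))
)

.mni_grid_shape <- c(91L, 109L, 91L)

#' Standard projections
#'
#' @return Character vector of the three anatomical projections handled by the
#'   pipeline: `"coronal"`, `"sagittal"`, `"axial"`.
#' @export
projections <- function() .projections

.match_projection <- function(projection) {
  match.arg(projection, .projections)
}

## axis of the volume array perpendicular to the slice plane (x, y, z) = (1, 2, 3)
.projection_axis <- function(projection) {
  switch(.match_projection(projection), sagittal = 1L, coronal = 2L, axial = 3L)
}

#' Slab definitions per projection
#'
#' Each projection's analysis range is partitioned into four contiguous,
#' non-overlapping slabs of slices.  Coronal slices span y = 17--95 (slabs
#' 17--36, 37--51, 52--76, 77--95), sagittal x = 14--77 (four slabs of 16
#' slices), axial z = 12--73 (15/15/15/17 slices).  Coordinates are 0-based
#' voxel indices on the 2 mm MNI grid.
#'
#' @param projection One of `"coronal"`, `"sagittal"`, `"axial"`, or `NULL`
#'   for all three.
#' @return A data.frame with columns `projection`, `slab_id`, `lo`, `hi`
#'   (inclusive coordinate bounds) and `n_slices`.
#' @export
#' @examples
#' slab_definitions("axial")
slab_definitions <- function(projection = NULL) {
  projs <- if (is.null(projection)) .projections else .match_projection(projection)
  out <- do.call(rbind, lapply(projs, function(p) {
    r <- .slab_ranges[[p]]
    data.frame(projection = p, slab_id = 1:4, lo = r[, "lo"], hi = r[, "hi"],
               n_slices = r[, "hi"] - r[, "lo"] + 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Analysis coordinate range of a projection
#'
#' @param projection One of `"coronal"`, `"sagittal"`, `"axial"`.
#' @return Integer vector `c(lo, hi)`, inclusive 0-based voxel coordinates.
#' @export
analysis_range <- function(projection) {
  r <- .slab_ranges[[.match_projection(projection)]]
  c(r[1L, "lo"], r[4L, "hi"])
}

#' Assign a slice coordinate to its slab
#'
#' @param projection One of `"coronal"`, `"sagittal"`, `"axial"`.
#' @param coordinate Integer voxel coordinate(s) along the projection axis,
#'   inside the projection's analysis range.
#' @return Integer slab id(s) in 1--4.  Coordinates outside the analysis
#'   range are an error, never silently unassigned.
#' @export
#' @examples
#' assign_slab("axial", 39) # slab 2
#' assign_slab("axial", 70) # slab 4
assign_slab <- function(projection, coordinate) {
  projection <- .match_projection(projection)
  coordinate <- as.integer(coordinate)
  r <- .slab_ranges[[projection]]
  rng <- analysis_range(projection)
  bad <- coordinate < rng[1L] | coordinate > rng[2L] | is.na(coordinate)
  if (any(bad)) {
    stop(sprintf("coordinate(s) %s outside the %s analysis range [%d, %d]",
                 paste(coordinate[bad], collapse = ", "), projection,
                 rng[1L], rng[2L]))
  }
  findInterval(coordinate, r[, "lo"])
}

#' Enumerate the discriminator design
#'
#' Lists every (replica, projection, slab) cell of the factorial training
#' design.  At the study design of 100 replicas, three projections and four
#' slabs this enumerates 1200 binary discriminators.
#'
#' @param n_replicas Number of ensemble replicas (default 100).
#' @param projs Character vector of projections (default all three).
#' @param n_slabs Slabs per projection (default 4).
#' @return data.frame with columns `replica`, `projection`, `slab_id`, one
#'   row per discriminator.
#' @export
enumerate_discriminators <- function(n_replicas = 100L,
                                     projs = projections(),
                                     n_slabs = 4L) {
  out <- expand.grid(replica = seq_len(n_replicas),
                     projection = projs,
                     slab_id = seq_len(n_slabs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$replica, out$projection, out$slab_id), , drop = FALSE]
}
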