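#' Intersect significant slices into a 3D voxel map
#'
#' A voxel is significant when one significant slice from each projection
#' crosses it: the coordinate triples are the Cartesian product of the
#' sagittal (x), coronal (y) and axial (z) significant-slice lists.  Two
#' counting rules are provided because per-projection lists may contain
#' repeated coordinates when one slice hosts several significant
#' classifiers: `"product_of_counts"` takes the lists as given, so the voxel
#' count is the product of the list lengths (the headline counting rule);
#' `"unique_voxels"` deduplicates each list first, which is the natural rule
#' for building a binary mask.
#'
#' @param sig_coronal,sig_sagittal,sig_axial Significant slice coordinates
#'   (y, x and z respectively; 0-based MNI voxel indices).
#' @param count_rule `"product_of_counts"` (default) or `"unique_voxels"`.
#' @param grid_shape Voxel grid (default the 2 mm MNI grid).
#' @return Object of class `voxel_map`: `voxels` (data.frame `x`, `y`, `z`
#'   of unique voxel coordinates), `count` (per the chosen rule), the rule
#'   and the grid.  Empty input on any projection yields an empty map with a
#'   warning.
#' @export
#' @examples
#' m <- intersect_slices(80:84, 20:24, rep(40:52, length.out = 15))
#' m$count # 5 * 5 * 15 = 375
intersect_slices <- function(sig_coronal, sig_sagittal, sig_axial,
                             count_rule = c("product_of_counts",
                                            "unique_voxels"),
                             grid_shape = c(91L, 109L, 91L)) {
  count_rule <- match.arg(count_rule)
  if (!length(sig_coronal) || !length(sig_sagittal) || !length(sig_axial)) {
    warning("empty significant-slice list on at least one projection; ",
            "no intersection possible")
    return(structure(list(voxels = data.frame(x = integer(0), y = integer(0),
                                              z = integer(0)),
                          count = 0L, count_rule = count_rule,
                          grid_shape = grid_shape),
                     class = "voxel_map"))
  }
  for (p in list(list("coronal", sig_coronal), list("sagittal", sig_sagittal),
                 list("axial", sig_axial))) {
    rng <- analysis_range(p[[1L]])
    bad <- p[[2L]] < rng[1L] | p[[2L]] > rng[2L]
    if (any(bad))
      stop(sprintf("%s coordinate(s) %s outside the analysis range [%d, %d]",
                   p[[1L]], paste(p[[2L]][bad], collapse = ", "),
                   rng[1L], rng[2L]))
  }
  xs <- sig_sagittal; ys <- sig_coronal; zs <- sig_axial
  if (count_rule == "unique_voxels") {
    xs <- sort(unique(xs)); ys <- sort(unique(ys)); zs <- sort(unique(zs))
  }
  count <- length(xs) * length(ys) * length(zs)
  vox <- unique(expand.grid(x = sort(unique(xs)), y = sort(unique(ys)),
                            z = sort(unique(zs)), KEEP.OUT.ATTRS = FALSE))
  structure(list(voxels = vox, count = count, count_rule = count_rule,
                 grid_shape = as.integer(grid_shape)),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map> %d significant voxels (%s; %d unique) on grid %s\n",
              x$count, x$count_rule, nrow(x$voxels),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Export a voxel map as a binary NIfTI mask
#'
#' @param map A `voxel_map`.
#' @param reference An `mri_volume` defining the grid and affine.
#' @param path Output NIfTI path; if `NULL` the mask volume is returned
#'   without writing.
#' @return The binary mask as an `mri_volume` (invisibly when written).
#' @export
export_mask <- function(map, reference, path = NULL) {
  stopifnot(inherits(map, "voxel_map"), inherits(reference, "mri_volume"))
  gs <- reference$grid_shape
  v <- map$voxels
  bad <- v$x > gs[1L] - 1L | v$y > gs[2L] - 1L | v$z > gs[3L] - 1L |
    v$x < 0L | v$y < 0L | v$z < 0L
  if (any(bad))
    stop("voxel(s) outside the reference grid: ",
         paste(sprintf("(%d,%d,%d)", v$x[bad], v$y[bad], v$z[bad]),
               collapse = " "))
  arr <- array(0, dim = gs)
  arr[cbind(v$x + 1L, v$y + 1L, v$z + 1L)] <- 1
  mask <- as_volume(arr, subject_id = "significant_voxels",
                    affine = reference$affine)
  if (!is.null(path)) {
    write_volume(mask, path)
    return(invisible(mask))
  }
  mask
}
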