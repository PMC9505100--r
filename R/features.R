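## Feature extraction for the lightweight classifier backbone: each slice is
## mean-pooled onto a small pixel grid and flattened.

.pool_weights <- function(n_in, n_out) {
  # average over nearly equal contiguous blocks
  breaks <- round(seq(0, n_in, length.out = n_out + 1))
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    cols <- (breaks[i] + 1):breaks[i + 1]
    W[i, cols] <- 1 / length(cols)
  }
  W
}

#' Mean-pool a slice to a coarse pixel grid
#'
#' @param pixels 2D matrix.
#' @param out_dim Output grid, e.g. `c(8, 8)`.
#' @return `out_dim[1] x out_dim[2]` matrix of block means.
#' @export
downsample_slice <- function(pixels, out_dim = c(8L, 8L)) {
  Wr <- .pool_weights(nrow(pixels), out_dim[1])
  Wc <- .pool_weights(ncol(pixels), out_dim[2])
  Wr %*% pixels %*% t(Wc)
}

#' Build the per-subject, per-slice feature table for one projection
#'
#' Slices every volume along `projection`, keeps the slices passing the
#' inclusion filter, and pools each to `out_dim` pixels.  Pixel intensities
#' are divided by 255 so features are on a unit scale.
#'
#' @param volumes List of `mri_volume` objects.
#' @param projection One of `"coronal"`, `"sagittal"`, `"axial"`.
#' @param out_dim Pooled grid (default `c(8, 8)`, i.e. 64 features).
#' @return List with `features` (numeric matrix, one row per
#'   (subject, included slice)) and `info` (data.frame `subject_id`,
#'   `coordinate`, `slab`).
#' @export
slice_features <- function(volumes, projection, out_dim = c(8L, 8L)) {
  projection <- .match_projection(projection)
  rows <- list(); infos <- list(); k <- 0L
  for (v in volumes) {
    st <- slice_volume(v, projection)
    keep <- which(st$info$included)
    if (!length(keep)) next
    feat <- t(vapply(keep, function(j)
      as.vector(downsample_slice(st$pixels[[j]], out_dim)) / 255,
      numeric(prod(out_dim))))
    k <- k + 1L
    rows[[k]] <- feat
    infos[[k]] <- st$info[keep, c("subject_id", "projection", "coordinate", "slab")]
  }
  if (k == 0L) stop("no included slices in any volume")
  list(features = do.call(rbind, rows),
       info = do.call(rbind, c(infos, list(make.row.names = FALSE))))
}
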