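#' Build the stratified replica train/validation splits
#'
#' Creates `n_replicas` random 90/10-style partitions of a labeled cohort,
#' stratified by class: per class, `round(train_fraction * n_class)` patients
#' go to training (so for the study cohort of 119 negatives and 62 positives
#' every replica trains on 163 patients, 107 negatives and 56 positives, and
#' validates on 18, 12 and 6).  Replicas are drawn independently and may
#' overlap; each carries its own seed derived from `seed` by drawing one
#' sub-seed per replica from the master stream.
#'
#' @param patients Labeled patient table (columns `patient_id`, `label`).
#' @param n_replicas Number of replicas (default 100).
#' @param train_fraction Training fraction (default 0.9).
#' @param seed Master seed.
#' @return List of `replica_split` objects: `replica_id`, `train_ids`,
#'   `val_ids`, `seed`.
#' @export
make_replicas <- function(patients, n_replicas = 100L, train_fraction = 0.9,
                          seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(patients)),
            train_fraction > 0, train_fraction < 1, n_replicas >= 1)
  ids <- split(as.character(patients$patient_id), patients$label)
  if (length(ids) < 2L) stop("cohort must contain both classes")
  n_train <- vapply(ids, function(v) as.integer(round(train_fraction * length(v))),
                    integer(1))
  if (any(n_train == lengths(ids)) || any(n_train == 0L))
    stop("a class is too small to stratify at this train fraction")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  lapply(seq_len(n_replicas), function(r) {
    set.seed(sub_seeds[r])
    tr <- unlist(lapply(names(ids), function(cl)
      sample(ids[[cl]], n_train[[cl]])), use.names = FALSE)
    structure(list(replica_id = r,
                   train_ids = tr,
                   val_ids = setdiff(unlist(ids, use.names = FALSE), tr),
                   seed = sub_seeds[r]),
              class = "replica_split")
  })
}
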