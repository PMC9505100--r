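#' Lightweight ridge-regression classifier backbone
#'
#' The default pluggable backbone: an L2-penalized logistic (binary) or
#' multinomial (slab-location) regression on pooled slice pixels, fit with
#' glmnet at a fixed penalty.  It is deterministic, fast enough to train the
#' full replica ensemble on one CPU, and exposes the `fit`/`prob` interface
#' any user-supplied backbone must implement.
#'
#' A backbone is a list of class `slice_classifier` with elements
#' \describe{
#'   \item{`fit(x, y)`}{`x` numeric feature matrix, `y` factor (2 levels for
#'     the progression task, 4 for the slab-location task); returns a fitted
#'     model object.}
#'   \item{`prob(model, x)`}{returns, for a binary model, a numeric vector of
#'     probabilities of the second factor level in `[0, 1]` (higher = more
#'     likely progressed); for a multiclass model, a matrix of class
#'     probabilities with one column per level.}
#' }
#'
#' @param lambda Ridge penalty (default 0.01).
#' @return A `slice_classifier`.
#' @export
ridge_classifier <- function(lambda = 0.01) {
  structure(list(
    name = sprintf("ridge(lambda=%g)", lambda),
    fit = function(x, y) {
      y <- factor(y)
      fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x, y, family = fam, alpha = 0, lambda = lambda,
                            standardize = FALSE)
      list(fit = fit, levels = levels(y), family = fam)
    },
    prob = function(model, x) {
      p <- stats::predict(model$fit, newx = x, type = "response")
      if (model$family == "binomial") as.vector(p)
      else {
        m <- p[, , 1L]
        if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                         dimnames = list(NULL, names(m)))
        m[, model$levels, drop = FALSE]
      }
    }
  ), class = "slice_classifier")
}

#' Pre-train the slab-location model
#'
#' First training step: a four-class classifier learns to place a slice into
#' its slab, per projection, from the slices alone (no progression labels).
#' The fitted location model then seeds the progression discriminators: its
#' four class probabilities are appended to the pixel features of every slice
#' the discriminators see.
#'
#' @param classifier A `slice_classifier` backbone.
#' @param features Output of [slice_features()] for one projection.
#' @param holdout_fraction Fraction of slices held out to report accuracy
#'   (default 0.2).
#' @param seed RNG seed for the holdout split.
#' @return List of class `location_model`: `model`, `classifier`,
#'   `accuracy` (held-out slab accuracy), `projection` slab levels.
#' @export
pretrain_location <- function(classifier, features, holdout_fraction = 0.2,
                              seed = 1L) {
  stopifnot(inherits(classifier, "slice_classifier"))
  slab <- features$info$slab
  present <- sort(unique(slab))
  if (length(present) < 4L)
    stop(sprintf("slab(s) %s have no included slices; cannot pre-train",
                 paste(setdiff(1:4, present), collapse = ", ")))
  n <- nrow(features$features)
  set.seed(seed)
  hold <- sample.int(n, max(1L, round(holdout_fraction * n)))
  y <- factor(slab, levels = 1:4)
  model <- classifier$fit(features$features[-hold, , drop = FALSE], y[-hold])
  probs <- classifier$prob(model, features$features[hold, , drop = FALSE])
  pred <- as.integer(colnames(probs)[max.col(probs, ties.method = "first")])
  structure(list(model = model, classifier = classifier,
                 accuracy = mean(pred == slab[hold]),
                 levels = 1:4),
            class = "location_model")
}

#' @export
print.location_model <- function(x, ...) {
  cat(sprintf("<location_model> held-out slab accuracy %.3f\n", x$accuracy))
  invisible(x)
}

## append the location model's slab probabilities to the pixel features
.augment_features <- function(features, location_model) {
  if (is.null(location_model)) return(features$features)
  probs <- location_model$classifier$prob(location_model$model,
                                          features$features)
  cbind(features$features, probs)
}
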