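#' Discrete AUC granularity (the admissibility half-width)
#'
#' The stepwise ROC of a validation set with `n_pos` positives and `n_neg`
#' negatives changes area in multiples of `1/(n_pos * n_neg)`; at the study
#' validation size of 6 positives and 12 negatives this is
#' 1/(6 x 12) = 0.0139.  A null model is considered to have no class
#' separation power when its AUC lies within `0.5 +/- delta`.
#'
#' @param n_pos,n_neg Positive and negative validation counts, both >= 1.
#' @return `1 / (n_pos * n_neg)`.
#' @export
#' @examples
#' round(auc_granularity(6, 12), 4) # 0.0139
auc_granularity <- function(n_pos, n_neg) {
  if (any(n_pos < 1) || any(n_neg < 1))
    stop("n_pos and n_neg must both be at least 1")
  1 / (n_pos * n_neg)
}

## DeLong structural components (placement values) of one score vector
.delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' DeLong's test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two models scored on the same validation
#' patients (real discriminator versus its permutation null twin).  The
#' variance of the AUC difference is estimated from the DeLong structural
#' components: `var = var_real + var_null - 2 cov`, with the positive- and
#' negative-placement covariance matrices scaled by their class sizes.  Z is
#' signed (`auc_real - auc_null` over its standard error) and the reported
#' p-value is two-sided standard normal.
#'
#' @param scores_real,scores_null Score vectors over the same patients.
#' @param labels Shared 0/1 labels (>= 2 positives and >= 2 negatives).
#' @return List of class `delong_test`: `z`, `p_value`, `auc_real`,
#'   `auc_null`, `variance`.
#' @export
delong_test <- function(scores_real, scores_null, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_real) == length(labels),
            length(scores_null) == length(labels))
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m < 2L || n < 2L)
    stop("DeLong's test needs at least 2 positives and 2 negatives")
  a <- .delong_placements(scores_real, labels)
  b <- .delong_placements(scores_null, labels)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$theta - b$theta
  if (v <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps) {
      z <- 0
    } else {
      stop("degenerate DeLong variance: both models are constant; ",
           "pair is untestable")
    }
  } else {
    z <- d / sqrt(v)
  }
  structure(list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 auc_real = a$theta, auc_null = b$theta, variance = v),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, Z = %.3f, p = %.4g\n",
              x$auc_real, x$auc_null, x$z, x$p_value))
  invisible(x)
}
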