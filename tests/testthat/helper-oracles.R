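# Independent brute-force oracles, kept free of the package's own code paths.

# AUC by exhaustive pair counting (ties 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# area under a step ROC by rectangle/trapezoid summation
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# a random scored validation set, optionally with heavy ties
random_instance <- function(n_pos = 6, n_neg = 12, ties = FALSE) {
  lab <- c(rep(1L, n_pos), rep(0L, n_neg))
  s <- if (ties) sample(seq(0, 1, by = 0.1), n_pos + n_neg, replace = TRUE)
       else runif(n_pos + n_neg)
  list(scores = s, labels = lab)
}
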