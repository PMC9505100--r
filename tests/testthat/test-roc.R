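test_that("rank-based AUC equals brute-force pair counting, with and without ties", {
  set.seed(42)
  for (i in 1:200) {
    inst <- random_instance(n_pos = sample(1:8, 1), n_neg = sample(1:15, 1),
                            ties = i %% 2 == 0)
    expect_equal(auc_mw(inst$scores, inst$labels),
                 oracle_auc(inst$scores, inst$labels))
  }
  expect_equal(auc_mw(c(0.9, 0.4, 0.7, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_mw(rep(0.3, 10), rep(c(1, 0), 5)), 0.5) # all ties
  expect_error(auc_mw(1:3, c(1, 1, 1)), "at least one")
})

test_that("the step ROC runs (0,0) to (1,1) with 1/n increments and trapezoid area = AUC", {
  set.seed(99)
  for (i in 1:50) {
    inst <- random_instance(ties = i %% 2 == 0)
    pts <- roc_points(inst$scores, inst$labels)
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr * 12, round(pts$fpr * 12))  # multiples of 1/n_neg
    expect_equal(pts$tpr * 6, round(pts$tpr * 6))    # multiples of 1/n_pos
    expect_equal(trapezoid_area(pts$fpr, pts$tpr),
                 auc_mw(inst$scores, inst$labels))
  }
})

test_that("reversing score signs maps AUC to 1 - AUC", {
  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance(ties = TRUE)
    expect_equal(auc_mw(-inst$scores, inst$labels),
                 1 - auc_mw(inst$scores, inst$labels))
  }
})

test_that("perturbing one score across one threshold changes AUC by 1/(n_pos*n_neg)", {
  set.seed(13)
  s <- runif(18); lab <- c(rep(1, 6), rep(0, 12))
  base <- auc_mw(s, lab)
  # nudge the lowest positive just above the next negative up
  pos_i <- which(lab == 1)[which.min(s[lab == 1])]
  next_neg <- min(s[lab == 0][s[lab == 0] > s[pos_i]])
  s2 <- s; s2[pos_i] <- next_neg + 1e-9
  expect_equal(auc_mw(s2, lab) - base, 1 / 72, tolerance = 1e-6)
})

test_that("slab-folded AUC treats every (patient, slice) pair as one instance", {
  set.seed(21)
  mk <- function(coords, scores_by_slice) {
    do.call(rbind, lapply(seq_along(coords), function(k)
      data.frame(projection = "axial", slab = 1, replica = 1,
                 coordinate = coords[k],
                 patient_id = sprintf("p%02d", 1:18),
                 true_label = c(rep(1, 6), rep(0, 12)),
                 score = scores_by_slice[[k]], model_kind = "real")))
  }
  s1 <- runif(18); s2 <- runif(18)
  # single slice reduces to the slice AUC
  one <- mk(40, list(s1))
  expect_equal(auc_slab_folded(one)$auc, auc_slice(s1, one$true_label[1:18])$auc)
  # duplicated slice leaves the AUC unchanged
  dup <- mk(c(40, 41), list(s1, s1))
  expect_equal(auc_slab_folded(dup)$auc, auc_mw(s1, c(rep(1, 6), rep(0, 12))))
  # pooled instances equal brute-force pair counting, with matching counts
  two <- mk(c(40, 41), list(s1, s2))
  fold <- auc_slab_folded(two)
  expect_equal(fold$auc, oracle_auc(two$score, two$true_label))
  expect_identical(fold$n_pos, 12L)  # 6 patients x 2 slices
  expect_identical(fold$n_neg, 24L)
  # a missing slice score is an error naming the coordinate
  broken <- two[-1, ]
  expect_error(auc_slab_folded(broken), "40")
})

test_that("distribution summaries use linear quartiles and the 1.5 IQR outlier rule", {
  set.seed(31)
  aucs <- c(runif(100, 0.4, 0.6), 0.95)
  s <- summarize_distribution(aucs)
  expect_identical(s$outliers, 101L)
  expect_equal(s$q25, unname(quantile(aucs, 0.25)))
  expect_true(s$q25 <= s$median && s$median <= s$q75)
  # constant distribution: zero IQR, no outliers under strict inequality
  s0 <- summarize_distribution(rep(0.5, 20))
  expect_length(s0$outliers, 0L)
  expect_error(summarize_distribution(c(0.5, 0.6, 0.7)), "at least 4")
})
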