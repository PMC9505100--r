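test_that("slab-location pre-training separates slabs on synthetic volumes", {
  af <- fixture_axial_features()
  loc <- pretrain_location(ridge_classifier(), af$features, seed = 9)
  expect_gt(loc$accuracy, 0.9)
})

test_that("location pre-training on permuted slab labels performs at 4-class chance", {
  af <- fixture_axial_features()
  shuffled <- af$features
  set.seed(11)
  shuffled$info$slab <- sample(shuffled$info$slab)
  loc <- pretrain_location(ridge_classifier(), shuffled, seed = 9)
  expect_lt(abs(loc$accuracy - 0.25), 0.12)
})

test_that("pre-training rejects input missing a slab", {
  af <- fixture_axial_features()
  single <- af$features
  keep <- single$info$slab == 1
  single$features <- single$features[keep, ]; single$info <- single$info[keep, ]
  expect_error(pretrain_location(ridge_classifier(), single), "slab")
})

test_that("a discriminator on a strongly separable slab reaches validation AUC 1", {
  af <- fixture_axial_features()
  reps <- make_replicas(af$patients, n_replicas = 2, train_fraction = 0.75,
                        seed = 5)
  ps <- train_discriminator(af$features, af$labels, reps[[1]], slab_id = 3,
                            classifier = ridge_classifier())
  # signal fills slab 3, so every slice separates the validation classes
  per_slice <- split(ps, ps$coordinate)
  aucs <- vapply(per_slice, function(d) auc_mw(d$score, d$true_label),
                 numeric(1))
  expect_true(all(aucs == 1))
  # and the brute-force oracle agrees
  expect_equal(unname(aucs[1]),
               oracle_auc(per_slice[[1]]$score, per_slice[[1]]$true_label))
  expect_error(train_discriminator(af$features, af$labels, reps[[1]],
                                   slab_id = 99,
                                   classifier = ridge_classifier()),
               "no included slices")
})

test_that("null twins permute training labels with class counts unchanged", {
  af <- fixture_axial_features()
  ens <- fit_slice_ensemble(fixture_cohort()$volumes, af$patients,
                            projs = "axial", n_replicas = 4,
                            train_fraction = 0.75, pretrain = FALSE, seed = 31)
  preds <- ens$predictions
  expect_setequal(unique(preds$model_kind), c("real", "null"))
  # real and null cover identical validation cells with identical truth
  key <- function(d) paste(d$replica, d$slab, d$coordinate, d$patient_id,
                           d$true_label)
  expect_setequal(key(preds[preds$model_kind == "real", ]),
                  key(preds[preds$model_kind == "null", ]))
})

test_that("the null path trains on a true permutation and only the labels differ", {
  # spy backbone recording exactly what the training step receives
  seen <- list()
  spy <- structure(list(
    name = "spy",
    fit = function(x, y) { seen[[length(seen) + 1]] <<- list(x = x, y = y); 0 },
    prob = function(model, x) rep(0.5, nrow(x))
  ), class = "slice_classifier")
  af <- fixture_axial_features()
  reps <- make_replicas(af$patients, n_replicas = 3, train_fraction = 0.75,
                        seed = 5)
  for (r in reps) {
    seen <- list()
    train_discriminator(af$features, af$labels, r, 2, spy)
    train_discriminator(af$features, af$labels, r, 2, spy,
                        shuffle_labels = TRUE, seed = 1000 + r$replica_id)
    real <- seen[[1]]; null <- seen[[2]]
    expect_identical(real$x, null$x)  # identical images, only labels differ
    expect_identical(table(real$y), table(null$y))  # class counts preserved
  }
  # across replicas at least one permutation changed the assignment
  seen <- list()
  for (r in reps)
    train_discriminator(af$features, af$labels, r, 2, spy,
                        shuffle_labels = TRUE, seed = 1000 + r$replica_id)
  real_y <- lapply(reps, function(r) {
    slab_rows <- af$features$info$slab == 2 &
      af$features$info$subject_id %in% r$train_ids
    factor(af$labels[af$features$info$subject_id[slab_rows]], levels = 0:1)
  })
  changed <- mapply(function(s, y) !identical(as.integer(s$y), as.integer(y)),
                    seen, real_y)
  expect_true(any(changed))
})

test_that("the ensemble is reproducible under the same master seed", {
  af <- fixture_axial_features()
  co <- fixture_cohort()
  e1 <- fit_slice_ensemble(co$volumes, af$patients, projs = "axial",
                           n_replicas = 4, train_fraction = 0.75,
                           pretrain = FALSE, seed = 77)
  e2 <- fit_slice_ensemble(co$volumes, af$patients, projs = "axial",
                           n_replicas = 4, train_fraction = 0.75,
                           pretrain = FALSE, seed = 77)
  expect_identical(e1$predictions, e2$predictions)
})
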