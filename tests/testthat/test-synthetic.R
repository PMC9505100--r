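test_that("generated cohorts are deterministic and hit the configured prevalence", {
  cfg <- generator_config(n_patients = 181, prevalence = 0.3425,
                          grid_shape = c(12, 14, 12),
                          signal_regions = list(signal_region(c(2, 2, 2),
                                                              c(6, 6, 6))),
                          seed = 7)
  co <- generate_cohort(cfg)
  expect_identical(sum(co$truth$labels), 62L)
  expect_identical(length(co$volumes), 181L)
  # EDSS pairs reproduce the truth labels under the progression rule
  expect_identical(unname(label_patients(co$patients)$label),
                   unname(co$truth$labels))
  # bit-identical under the same seed
  co2 <- generate_cohort(cfg)
  expect_identical(co$patients, co2$patients)
  expect_identical(co$volumes[[5]]$intensities, co2$volumes[[5]]$intensities)
  # different seed changes the draw
  co3 <- generate_cohort(generator_config(n_patients = 181, prevalence = 0.3425,
                                          grid_shape = c(12, 14, 12),
                                          signal_regions = cfg$signal_regions,
                                          seed = 8))
  expect_false(identical(co$volumes[[5]]$intensities,
                         co3$volumes[[5]]$intensities))
})

test_that("volumes are zero outside the brain mask and masked inside", {
  co <- fixture_cohort()
  arr <- co$volumes[[1]]$intensities
  corner <- arr[1:5, 1:5, 1:5]  # far outside the inscribed ellipsoid
  expect_true(all(corner == 0))
  expect_gt(mean(arr != 0), 0.3)
})

test_that("planted signal elevates positive-class region means by the effect size", {
  cfg <- generator_config(n_patients = 60, prevalence = 0.5,
                          grid_shape = c(30, 36, 30),
                          signal_regions = list(signal_region(c(10, 12, 10),
                                                              c(20, 24, 20))),
                          effect_size = 25, noise_sd = 10, seed = 11)
  co <- generate_cohort(cfg)
  reg <- function(v) mean(v$intensities[11:21, 13:25, 11:21])
  mu <- vapply(co$volumes, reg, numeric(1))
  diff <- mean(mu[co$truth$labels == 1]) - mean(mu[co$truth$labels == 0])
  expect_equal(diff, 25, tolerance = 0.05)
  # effect 0: class means differ only by noise
  cfg0 <- cfg; cfg0$effect_size <- 0
  co0 <- generate_cohort(cfg0)
  mu0 <- vapply(co0$volumes, reg, numeric(1))
  expect_gt(t.test(mu0[co0$truth$labels == 1],
                   mu0[co0$truth$labels == 0])$p.value, 0.05)
})

test_that("invalid generator configurations are rejected with informative errors", {
  expect_error(generator_config(prevalence = 0), "prevalence")
  expect_error(generator_config(prevalence = 1), "prevalence")
  expect_error(generator_config(n_patients = 10, prevalence = 0.01),
               "at least 1")
  expect_error(
    generator_config(grid_shape = c(10, 10, 10),
                     signal_regions = list(signal_region(c(5, 5, 5),
                                                         c(12, 5, 5)))),
    "12")
})

test_that("cohorts round-trip through NIfTI + CSV + JSON exactly", {
  cfg <- generator_config(n_patients = 3, prevalence = 1 / 3,
                          grid_shape = c(12, 14, 12),
                          signal_regions = list(signal_region(c(2, 2, 2),
                                                              c(6, 6, 6))),
                          seed = 5)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  man <- write_cohort(co, d)
  expect_length(man$volumes, 3L)
  back <- read_cohort(d)
  expect_equal(back$patients$edss_baseline, co$patients$edss_baseline)
  expect_identical(unname(back$truth$labels), unname(co$truth$labels))
  for (i in 1:3)
    expect_equal(back$volumes[[i]]$intensities, co$volumes[[i]]$intensities,
                 tolerance = 1e-6)
  # empty cohort writes an empty manifest without error
  empty <- co; empty$volumes <- list(); empty$patients <- co$patients[0, ]
  man0 <- write_cohort(empty, file.path(d, "empty"))
  expect_length(man0$volumes, 0L)
})
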