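test_that("intensity normalization is linear, zero-preserving and maps max to 255", {
  arr <- array(0, c(4, 4, 4)); arr[1, 1, 1] <- 510; arr[2, 2, 2] <- 255
  v <- normalize_intensity(as_volume(arr, "s1"))
  expect_equal(max(v$intensities), 255)
  expect_equal(v$intensities[2, 2, 2], 127.5)
  expect_equal(sum(v$intensities == 0), 62)  # zeros preserved
  # already at 255: unchanged
  arr2 <- array(runif(64) * 255, c(4, 4, 4)); arr2[1] <- 255
  v2 <- normalize_intensity(as_volume(arr2, "s2"))
  expect_equal(v2$intensities, arr2)
  # random positives end at exactly 255
  v3 <- normalize_intensity(as_volume(array(runif(64), c(4, 4, 4)), "s3"))
  expect_identical(max(v3$intensities), 255)
  expect_error(normalize_intensity(as_volume(array(0, c(2, 2, 2)), "z9")), "z9")
})

test_that("slicing yields 79 coronal, 64 sagittal and 62 axial analysis slices", {
  v <- fixture_volume()
  expected <- c(coronal = 79L, sagittal = 64L, axial = 62L)
  for (p in projections()) {
    st <- slice_volume(v, p)
    expect_identical(nrow(st$info), expected[[p]])
    rng <- analysis_range(p)
    expect_identical(st$info$coordinate, seq(rng[1], rng[2]))
    expect_identical(st$info$slab, assign_slab(p, st$info$coordinate))
  }
  small <- as_volume(array(1, c(10, 10, 10)), "tiny")
  expect_error(slice_volume(small, "coronal"), "analysis range")
})

test_that("slice pixels match the volume plane at the 0-based coordinate", {
  v <- fixture_volume()
  st <- slice_volume(v, "axial")
  k <- which(st$info$coordinate == 40)
  expect_equal(st$pixels[[k]], v$intensities[, , 41])
  st2 <- slice_volume(v, "coronal")
  expect_equal(st2$pixels[[5]], v$intensities[, 17 + 5, ])
})

test_that("inclusion requires >= 10% non-zero pixels and is monotone under zeroing", {
  arr <- array(0, c(91, 109, 91))
  arr[, , 41] <- 2  # fully non-zero plane
  v <- as_volume(arr, "s")
  st <- slice_volume(v, "axial")
  inc <- st$info$included
  expect_true(inc[st$info$coordinate == 40])
  expect_false(any(inc[st$info$coordinate != 40]))
  # zeroing pixels can only exclude, never include
  v$intensities[seq(1, 91, by = 2), , 41] <- 0  # ~50% still non-zero
  expect_true(slice_volume(v, "axial")$info$included[
    st$info$coordinate == 40])
  v$intensities[, , 41] <- 0
  expect_false(any(slice_volume(v, "axial")$info$included))
})

test_that("slice export writes one file per included slice and 224x224 images", {
  v <- fixture_volume()
  st <- slice_volume(v, "axial")
  d <- withr::local_tempdir()
  man <- export_slices(st, d, format = "array")
  expect_identical(nrow(man), sum(st$info$included))
  expect_true(all(file.exists(man$path)))
  back <- as.matrix(read.table(man$path[1], sep = "\t"))
  dimnames(back) <- NULL
  expect_equal(back, st$pixels[[which(st$info$included)[1]]])
  # png export upsamples to 224 x 224
  sub <- st; keep <- 1:2
  sub$pixels <- st$pixels[keep]; sub$info <- st$info[keep, ]
  class(sub) <- "slice_stack"
  man2 <- export_slices(sub, d, format = "png", included_only = FALSE)
  img <- png::readPNG(man2$path[1])
  expect_identical(dim(img), c(224L, 224L))
  # empty stack -> empty manifest
  empty <- structure(list(pixels = list(), info = st$info[0, ]),
                     class = "slice_stack")
  expect_identical(nrow(export_slices(empty, d)), 0L)
})

test_that("volumes round-trip through NIfTI with grid and affine intact", {
  arr <- array(runif(6 * 7 * 8), c(6, 7, 8))
  v <- as_volume(arr, "rt")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path, "rt")
  expect_equal(back$intensities, arr, tolerance = 1e-6)
  expect_equal(unclass(back$affine)[1:3, 1:4], mni_affine_2mm()[1:3, 1:4],
               ignore_attr = TRUE)
})
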