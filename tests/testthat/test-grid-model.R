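test_that("volumes round-trip through NIfTI losslessly", {
  set.seed(11)
  v <- scalar_volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                     spacing = c(2.5, 2, 1.25), origin = c(-10, 5.5, 30))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_identical(r$values, v$values)
  expect_identical(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
})

test_that("reader rejects missing files and non-3D payloads", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(3, 3, 3, 2)))
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "dimensionality")
})

test_that("scalar_volume validates its geometry fields", {
  expect_error(scalar_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(scalar_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "spacing")
  expect_error(scalar_volume(array(0, c(2, 2, 2)), c(1, 1, 1), c(0, NA, 0)),
               "origin")
})

test_that("voxel volume follows the spacing product", {
  v <- const_vol(0, dim = c(4, 4, 4), spacing = c(2, 2, 2))
  expect_equal(voxel_volume_cm3(v), 0.008)
  expect_equal(voxel_volume_cm3(const_vol(1, spacing = c(2.5, 2.5, 2.5))),
               2.5^3 / 1000)
})

test_that("resample on the identical grid is the identity", {
  set.seed(2)
  v <- make_vol(array(rnorm(64), c(4, 4, 4)))
  r <- resample(v, grid_of(v), mode = "linear")
  expect_identical(r$values, v$values)
})

test_that("resampling preserves constants and respects the input range", {
  v <- const_vol(7, dim = c(6, 6, 6), spacing = c(2, 2, 2))
  tg <- list(dim = c(9L, 9L, 9L), spacing = c(1.3, 1.3, 1.3),
             origin = c(0.5, 0.5, 0.5))
  r <- resample(v, tg, mode = "linear", fill = 0)
  expect_true(all(r$values %in% c(0, 7) | (r$values > 0 & r$values < 7)))
  inside <- resample(const_vol(1, dim = c(6, 6, 6), spacing = c(2, 2, 2)),
                     tg, mode = "nearest", fill = 0)$values > 0.5
  expect_true(all(r$values[inside] == 7))

  set.seed(3)
  w <- make_vol(array(rnorm(216), c(6, 6, 6)), spacing = c(2, 2, 2))
  rw <- resample(w, tg, mode = "linear", fill = 0)
  expect_true(max(rw$values) <= max(w$values) + 1e-12)
  expect_true(min(rw$values) >= min(c(0, w$values)) - 1e-12)
})

test_that("linear resampling at half spacing recovers neighbour midpoints", {
  ramp <- array(rep(seq(0, 14, by = 2), times = 9), c(8, 3, 3))
  v <- make_vol(ramp, spacing = c(2, 2, 2))
  tg <- list(dim = c(15L, 3L, 3L), spacing = c(1, 2, 2), origin = c(0, 0, 0))
  r <- resample(v, tg, mode = "linear")
  # odd target voxels sit midway between source voxels along x
  expect_equal(r$values[seq(2, 14, by = 2), 2, 2],
               (ramp[1:7, 2, 2] + ramp[2:8, 2, 2]) / 2)
  expect_equal(r$values[seq(1, 15, by = 2), 2, 2], ramp[, 2, 2])
})

test_that("nearest-mode output values are a subset of the input values", {
  set.seed(4)
  vals <- sample(c(0, 1, 5), 27, replace = TRUE)
  v <- make_vol(array(vals, c(3, 3, 3)), spacing = c(3, 3, 3))
  tg <- list(dim = c(5L, 5L, 5L), spacing = c(1.7, 1.7, 1.7),
             origin = c(0.2, 0.2, 0.2))
  r <- resample(v, tg, mode = "nearest", fill = 0)
  expect_true(all(r$values %in% c(0, 1, 5)))
})

test_that("disjoint grids are rejected", {
  v <- const_vol(1, dim = c(4, 4, 4))
  tg <- list(dim = c(4L, 4L, 4L), spacing = c(1, 1, 1), origin = c(100, 0, 0))
  expect_error(resample(v, tg), "overlap")
})

test_that("structure sets enforce anatomical invariants", {
  m <- array(FALSE, c(6, 6, 6))
  body <- m; body[2:5, 2:5, 2:5] <- TRUE
  a <- m; a[2:3, 2:3, 2:3] <- TRUE
  b <- m; b[4:5, 4:5, 4:5] <- TRUE
  expect_silent(structure_set(list(uterus = a, rectum = b, body = body),
                              spacing = c(1, 1, 1)))
  overlapping <- a; overlapping[3:4, 3:4, 3:4] <- TRUE
  expect_error(structure_set(list(uterus = a, rectum = overlapping,
                                  body = body), spacing = c(1, 1, 1)),
               "overlap")
  outside <- m; outside[1, 1, 1] <- TRUE
  expect_error(structure_set(list(uterus = outside, body = body),
                             spacing = c(1, 1, 1)), "outside the body")
})

test_that("structure sets round-trip through NIfTI + JSON sidecar", {
  s <- cached_case(1)$structures
  dir <- withr::local_tempdir()
  write_structures(s, dir)
  r <- read_structures(dir)
  expect_identical(names(r$masks), names(s$masks))
  for (nm in names(s$masks)) expect_identical(r$masks[[nm]], s$masks[[nm]])
  expect_identical(r$spacing, s$spacing)
})
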