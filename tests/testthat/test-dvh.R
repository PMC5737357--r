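test_that("DVH of a uniform dose is a step function at the dose", {
  organ <- array(TRUE, c(5, 5, 4))
  dose <- const_vol(10, dim = c(5, 5, 4), spacing = c(10, 10, 10))
  vv <- voxel_volume_cm3(dose)
  curve <- compute_dvh(dose, organ, bin_width = 0.5)
  expect_equal(curve$volume_cm3[curve$dose_gy <= 10], rep(100 * vv, 21))
  expect_equal(curve$volume_cm3[curve$dose_gy > 10], 0)
  expect_equal(curve$volume_cm3[1], attr(curve, "organ_volume_cm3"))
})

test_that("DVH values at shared edges are independent of bin width", {
  set.seed(14)
  dose <- make_vol(array(runif(216, 0, 20), c(6, 6, 6)))
  organ <- array(runif(216) < 0.6, c(6, 6, 6))
  coarse <- compute_dvh(dose, organ, bin_width = 1)
  fine <- compute_dvh(dose, organ, bin_width = 0.5)
  shared <- intersect(coarse$dose_gy, fine$dose_gy)
  expect_equal(coarse$volume_cm3[match(shared, coarse$dose_gy)],
               fine$volume_cm3[match(shared, fine$dose_gy)])
  expect_true(all(diff(coarse$volume_cm3) <= 0))
  expect_error(compute_dvh(dose, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("d_cc reproduces the sort oracle on the 30-voxel example", {
  # 30 voxels of 0.1 cm3 with doses 1..30 Gy: the hottest 1 cm3 is the top
  # 10 voxels, whose minimum dose is 21 Gy
  vals <- array(0, c(30, 1, 1)); vals[, 1, 1] <- 1:30
  dose <- make_vol(vals, spacing = c(10, 10, 1))  # 0.1 cm3 voxels
  organ <- array(TRUE, c(30, 1, 1))
  expect_equal(d_cc(dose, organ, 1), 21)
  # tiny volumes approach the maximum dose
  expect_equal(d_cc(dose, organ, 1e-9), 30)
  # uniform dose gives that dose at any volume
  u <- const_vol(5, dim = c(4, 4, 4), spacing = c(10, 10, 10))
  expect_equal(d_cc(u, array(TRUE, c(4, 4, 4)), 2), 5)
  expect_error(d_cc(dose, organ, 100), "exceeds")
  expect_error(d_cc(dose, organ, 0), "positive")
})

test_that("d_cc agrees with an exhaustive sort-and-scan oracle", {
  # independent oracle: accumulate voxel volumes over descending doses and
  # linearly interpolate inside the crossing voxel
  oracle <- function(d, vv, v) {
    d <- sort(d, decreasing = TRUE)
    q <- v / vv
    m <- floor(q + 1e-9)
    if (m == 0) return(d[1])
    if (m >= length(d) || q - m <= 1e-9) return(d[m])
    d[m] + (q - m) * (d[m + 1] - d[m])
  }
  set.seed(15)
  for (i in 1:100) {
    dims <- sample(3:8, 3, replace = TRUE)
    sp <- runif(3, 1, 6)
    dose <- make_vol(array(rexp(prod(dims), rate = 0.2), dims), spacing = sp)
    organ <- array(runif(prod(dims)) < 0.7, dims)
    if (sum(organ) < 3) next
    vv <- prod(sp) / 1000
    vmax <- sum(organ) * vv
    for (v in runif(3, 1e-6, vmax * 0.999)) {
      expect_equal(d_cc(dose, organ, v), oracle(dose$values[organ], vv, v),
                   tolerance = 1e-12)
    }
  }
})

test_that("hottest-subvolume doses are nested: D0.1 >= D1 >= D2", {
  set.seed(16)
  for (i in 1:25) {
    dose <- make_vol(array(rexp(1000, 0.1), c(10, 10, 10)),
                     spacing = c(5, 5, 5))
    organ <- array(runif(1000) < 0.5, c(10, 10, 10))
    if (sum(organ) * voxel_volume_cm3(dose) < 2.5) next
    d01 <- d_cc(dose, organ, 0.1)
    d1 <- d_cc(dose, organ, 1)
    d2 <- d_cc(dose, organ, 2)
    expect_true(d01 >= d1 && d1 >= d2)
  }
})

test_that("D90 matches its definition on uniform and ordered doses", {
  u <- const_vol(6, dim = c(5, 5, 5), spacing = c(5, 5, 5))
  target <- array(TRUE, c(5, 5, 5))
  expect_equal(d90(u, target), 6)
  # removing the coldest 10% of voxels cannot decrease D90
  vals <- array(0, c(100, 1, 1)); vals[, 1, 1] <- sort(rexp(100, 0.1))
  dose <- make_vol(vals, spacing = c(5, 5, 5))
  full <- array(TRUE, c(100, 1, 1))
  trimmed <- full; trimmed[1:10, , ] <- FALSE   # drop the 10 coldest
  expect_gte(d90(dose, trimmed), d90(dose, full))
})

test_that("DVH parameter addition sums included plans and skips CS", {
  g3 <- c(3, 3, 3)
  organ <- array(TRUE, g3)
  # two BT fractions with uniform per-fraction EQD2 of 5 and 7 Gy:
  # uniform physical doses chosen so that EQD2 comes out exactly
  # EQD2 = D (d + 3) / 5 with d = D -> solve for D
  solve_d <- function(eq) (-3 + sqrt(9 + 20 * eq)) / 2
  p1 <- make_plan("BT1", array(solve_d(5), g3), 1, spacing = c(10, 10, 10))
  p2 <- make_plan("BT2", array(solve_d(7), g3), 1, frame_id = "f2",
                  spacing = c(10, 10, 10))
  masks <- list(f1 = organ, f2 = organ)
  expect_equal(dvh_parameter_addition(list(p1, p2), masks, 2), 12,
               tolerance = 1e-12)
  # a CS plan with nonzero dose is ignored
  cs <- make_plan("CS", array(8, g3), 4, frame_id = "f2",
                  spacing = c(10, 10, 10))
  expect_false(cs$include_in_addition)
  expect_equal(dvh_parameter_addition(list(p1, p2, cs), masks, 2), 12,
               tolerance = 1e-12)
  expect_equal(dvh_parameter_addition(list(p2, cs, p1), masks, 2), 12,
               tolerance = 1e-12)
  expect_error(dvh_parameter_addition(list(cs), masks, 2), "no plans")
})

test_that("addition equals the accumulated-dose metric for co-located hotspots", {
  set.seed(17)
  base <- array(rexp(512, 0.2), c(8, 8, 8))
  organ <- array(runif(512) < 0.6, c(8, 8, 8))
  plans <- lapply(1:3, function(i)
    fraction_plan(paste0("BT", i), "f1", make_vol(2 * base, c(5, 5, 5)), 1))
  masks <- list(f1 = organ)
  add <- dvh_parameter_addition(plans, masks, 2)
  acc <- accumulate_dose(plans)
  expect_equal(add, d_cc(acc$dose, organ, 2), tolerance = 0.1)
})
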