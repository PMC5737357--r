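test_that("EQD2 conversion matches the linear-quadratic closed forms", {
  # 2 Gy/fraction is the fixed point
  p <- make_plan("WP", array(30, c(3, 3, 3)), n_fractions = 15)
  expect_equal(eqd2_convert(p, alpha_beta = 3)$values,
               array(30, c(3, 3, 3)))
  # single 6 Gy brachytherapy fraction inflates to 6 * 9 / 5 = 10.8
  b <- make_plan("BT1", array(6, c(3, 3, 3)), n_fractions = 1)
  expect_equal(eqd2_convert(b, alpha_beta = 3)$values,
               array(10.8, c(3, 3, 3)))
  # zero dose stays zero
  z <- make_plan("BT1", array(0, c(3, 3, 3)), n_fractions = 1)
  expect_equal(eqd2_convert(z)$values, array(0, c(3, 3, 3)))
  expect_error(eqd2_convert(b, alpha_beta = 0), "positive")
})

test_that("EQD2 is monotone in fraction dose and exceeds D when d > 2 Gy", {
  D <- 24
  eq <- vapply(c(12L, 8L, 6L, 4L, 3L, 2L, 1L), function(n) {
    eqd2_convert(make_plan("BT1", array(D, c(2, 2, 2)), n))$values[1]
  }, numeric(1))
  expect_true(all(diff(eq) > 0))         # fewer fractions -> larger d -> larger EQD2
  hyper <- eqd2_convert(make_plan("BT1", array(6, c(2, 2, 2)), 1))$values[1]
  expect_gt(hyper, 6)
})

test_that("dose warping preserves identity, constants and integer shifts", {
  g <- list(dim = c(8L, 8L, 8L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  set.seed(10)
  dose <- make_vol(array(runif(512, 0, 10), c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_identical(warp_dose(dose, zero_field(g))$values, dose$values)
  const <- const_vol(10, dim = c(8, 8, 8), spacing = c(2, 2, 2))
  off <- array(0, c(8, 8, 8, 3)); off[, , , 2] <- 1.3
  sm_field <- displacement_field(off, c(2, 2, 2))
  w <- warp_dose(const, sm_field)
  inb <- w$values[, 1:7, ]
  expect_true(all(abs(inb - 10) < 1e-12))
  # exact one-voxel integer translation equals an index shift
  off2 <- array(0, c(8, 8, 8, 3)); off2[, , , 1] <- 2
  ws <- warp_dose(dose, displacement_field(off2, c(2, 2, 2)))
  expect_equal(ws$values[1:7, , ], dose$values[2:8, , ])
  # output bounded by the input range
  expect_true(max(ws$values) <= max(dose$values) + 1e-12)
  expect_true(min(ws$values) >= 0)
})

test_that("accumulation reduces to EQD2 for a single reference-frame plan", {
  p <- make_plan("BT1", array(runif(27, 0, 6), c(3, 3, 3)), 1)
  acc <- accumulate_dose(list(p))
  expect_equal(acc$dose$values, eqd2_convert(p)$values)
  expect_identical(nrow(acc$provenance), 1L)
})

test_that("co-registered plans sum voxel-wise and commute", {
  set.seed(12)
  plans <- list(
    make_plan("BT1", array(runif(64, 0, 6), c(4, 4, 4)), 1),
    make_plan("BT2", array(runif(64, 0, 6), c(4, 4, 4)), 1, frame_id = "f2"),
    make_plan("WP", array(2 * round(runif(64, 0, 15)), c(4, 4, 4)), 15,
              frame_id = "f3"))
  g <- grid_of(plans[[1]]$dose)
  fields <- list(f2 = zero_field(g), f3 = zero_field(g))
  acc <- accumulate_dose(plans, fields)
  manual <- Reduce(`+`, lapply(plans, function(p) eqd2_convert(p)$values))
  expect_equal(acc$dose$values, manual)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(accumulate_dose(plans[perm], fields)$dose$values,
                     acc$dose$values)
  }
})

test_that("a non-reference frame without a field is an error naming the frame", {
  p1 <- make_plan("BT1", array(1, c(3, 3, 3)), 1)
  p2 <- fraction_plan("BT2", "bt2",
                      make_vol(array(1, c(3, 3, 3)), origin = c(50, 0, 0)), 1)
  expect_error(accumulate_dose(list(p1, p2), reference_grid = grid_of(p1$dose)),
               "bt2")
})

test_that("warp-then-convert order is available and differs for warped plans", {
  set.seed(13)
  d <- array(runif(512, 0, 8), c(8, 8, 8))
  p <- fraction_plan("BT2", "f2", make_vol(d, spacing = c(2, 2, 2)), 1)
  g <- grid_of(p$dose)
  off <- array(0.9, c(8, 8, 8, 3))
  f <- list(f2 = displacement_field(off, c(2, 2, 2)))
  a1 <- accumulate_dose(list(p), f, eqd2_first = TRUE)
  a2 <- accumulate_dose(list(p), f, eqd2_first = FALSE)
  expect_false(isTRUE(all.equal(a1$dose$values, a2$dose$values)))
  expect_identical(a1$eqd2_first, TRUE)
  expect_identical(a2$eqd2_first, FALSE)
})

test_that("plans validate dose sign and fractionation", {
  expect_error(make_plan("BT1", array(-1, c(2, 2, 2)), 1), "negative")
  expect_error(make_plan("BT1", array(1, c(2, 2, 2)), 0), "positive")
})
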