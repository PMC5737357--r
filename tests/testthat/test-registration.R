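test_that("applicator HU replacement touches exactly the mask voxels", {
  case <- cached_case(1)
  app <- case$structures$masks$applicator
  out <- replace_applicator_hu(case$ct, app)
  expect_true(all(out$values[app] == -1000))
  expect_identical(out$values[!app], case$ct$values[!app])
  expect_identical(sum(out$values != case$ct$values), sum(app))
  # empty mask is a no-op
  empty <- array(FALSE, dim(case$ct$values))
  expect_identical(replace_applicator_hu(case$ct, empty)$values,
                   case$ct$values)
  wrong <- scalar_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(replace_applicator_hu(case$ct, wrong), "grid")
})

test_that("dice matches its definition, is symmetric and bounded", {
  m <- array(FALSE, c(6, 6, 6))
  a <- m; a[2:3, 2:3, 2:3] <- TRUE          # 8 voxels
  expect_equal(dice(a, a), 1)
  b <- m; b[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dice(a, b), 0)
  c_ <- m; c_[2:3, 2:3, 3:4] <- TRUE        # overlap 4 of 8
  expect_equal(dice(a, c_), 0.5)
  expect_error(dice(m, m), "empty")
  set.seed(9)
  for (i in 1:20) {
    x <- array(runif(216) < 0.3, c(6, 6, 6))
    y <- array(runif(216) < 0.3, c(6, 6, 6))
    if (!any(x) && !any(y)) next
    d <- dice(x, y)
    expect_equal(d, 2 * sum(x & y) / (sum(x) + sum(y)))
    expect_equal(d, dice(y, x))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("rigid self-registration returns the identity", {
  case <- cached_case(1)
  tf <- rigid_register(case$structures, case$structures, "uterus")
  expect_lt(max(abs(tf$translation)), max(case$structures$spacing))
  expect_equal(attr(tf, "dsc"), 1, tolerance = 1e-9)
})

test_that("rigid registration recovers a known translation", {
  case <- cached_case(1)
  g <- grid_of(case$ct)
  push <- rigid_transform(translation = c(5, 0, 0))
  moved <- dirdose:::align_structures(case$structures, push, g)
  tf <- rigid_register(moved, case$structures, "uterus")
  # content moved +5 mm; recovering alignment needs -5 mm
  expect_equal(tf$translation[1], -5, tolerance = g$spacing[1] / 2)
  expect_lt(max(abs(tf$translation[2:3])), g$spacing[1] / 2 + 1e-9)
  # optimization cannot be worse than identity
  mv <- moved$masks$uterus
  expect_gte(attr(tf, "dsc"), dice(mv, case$structures$masks$uterus))
  s_empty <- case$structures; s_empty$masks$uterus[] <- FALSE
  expect_error(rigid_register(s_empty, case$structures), "empty")
})

test_that("deformable self-registration does not move and is monotone", {
  case <- generate_reference_case(test_spec(2))
  ct <- replace_applicator_hu(case$ct, case$structures$masks$applicator)
  cfg <- dir_config("hybrid", pyramid = c(2L, 1L), iterations = c(15L, 10L))
  u <- deformable_register(ct, ct, case$structures, case$structures, cfg)
  tr <- attr(u, "trace")
  for (lv in tr) expect_true(all(diff(lv) <= 0))
  # final objective no worse than the zero field's
  expect_lte(tail(tr[[length(tr)]], 1), tr[[1]][1])
  for (s in c("uterus", "rectum", "bladder")) {
    w <- warp_mask(case$structures$masks[[s]], u,
                   mask_grid = grid_of(case$ct))
    expect_gte(dice(w, case$structures$masks[[s]]), 0.99)
  }
})

test_that("registration is deterministic on identical inputs", {
  case <- cached_case(2)
  fr <- generate_deformed_frame(case, deformation_spec(), "BT_fraction", "bt2")
  g <- grid_of(case$ct)
  ref_ct <- replace_applicator_hu(case$ct, case$structures$masks$applicator)
  mov_ct <- replace_applicator_hu(fr$ct, fr$structures$masks$applicator)
  cfg <- dir_config("hybrid", pyramid = c(2L, 1L), iterations = c(10L, 5L))
  u1 <- deformable_register(mov_ct, ref_ct, fr$structures, case$structures, cfg)
  u2 <- deformable_register(mov_ct, ref_ct, fr$structures, case$structures, cfg)
  expect_identical(u1$offsets, u2$offsets)
  t1 <- rigid_register(fr$structures, case$structures)
  t2 <- rigid_register(fr$structures, case$structures)
  expect_identical(t1$translation, t2$translation)
  expect_identical(t1$rotation, t2$rotation)
})

test_that("mode contracts: missing structures rejected, intensity has no struct term", {
  case <- cached_case(1)
  ct <- case$ct
  s <- case$structures
  s$masks$bladder <- NULL
  expect_error(
    deformable_register(ct, ct, s, s, dir_config("hybrid")), "bladder")
  cfg <- dir_config("intensity")
  expect_equal(cfg$w_struct, 0)
  expect_identical(cfg$structures, "body")
})

test_that("hybrid DIR beats rigid alone on a deformed phantom pair", {
  sw <- registration_sweep()
  d <- sw$dsc
  m <- aggregate(dsc ~ method, data = d, FUN = mean)
  hy <- m$dsc[m$method == "hybrid"]
  ri <- m$dsc[m$method == "rigid"]
  expect_gt(hy, ri)
  t <- aggregate(tre ~ method, data = sw$tre, FUN = mean)
  expect_lt(t$tre[t$method == "hybrid"], t$tre[t$method == "rigid"])
})
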