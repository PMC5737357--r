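test_that("reference case generation is deterministic and anatomically valid", {
  a <- generate_reference_case(test_spec(3))
  b <- generate_reference_case(test_spec(3))
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$structures$masks, b$structures$masks)
  m <- a$structures$masks
  expect_false(any(m$uterus & m$rectum))
  expect_false(any(m$uterus & m$bladder))
  expect_false(any(m$rectum & m$bladder))
  expect_false(any((m$uterus | m$rectum | m$bladder) & !m$body))
  # applicator voxels are metal-like and inside the uterus canal region
  expect_true(all(a$ct$values[m$applicator] == a$spec$hu$applicator))
  expect_true(all(a$ct$values >= -1024 & a$ct$values <= 3071))
})

test_that("voxelized organ volumes match the analytic ellipsoid volume", {
  case <- cached_case(1)
  spec <- case$spec
  analytic <- 4 / 3 * pi * prod(spec$bladder_semi) / 1000
  voxel <- structure_volume_cm3(case$structures, "bladder")
  expect_lt(abs(voxel - analytic) / analytic, 0.10)
  analytic_ut <- 4 / 3 * pi * prod(spec$uterus_semi) / 1000
  expect_lt(abs(structure_volume_cm3(case$structures, "uterus") -
                  analytic_ut) / analytic_ut, 0.10)
})

test_that("zero-amplitude deformation is the identity", {
  case <- generate_reference_case(test_spec(2, noise_sd = 0))
  defs <- deformation_spec(applicator_push_mm = 0,
                           bladder_fill = c(bt2 = 1), rectum_scale = c(bt2 = 1))
  fr <- generate_deformed_frame(case, defs, "BT_fraction", "bt2")
  expect_true(all(fr$gt_field$offsets == 0))
  expect_equal(fr$ct$values, case$ct$values, tolerance = 1e-12)
  expect_identical(fr$structures$masks$uterus, case$structures$masks$uterus)
})

test_that("organ-filling scales change organ volumes in the stated direction", {
  case <- cached_case(1)
  defs <- deformation_spec()
  fr2 <- generate_deformed_frame(case, defs, "BT_fraction", "bt2")
  fr3 <- generate_deformed_frame(case, defs, "BT_fraction", "bt3")
  v0 <- structure_volume_cm3(case$structures, "bladder")
  expect_gt(structure_volume_cm3(fr2$structures, "bladder"), v0)  # fill 1.2
  expect_lt(structure_volume_cm3(fr3$structures, "bladder"), v0)  # fill 0.85
})

test_that("EBRT frame drops the applicator and moves the uterus", {
  case <- cached_case(1)
  fr <- generate_deformed_frame(case, deformation_spec(), "EBRT", "ebrt")
  expect_false("applicator" %in% names(fr$structures$masks))
  expect_true(max(fr$ct$values) < 2000)  # no metal voxels left
  d <- dice(fr$structures$masks$uterus, case$structures$masks$uterus)
  expect_lt(d, 1)
})

test_that("ground-truth fields are invertible at defaults, rejected when folding", {
  case <- cached_case(1)
  fr <- generate_deformed_frame(case, deformation_spec(), "EBRT", "ebrt")
  jd <- jacobian_determinant(fr$gt_field)
  expect_true(all(jd > 0, na.rm = TRUE))
  expect_error(
    generate_deformed_frame(case, deformation_spec(applicator_push_mm = 60),
                            "EBRT", "ebrt"),
    "not invertible")
})

test_that("full course generation is deterministic and complete", {
  spec <- test_spec(4)
  a <- generate_phantom_course(seed = 4, spec = spec)
  b <- generate_phantom_course(seed = 4, spec = spec)
  expect_identical(names(a$plans), c("BT1", "BT2", "BT3", "BT4", "WP", "CS"))
  expect_identical(names(a$frames), c("bt1", "bt2", "bt3", "bt4", "ebrt"))
  for (p in names(a$plans)) {
    expect_identical(a$plans[[p]]$dose$values, b$plans[[p]]$dose$values)
  }
  expect_false(a$plans$CS$include_in_addition)
  expect_true(all(vapply(a$plans[c("BT1", "WP")],
                         function(p) p$include_in_addition, logical(1))))
  expect_equal(a$manifest$ebrt_total_gy,
               a$manifest$wp_gy + a$manifest$cs_gy)
})

test_that("case directories round-trip", {
  course <- generate_phantom_course(seed = 5, spec = test_spec(5))
  dir <- withr::local_tempdir()
  write_case(course, dir)
  r <- read_case(dir)
  expect_identical(r$frames$bt1$ct$values, course$frames$bt1$ct$values)
  expect_identical(r$frames$bt2$structures$masks$bladder,
                   course$frames$bt2$structures$masks$bladder)
  expect_identical(r$frames$ebrt$gt_field$offsets,
                   course$frames$ebrt$gt_field$offsets)
  expect_identical(r$plans$CS$include_in_addition, FALSE)
  expect_equal(r$plans$BT2$dose$values, course$plans$BT2$dose$values)
})
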