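#' Synthetic pelvic phantom specification
#'
#' Defines the reference-frame geometry of a synthetic pelvic CT case: an
#' elliptic-cylinder body, ellipsoidal uterus and bladder, a tubular rectum, a
#' high-risk CTV around the cervix, and an intracavitary tandem applicator
#' (straight cylinder) inside the uterine canal. All lengths in mm (world
#' coordinates), HU assignments per tissue. Pelvic topology is enforced:
#' bladder anterior to the uterus, rectum posterior.
#'
#' @param dim Grid size in voxels (default `c(96, 96, 64)`).
#' @param spacing Voxel spacing mm (default 2.5 isotropic).
#' @param origin World position of the first voxel center.
#' @param body_center,body_semi Elliptic body cylinder (x/y center, semi-axes).
#' @param uterus_center,uterus_semi Uterus ellipsoid.
#' @param bladder_center,bladder_semi Bladder ellipsoid.
#' @param rectum_center Rectum tube axis point (x, y) and z mid-point.
#' @param rectum_radius,rectum_length Rectum tube radius / length (mm).
#' @param hrctv_center,hrctv_semi High-risk CTV ellipsoid.
#' @param applicator_radius Applicator cylinder radius (mm).
#' @param applicator_z Applicator axial extent `c(z_lo, z_hi)` (mm).
#' @param hu Named list of HU values per tissue.
#' @param noise_sd Approximate standard deviation of the smoothed CT noise
#'   (HU); 0 disables noise.
#' @param seed Random seed for the noise texture.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96L, 96L, 64L),
                         spacing = c(2.5, 2.5, 2.5),
                         origin = c(0, 0, 0),
                         body_center = c(119, 119),
                         body_semi = c(100, 82),
                         uterus_center = c(119, 117, 80),
                         uterus_semi = c(24, 30, 42),
                         bladder_center = c(119, 60, 74),
                         bladder_semi = c(26, 20, 24),
                         rectum_center = c(119, 167, 80),
                         rectum_radius = 14,
                         rectum_length = 110,
                         hrctv_center = c(119, 117, 58),
                         hrctv_semi = c(20, 20, 22),
                         applicator_radius = 3,
                         applicator_z = c(32, 94),
                         hu = list(air = -1000, soft = 35, uterus = 45,
                                   bladder = 10, rectum = 25,
                                   applicator = 3000),
                         noise_sd = 12,
                         seed = 1L) {
  if (!(bladder_center[2] < uterus_center[2] &&
        uterus_center[2] < rectum_center[2])) {
    stop("pelvic topology violated: need bladder anterior to uterus and ",
         "rectum posterior (bladder y < uterus y < rectum y)", call. = FALSE)
  }
  structure(
    list(dim = as.integer(dim), spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         body_center = body_center, body_semi = body_semi,
         uterus_center = uterus_center, uterus_semi = uterus_semi,
         bladder_center = bladder_center, bladder_semi = bladder_semi,
         rectum_center = rectum_center, rectum_radius = rectum_radius,
         rectum_length = rectum_length,
         hrctv_center = hrctv_center, hrctv_semi = hrctv_semi,
         applicator_radius = applicator_radius, applicator_z = applicator_z,
         hu = hu, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Ground-truth deformation specification
#'
#' Parameters of the analytic inter-fraction deformations: radial applicator
#' push/release around the tandem axis (Gaussian-profile falloff), per-fraction
#' organ-filling changes (radial scaling of bladder volume and rectum
#' diameter about the organ centroid), and the rigid pose offset of the
#' applicator-free EBRT frame. All resulting pull-back fields are smoothed and
#' checked for a positive discrete Jacobian (invertibility).
#'
#' @param applicator_push_mm Peak applicator-induced displacement (mm).
#' @param push_falloff_mm Radial falloff length of the push profile (mm).
#' @param bladder_fill Named per-frame bladder volume scale factors.
#' @param rectum_scale Named per-frame rectum diameter scale factors.
#' @param ebrt_rotation,ebrt_translation Rigid pose offset of the EBRT frame
#'   (Euler degrees; mm). Defaults: 3 degrees + 5 mm, a plausible
#'   inter-session setup difference.
#' @param smooth_sigma_vox Field smoothing in voxels.
#' @param seed Seed offset for per-frame CT noise.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(applicator_push_mm = 10,
                             push_falloff_mm = 30,
                             bladder_fill = c(bt2 = 1.2, bt3 = 0.85,
                                              bt4 = 1.1, ebrt = 1.12),
                             rectum_scale = c(bt2 = 0.9, bt3 = 1.15,
                                              bt4 = 1.05, ebrt = 0.95),
                             ebrt_rotation = c(3, 0, 0),
                             ebrt_translation = c(0, 3, 4),
                             smooth_sigma_vox = 1,
                             seed = 1L) {
  structure(
    list(applicator_push_mm = applicator_push_mm,
         push_falloff_mm = push_falloff_mm,
         bladder_fill = bladder_fill, rectum_scale = rectum_scale,
         ebrt_rotation = as.numeric(ebrt_rotation),
         ebrt_translation = as.numeric(ebrt_translation),
         smooth_sigma_vox = smooth_sigma_vox, seed = as.integer(seed)),
    class = "deformation_spec")
}

#' Course manifest: plans, fractionation, prescriptions
#'
#' One external-beam course (whole-pelvis + center-shielded plan summing to
#' the EBRT total) plus weekly HDR brachytherapy fractions prescribed to the
#' HR-CTV D90.
#'
#' @param wp_gy,wp_fractions Whole-pelvis plan total dose (Gy) and fractions.
#' @param cs_gy,cs_fractions Center-shielded plan total dose and fractions.
#' @param cs_block_width_mm Midline block width (mm).
#' @param cs_transmission Dose transmission under the block (fraction of the
#'   open dose; 0 = complete block).
#' @param bt_gy_per_fraction Prescription to HR-CTV D90 per BT session (Gy).
#' @param n_bt Number of BT fractions (>= 1; the first is the reference).
#' @param alpha_beta Linear-quadratic alpha/beta ratio (Gy) used for EQD2.
#' @return An object of class `course_manifest`.
#' @export
course_manifest <- function(wp_gy = 30, wp_fractions = 15,
                            cs_gy = 20, cs_fractions = 10,
                            cs_block_width_mm = 40, cs_transmission = 0,
                            bt_gy_per_fraction = 6, n_bt = 4,
                            alpha_beta = 3) {
  if (n_bt < 1) stop("need at least one BT fraction", call. = FALSE)
  structure(
    list(wp_gy = wp_gy, wp_fractions = as.integer(wp_fractions),
         cs_gy = cs_gy, cs_fractions = as.integer(cs_fractions),
         cs_block_width_mm = cs_block_width_mm,
         cs_transmission = cs_transmission,
         bt_gy_per_fraction = bt_gy_per_fraction, n_bt = as.integer(n_bt),
         ebrt_total_gy = wp_gy + cs_gy, alpha_beta = alpha_beta,
         reference_frame = "bt1"),
    class = "course_manifest")
}

# evaluate with a private RNG stream, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# world-coordinate arrays for each axis on a grid
coord_arrays <- function(grid) {
  g <- grid_of(grid)
  x <- g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1]
  y <- g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2]
  z <- g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3]
  list(
    x = array(rep(x, times = g$dim[2] * g$dim[3]), g$dim),
    y = array(rep(rep(y, each = g$dim[1]), times = g$dim[3]), g$dim),
    z = array(rep(z, each = g$dim[1] * g$dim[2]), g$dim)
  )
}

smoothed_noise <- function(dim, sd, seed) {
  if (sd <= 0) return(array(0, dim))
  raw <- with_local_seed(seed, array(stats::rnorm(prod(dim)), dim))
  sm <- cpp_gauss3(raw, dim, c(1, 1, 1))
  sm * (sd / stats::sd(sm))
}

#' Generate the reference brachytherapy case
#'
#' Voxelizes the phantom geometry into a CT volume and structure set for the
#' reference frame (first BT fraction): organs rendered at their tissue HU
#' over a soft-tissue body, tissue interfaces softened by light smoothing,
#' metal-like applicator voxels inside the uterine canal, plus a seeded
#' smooth noise texture. Deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ct` (a `scalar_volume`) and `structures`
#'   (a `structure_set` with uterus, rectum, bladder, body, hrctv,
#'   applicator), plus the `spec` itself.
#' @export
generate_reference_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- list(dim = spec$dim, spacing = spec$spacing, origin = spec$origin)
  co <- coord_arrays(g)
  ell <- function(center, semi) {
    ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
      ((co$z - center[3]) / semi[3])^2 <= 1
  }
  body <- ((co$x - spec$body_center[1]) / spec$body_semi[1])^2 +
    ((co$y - spec$body_center[2]) / spec$body_semi[2])^2 <= 1
  uterus <- ell(spec$uterus_center, spec$uterus_semi)
  bladder <- ell(spec$bladder_center, spec$bladder_semi)
  rectum <- (co$x - spec$rectum_center[1])^2 +
    (co$y - spec$rectum_center[2])^2 <= spec$rectum_radius^2 &
    abs(co$z - spec$rectum_center[3]) <= spec$rectum_length / 2
  hrctv <- ell(spec$hrctv_center, spec$hrctv_semi)
  applicator <- (co$x - spec$uterus_center[1])^2 +
    (co$y - spec$uterus_center[2])^2 <= spec$applicator_radius^2 &
    co$z >= spec$applicator_z[1] & co$z <= spec$applicator_z[2]
  if (any(uterus & bladder) || any(uterus & rectum) || any(bladder & rectum)) {
    stop("phantom spec implies overlapping organs; adjust centers/semi-axes",
         call. = FALSE)
  }
  if (any((uterus | bladder | rectum | hrctv) & !body)) {
    stop("phantom spec places organs outside the body", call. = FALSE)
  }
  hu <- spec$hu
  ct <- array(hu$air, g$dim)
  ct[body] <- hu$soft
  ct[uterus] <- hu$uterus
  ct[hrctv] <- hu$uterus
  ct[bladder] <- hu$bladder
  ct[rectum] <- hu$rectum
  ct <- cpp_gauss3(ct, g$dim, c(1, 1, 1))      # soft tissue interfaces
  ct <- ct + smoothed_noise(g$dim, spec$noise_sd, spec$seed)
  ct[applicator] <- hu$applicator
  ct <- pmin(pmax(ct, -1024), 3071)
  structures <- structure_set(
    list(uterus = uterus, rectum = rectum, bladder = bladder, body = body,
         hrctv = hrctv, applicator = applicator),
    spacing = g$spacing, origin = g$origin)
  list(ct = scalar_volume(ct, g$spacing, g$origin),
       structures = structures, spec = spec)
}

# pull-back organ-filling field: radial scaling about the organ center with a
# smooth falloff outside the organ (rho <= 1 inside)
fill_field_ellipsoid <- function(co, center, semi, scale) {
  rho <- sqrt(((co$x - center[1]) / semi[1])^2 +
                ((co$y - center[2]) / semi[2])^2 +
                ((co$z - center[3]) / semi[3])^2)
  w <- ifelse(rho <= 1, 1, exp(-((rho - 1) / 0.5)^2))
  k <- (1 / scale - 1) * w
  list(x = (co$x - center[1]) * k,
       y = (co$y - center[2]) * k,
       z = (co$z - center[3]) * k)
}

fill_field_tube <- function(co, center, radius, length, scale) {
  rho <- sqrt((co$x - center[1])^2 + (co$y - center[2])^2) / radius
  w <- ifelse(rho <= 1, 1, exp(-((rho - 1) / 0.5)^2))
  dz <- abs(co$z - center[3]) - length / 2
  wz <- ifelse(dz <= 0, 1, exp(-(dz / 15)^2))
  k <- (1 / scale - 1) * w * wz
  list(x = (co$x - center[1]) * k, y = (co$y - center[2]) * k,
       z = array(0, dim(co$x)))
}

# applicator release field (EBRT frame): sampling pushed radially outward from
# the tandem axis, Gaussian radial profile peaking at the falloff length
release_field <- function(co, axis_xy, z_range, amplitude, falloff) {
  dx <- co$x - axis_xy[1]; dy <- co$y - axis_xy[2]
  rho <- sqrt(dx^2 + dy^2)
  f <- amplitude * (rho / falloff) * exp(0.5 - rho^2 / (2 * falloff^2))
  dz <- pmax(co$z - z_range[2], z_range[1] - co$z)
  wz <- ifelse(dz <= 0, 1, exp(-(dz / 20)^2))
  scale <- ifelse(rho > 0, f * wz / pmax(rho, 1e-9), 0)
  list(x = dx * scale, y = dy * scale, z = array(0, dim(co$x)))
}

add_fields <- function(a, b) list(x = a$x + b$x, y = a$y + b$y, z = a$z + b$z)

#' Generate a deformed treatment frame with known ground truth
#'
#' Produces a new CT frame plus consistently warped masks and the *exact*
#' pull-back displacement field used to create them. For
#' `kind = "BT_fraction"` only inter-fraction organ-filling changes apply
#' (bladder volume and rectum diameter scaling). For `kind = "EBRT"` the
#' applicator is absent (its voxels replaced by uterine tissue before
#' warping), the tissue around the canal relaxes radially by the applicator
#' push amplitude, and the whole frame is rigidly re-posed by the spec's
#' offset.
#'
#' The generative field uses the pull-back convention (the new frame samples
#' the reference at `y + h(y)`), so the stored field maps points of the new
#' frame into the reference. Fields with a non-positive discrete Jacobian are
#' rejected.
#'
#' @param case Output of [generate_reference_case()].
#' @param defspec A [deformation_spec()].
#' @param kind `"BT_fraction"` or `"EBRT"`.
#' @param frame_id Frame label selecting the per-frame filling scales
#'   (`"bt2"`, `"bt3"`, `"bt4"`, `"ebrt"`).
#' @return A list with `ct`, `structures`, `gt_field` (a
#'   `displacement_field`), and `frame_id`.
#' @export
generate_deformed_frame <- function(case, defspec,
                                    kind = c("BT_fraction", "EBRT"),
                                    frame_id = "bt2") {
  kind <- match.arg(kind)
  spec <- case$spec
  g <- grid_of(case$ct)
  co <- coord_arrays(g)
  bl_scale <- if (frame_id %in% names(defspec$bladder_fill))
    defspec$bladder_fill[[frame_id]] else 1
  rc_scale <- if (frame_id %in% names(defspec$rectum_scale))
    defspec$rectum_scale[[frame_id]] else 1
  h <- list(x = array(0, g$dim), y = array(0, g$dim), z = array(0, g$dim))
  if (bl_scale != 1) {
    h <- add_fields(h, fill_field_ellipsoid(co, spec$bladder_center,
                                            spec$bladder_semi, bl_scale))
  }
  if (rc_scale != 1) {
    h <- add_fields(h, fill_field_tube(co, spec$rectum_center,
                                       spec$rectum_radius,
                                       spec$rectum_length, rc_scale))
  }
  if (kind == "EBRT" && defspec$applicator_push_mm != 0) {
    h <- add_fields(h, release_field(co, spec$uterus_center[1:2],
                                     spec$applicator_z,
                                     defspec$applicator_push_mm,
                                     defspec$push_falloff_mm))
  }
  sm <- defspec$smooth_sigma_vox
  if (sm > 0) {
    for (k in c("x", "y", "z")) h[[k]] <- cpp_gauss3(h[[k]], g$dim, rep(sm, 3))
  }
  h_arr <- array(c(h$x, h$y, h$z), dim = c(g$dim, 3))

  if (kind == "EBRT") {
    center <- g$origin + (g$dim - 1) * g$spacing / 2
    pose <- rigid_transform(defspec$ebrt_rotation, defspec$ebrt_translation,
                            center = center)
    base_pts <- grid_world_coords(g)
    gy <- transform_points(pose, base_pts, inverse = TRUE)
    h_field0 <- displacement_field(h_arr, g$spacing, g$origin)
    H <- gy + sample_field(h_field0, gy) - base_pts
    gt_field <- displacement_field(array(H, dim = c(g$dim, 3)),
                                   g$spacing, g$origin)
  } else {
    gt_field <- displacement_field(h_arr, g$spacing, g$origin)
  }

  jd <- jacobian_determinant(gt_field)
  if (any(jd <= 0, na.rm = TRUE)) {
    stop("deformation is not invertible (Jacobian <= 0); reduce amplitudes ",
         "(applicator push ", defspec$applicator_push_mm, " mm, bladder scale ",
         bl_scale, ", rectum scale ", rc_scale, ")", call. = FALSE)
  }

  src_ct <- case$ct
  src_masks <- case$structures$masks
  if (kind == "EBRT") {
    v <- src_ct$values
    v[src_masks$applicator] <- spec$hu$uterus
    src_ct <- scalar_volume(v, src_ct$spacing, src_ct$origin)
    src_masks <- src_masks[setdiff(names(src_masks), "applicator")]
  }
  ct_new <- warp_volume(src_ct, gt_field, mode = "linear", fill = spec$hu$air)
  frame_index <- match(frame_id, c("bt2", "bt3", "bt4", "ebrt"), nomatch = 9L)
  noise_seed <- (spec$seed * 131L + defspec$seed * 7L + frame_index) %% .Machine$integer.max
  ct_new$values <- pmin(pmax(
    ct_new$values + smoothed_noise(g$dim, spec$noise_sd, noise_seed),
    -1024), 3071)
  masks_new <- lapply(src_masks, function(m) warp_mask(m, gt_field,
                                                       mask_grid = g))
  # warping can create single-voxel ties at shared boundaries; restore the
  # anatomical invariants deterministically (uterus > rectum > bladder)
  if (!is.null(masks_new$rectum)) {
    masks_new$rectum <- masks_new$rectum & !masks_new$uterus
  }
  if (!is.null(masks_new$bladder)) {
    masks_new$bladder <- masks_new$bladder & !masks_new$uterus &
      !masks_new$rectum
  }
  for (o in intersect(c("uterus", "rectum", "bladder"), names(masks_new))) {
    masks_new[[o]] <- masks_new[[o]] & masks_new$body
  }
  structures <- structure_set(masks_new, spacing = g$spacing,
                              origin = g$origin)
  list(ct = ct_new, structures = structures, gt_field = gt_field,
       frame_id = frame_id, kind = kind)
}
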