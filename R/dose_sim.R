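#' Simulate a brachytherapy fraction dose
#'
#' Inverse-square dwell-sum model: `dose = S * sum_i (r0 / r_i)^2` with
#' `r0 = 10` mm and `r_i` the distance to dwell position i, floored at half
#' the voxel diagonal to avoid the source singularity. The common scale `S`
#' is chosen so that the HR-CTV D90 equals the prescription exactly. This
#' deliberately reproduces only the sharp applicator-centred gradient of an
#' HDR source train; anisotropy and radial dose functions are out of scope.
#'
#' @param structs A `structure_set` with nonempty `applicator` and `hrctv`.
#' @param dwells Optional n x 3 matrix of dwell positions (world mm). By
#'   default 5 dwells spaced 5 mm along the applicator axis, centred on the
#'   HR-CTV.
#' @param prescription Dose prescribed to the HR-CTV D90 (Gy per fraction).
#' @param r0 Reference radius (mm).
#' @return A `scalar_volume` dose in Gy on the structure grid.
#' @export
simulate_bt_dose <- function(structs, dwells = NULL, prescription = 6,
                             r0 = 10) {
  stopifnot(inherits(structs, "structure_set"))
  if (is.null(structs$masks$hrctv) || !any(structs$masks$hrctv)) {
    stop("empty HR-CTV mask: cannot normalize the prescription", call. = FALSE)
  }
  g <- grid_of(structs)
  if (is.null(dwells)) {
    app <- structs$masks$applicator
    if (is.null(app) || !any(app)) {
      stop("no applicator present: cannot place dwell positions", call. = FALSE)
    }
    idx <- arrayInd(which(app), g$dim)
    axis_xy <- g$origin[1:2] + (colMeans(idx)[1:2] - 1) * g$spacing[1:2]
    hr_idx <- arrayInd(which(structs$masks$hrctv), g$dim)
    z_mid <- g$origin[3] + (mean(hr_idx[, 3]) - 1) * g$spacing[3]
    z_app <- range(g$origin[3] + (idx[, 3] - 1) * g$spacing[3])
    zs <- pmin(pmax(z_mid + seq(-10, 10, by = 5), z_app[1]), z_app[2])
    dwells <- cbind(axis_xy[1], axis_xy[2], zs)
  }
  dwells <- as.matrix(dwells)
  if (nrow(dwells) < 1) stop("need at least one dwell position", call. = FALSE)
  co <- coord_arrays(g)
  rmin <- sqrt(sum(g$spacing^2)) / 2
  unit <- array(0, g$dim)
  for (i in seq_len(nrow(dwells))) {
    r2 <- (co$x - dwells[i, 1])^2 + (co$y - dwells[i, 2])^2 +
      (co$z - dwells[i, 3])^2
    unit <- unit + r0^2 / pmax(r2, rmin^2)
  }
  unit_vol <- scalar_volume(unit, g$spacing, g$origin)
  s <- prescription / d90(unit_vol, structs$masks$hrctv)
  scalar_volume(unit * s, g$spacing, g$origin)
}

# product of logistic edge profiles: ~1 inside [lo, hi], 0.5 exactly at the
# edges, with 'penumbra' controlling the edge steepness
box_profile <- function(v, lo, hi, penumbra) {
  stats::plogis(4 * (v - lo) / penumbra) * stats::plogis(4 * (hi - v) / penumbra)
}

#' Simulate a whole-pelvis 4-field-box EBRT dose
#'
#' Near-uniform dose inside an axis-aligned box with sigmoidal penumbra at the
#' field edges and ~0 outside, emulating the composite of a 4-field box
#' technique.
#'
#' @param structs A `structure_set` with a nonempty `body` mask.
#' @param total Plan total dose (Gy).
#' @param center Box center (world mm); defaults to the body-mask centroid.
#' @param half_widths Per-axis half-widths of the box (mm).
#' @param penumbra Penumbra width parameter (mm; 50% at the field edge).
#' @return A `scalar_volume` dose in Gy.
#' @export
simulate_ebrt_wp <- function(structs, total = 30, center = NULL,
                             half_widths = c(70, 70, 55), penumbra = 6) {
  stopifnot(inherits(structs, "structure_set"))
  body <- structs$masks$body
  if (is.null(body) || !any(body)) stop("body mask required", call. = FALSE)
  g <- grid_of(structs)
  if (is.null(center)) {
    idx <- arrayInd(which(body), g$dim)
    center <- g$origin + (colMeans(idx) - 1) * g$spacing
  }
  co <- coord_arrays(g)
  inside_box <- abs(co$x - center[1]) <= half_widths[1] &
    abs(co$y - center[2]) <= half_widths[2] &
    abs(co$z - center[3]) <= half_widths[3]
  if (!any(inside_box & body)) {
    stop("field box does not intersect the body", call. = FALSE)
  }
  dose <- total *
    box_profile(co$x, center[1] - half_widths[1], center[1] + half_widths[1], penumbra) *
    box_profile(co$y, center[2] - half_widths[2], center[2] + half_widths[2], penumbra) *
    box_profile(co$z, center[3] - half_widths[3], center[3] + half_widths[3], penumbra)
  scalar_volume(dose, g$spacing, g$origin)
}

#' Simulate a center-shielded AP/PA EBRT dose
#'
#' AP/PA parallel-opposed box dose with a midline block: a central
#' left-right strip of the stated width (full height) is reduced to
#' `transmission * total`, emulating the midline shield that spares the zone
#' receiving the highest brachytherapy dose. Outside the strip the dose
#' behaves like the open box.
#'
#' @param structs A `structure_set` with a nonempty `body` mask.
#' @param total Plan total dose (Gy).
#' @param block_width Width of the midline block in the left-right (x)
#'   direction (mm); default 40 mm.
#' @param transmission Fractional transmission under the block (default 0).
#' @param midline_x Block center in x (mm); defaults to the uterus centroid x
#'   when present, else the body centroid x.
#' @param center,half_widths,penumbra Open-field box as in
#'   [simulate_ebrt_wp()].
#' @param block_penumbra Block edge steepness (mm).
#' @return A `scalar_volume` dose in Gy.
#' @export
simulate_ebrt_cs <- function(structs, total = 20, block_width = 40,
                             transmission = 0, midline_x = NULL,
                             center = NULL, half_widths = c(70, 70, 55),
                             penumbra = 6, block_penumbra = 1.5) {
  if (block_width <= 0) stop("block width must be positive", call. = FALSE)
  if (block_width >= 2 * half_widths[1]) {
    stop("midline block (", block_width, " mm) is as wide as the field",
         call. = FALSE)
  }
  open <- simulate_ebrt_wp(structs, total = total, center = center,
                           half_widths = half_widths, penumbra = penumbra)
  g <- grid_of(structs)
  if (is.null(midline_x)) {
    m <- if (!is.null(structs$masks$uterus) && any(structs$masks$uterus)) {
      structs$masks$uterus
    } else structs$masks$body
    idx <- arrayInd(which(m), g$dim)
    midline_x <- g$origin[1] + (mean(idx[, 1]) - 1) * g$spacing[1]
  }
  co <- coord_arrays(g)
  hw <- block_width / 2
  blocked <- box_profile(co$x, midline_x - hw, midline_x + hw, block_penumbra)
  factor <- 1 - (1 - transmission) * blocked
  scalar_volume(open$values * factor, g$spacing, g$origin)
}
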