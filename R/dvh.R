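#' Cumulative dose-volume histogram of an organ
#'
#' Exact voxel counting on uniform dose-bin edges: `volume(b)` is the organ
#' volume (cm^3) receiving at least the dose of edge `b`. No smoothing; the
#' value at 0 Gy is the total organ volume.
#'
#' @param dose A `scalar_volume` in Gy.
#' @param organ Binary mask (3D array or 0/1 `scalar_volume`) on the dose
#'   grid; must be nonempty.
#' @param bin_width Bin width in Gy (default 0.1).
#' @return A tibble of class `dvh_curve` with columns `dose_gy` and
#'   `volume_cm3`, plus attributes `organ_volume_cm3` and `bin_width`.
#' @export
compute_dvh <- function(dose, organ, bin_width = 0.1) {
  stopifnot(inherits(dose, "scalar_volume"))
  m <- organ_mask(dose, organ)
  vv <- voxel_volume_cm3(dose)
  d <- dose$values[m]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  ds <- sort(d)
  n <- length(ds)
  # voxels with dose >= edge, via binary search on the sorted doses
  counts <- n - findInterval(edges - 1e-12, ds)
  out <- tibble::tibble(dose_gy = edges, volume_cm3 = counts * vv)
  class(out) <- c("dvh_curve", class(out))
  attr(out, "organ_volume_cm3") <- n * vv
  attr(out, "bin_width") <- bin_width
  out
}

organ_mask <- function(dose, organ) {
  m <- if (inherits(organ, "scalar_volume")) {
    stop_if_grid_mismatch(dose, organ, "dose and organ mask")
    organ$values >= 0.5
  } else {
    if (!identical(dim(organ), dim(dose$values))) {
      stop("organ mask grid does not match the dose grid", call. = FALSE)
    }
    array(as.logical(organ), dim = dim(organ))
  }
  if (!any(m)) stop("organ mask is empty", call. = FALSE)
  m
}

#' Minimum dose to the most exposed x cm^3 (D_x cm^3)
#'
#' Exact voxel sorting with partial-voxel linear interpolation: organ voxel
#' doses are sorted descending and voxel volumes accumulated until
#' `volume_cm3` is reached; the dose at the crossing is interpolated linearly
#' between the bracketing voxels in proportion to the partial-voxel volume.
#' As `volume_cm3` tends to 0 the result tends to the maximum organ dose.
#'
#' @param dose A `scalar_volume` in Gy (physical or EQD2).
#' @param organ Binary mask on the dose grid.
#' @param volume_cm3 Evaluated hottest volume in cm^3 (> 0, at most the organ
#'   volume).
#' @return Dose in Gy.
#' @examples
#' # 30 voxels of 0.1 cm3 with doses 1..30 Gy: the hottest 1 cm3 is the top
#' # 10 voxels, whose minimum dose is 21 Gy
#' dose <- scalar_volume(array(1:30, c(30, 1, 1)), spacing = c(10, 10, 1))
#' d_cc(dose, array(TRUE, c(30, 1, 1)), 1)
#' @export
d_cc <- function(dose, organ, volume_cm3) {
  stopifnot(inherits(dose, "scalar_volume"))
  m <- organ_mask(dose, organ)
  if (!is.numeric(volume_cm3) || volume_cm3 <= 0) {
    stop("`volume_cm3` must be positive", call. = FALSE)
  }
  vv <- voxel_volume_cm3(dose)
  d <- sort(dose$values[m], decreasing = TRUE)
  n <- length(d)
  if (volume_cm3 > n * vv * (1 + 1e-9)) {
    stop(sprintf("requested %.3f cm3 exceeds the organ volume (%.3f cm3)",
                 volume_cm3, n * vv), call. = FALSE)
  }
  q <- volume_cm3 / vv
  m0 <- floor(q + 1e-9)
  frac <- q - m0
  if (m0 == 0) return(d[1])
  if (m0 >= n || frac <= 1e-9) return(d[m0])
  d[m0] + frac * (d[m0 + 1] - d[m0])
}

#' Minimum dose covering 90% of a target volume (D90)
#'
#' `d_cc` evaluated at 90% of the target volume, the standard coverage metric
#' of the high-risk CTV prescription.
#'
#' @param dose A `scalar_volume` in Gy.
#' @param target Binary target mask on the dose grid; nonempty.
#' @return Dose in Gy.
#' @export
d90 <- function(dose, target) {
  m <- organ_mask(dose, target)
  vv <- voxel_volume_cm3(dose)
  d_cc(dose, m, 0.9 * sum(m) * vv)
}

#' DVH parameter addition across plans
#'
#' The GEC-ESTRO-style baseline: each plan's D_x cm^3 is computed in EQD2 on
#' the organ mask of the plan's *own* frame, then the per-plan values are
#' summed. The method assumes the hottest subvolumes of all plans co-locate.
#' Plans flagged `include_in_addition = FALSE` (center-shielded plans) are
#' skipped.
#'
#' @param plans List of [fraction_plan()]s.
#' @param organ_masks Named list keyed by frame id giving the organ mask on
#'   each plan's frame.
#' @param volume_cm3 Evaluated hottest volume (cm^3).
#' @param alpha_beta Alpha/beta ratio (Gy) for the EQD2 conversion.
#' @return Summed dose in Gy EQD2.
#' @export
dvh_parameter_addition <- function(plans, organ_masks, volume_cm3,
                                   alpha_beta = 3) {
  included <- Filter(function(p) p$include_in_addition, plans)
  if (length(included) == 0) {
    stop("no plans are included in DVH parameter addition", call. = FALSE)
  }
  total <- 0
  for (plan in included) {
    mask <- organ_masks[[plan$frame_id]]
    if (is.null(mask)) {
      stop("no organ mask supplied for frame `", plan$frame_id, "`",
           call. = FALSE)
    }
    total <- total + d_cc(eqd2_convert(plan, alpha_beta), mask, volume_cm3)
  }
  total
}

#' @rdname compute_dvh
#' @param object,... A `dvh_curve` (autoplot method).
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy, y = .data$volume_cm3)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (Gy)", y = expression(Volume ~ (cm^3)),
                  title = "Cumulative DVH") +
    ggplot2::theme_minimal()
}
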