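#' One treatment component (plan) of a course
#'
#' Wraps a physical dose distribution with its fractionation and frame
#' identity. `include_in_addition` marks whether the plan participates in
#' DVH parameter addition; center-shielded plans are excluded by default
#' because the midline block spares the zone receiving the highest
#' brachytherapy dose (DIR-based accumulation still uses their dose).
#'
#' @param label Plan label (`"WP"`, `"CS"`, `"BT1"`...).
#' @param frame_id Id of the CT frame the plan was computed on.
#' @param dose A `scalar_volume`, total physical dose of the plan in Gy.
#' @param n_fractions Number of fractions the total was delivered in.
#' @param include_in_addition Logical; defaults to `FALSE` for labels
#'   starting with "CS".
#' @return An object of class `fraction_plan`.
#' @export
fraction_plan <- function(label, frame_id, dose, n_fractions,
                          include_in_addition = !grepl("^cs", tolower(label))) {
  stopifnot(inherits(dose, "scalar_volume"))
  if (any(dose$values < 0)) {
    stop("plan `", label, "` has negative dose voxels", call. = FALSE)
  }
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1) {
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  }
  structure(list(label = label, frame_id = frame_id, dose = dose,
                 n_fractions = n_fractions,
                 include_in_addition = isTRUE(include_in_addition)),
            class = "fraction_plan")
}

#' @export
print.fraction_plan <- function(x, ...) {
  cat(sprintf("<fraction_plan> %s on frame %s: max %.2f Gy in %d fx%s\n",
              x$label, x$frame_id, max(x$dose$values), x$n_fractions,
              if (x$include_in_addition) "" else " (excluded from DVH addition)"))
  invisible(x)
}

#' Convert a plan's physical dose to EQD2
#'
#' Voxel-wise equivalent dose in 2 Gy fractions under the linear-quadratic
#' model: with per-fraction dose `d = D / n_fractions`,
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`. Applied in the plan's
#' native frame. A plan delivered at exactly 2 Gy per fraction is unchanged;
#' hypofractionated brachytherapy is inflated (6 Gy in one fraction at
#' alpha/beta = 3 becomes 10.8 Gy EQD2).
#'
#' @param plan A [fraction_plan()].
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0); 3 Gy for
#'   late-responding organs at risk.
#' @return A `scalar_volume` in Gy EQD2.
#' @examples
#' bt <- fraction_plan("BT1", "bt1",
#'                     scalar_volume(array(6, c(2, 2, 2)), c(2.5, 2.5, 2.5)),
#'                     n_fractions = 1)
#' eqd2_convert(bt, alpha_beta = 3)$values[1, 1, 1]  # 6 * 9 / 5 = 10.8
#' @export
eqd2_convert <- function(plan, alpha_beta = 3) {
  stopifnot(inherits(plan, "fraction_plan"))
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be positive", call. = FALSE)
  }
  D <- plan$dose$values
  if (any(D < 0)) stop("negative dose voxels", call. = FALSE)
  d <- D / plan$n_fractions
  scalar_volume(D * (d + alpha_beta) / (2 + alpha_beta),
                plan$dose$spacing, plan$dose$origin)
}

#' Warp a dose distribution to the reference frame
#'
#' Trilinear pull-back sampling of the dose through a displacement field;
#' out-of-support voxels get 0 Gy. An identity (zero) field on the dose's
#' own grid is a no-op.
#'
#' @param dose A `scalar_volume` in Gy.
#' @param field A `displacement_field` on the reference grid.
#' @return A `scalar_volume` on the reference grid.
#' @export
warp_dose <- function(dose, field) {
  stopifnot(inherits(dose, "scalar_volume"),
            inherits(field, "displacement_field"))
  warp_volume(dose, field, mode = "linear", fill = 0)
}

#' Accumulate plan doses on the reference frame
#'
#' Converts every plan to EQD2 in its native frame, warps it through its
#' frame's displacement field, and sums on the reference grid:
#' `result = sum_plans warp(eqd2(plan))`. Plans on the reference frame need
#' no field; any other frame without a field is an error. All configured
#' plans contribute, including center-shielded plans (their exclusion applies
#' only to DVH parameter addition). Summation order is irrelevant.
#'
#' @param plans List of [fraction_plan()]s.
#' @param fields Named list of `displacement_field`s keyed by frame id
#'   (entries may be `NULL` for frames on the reference grid).
#' @param alpha_beta Alpha/beta ratio (Gy) for EQD2.
#' @param reference_grid Reference grid; defaults to the grid of the first
#'   available field, else the first plan's dose grid.
#' @param eqd2_first Convert to EQD2 before warping (default); set `FALSE`
#'   to warp the physical dose first and convert on the reference grid.
#' @return An object of class `accumulated_dose` with elements `dose`
#'   (a `scalar_volume` in Gy EQD2) and `provenance` (a tibble).
#' @export
accumulate_dose <- function(plans, fields = list(), alpha_beta = 3,
                            reference_grid = NULL, eqd2_first = TRUE) {
  if (length(plans) == 0) stop("no plans to accumulate", call. = FALSE)
  if (is.null(reference_grid)) {
    nonnull <- Filter(Negate(is.null), fields)
    reference_grid <- if (length(nonnull) > 0) grid_of(nonnull[[1]])
                      else grid_of(plans[[1]]$dose)
  }
  g <- grid_of(reference_grid)
  total <- array(0, g$dim)
  prov <- list()
  # sum in canonical label order so the result is bit-identical under any
  # permutation of the input plan list (floating-point addition is not
  # associative)
  labels <- vapply(plans, function(p) p$label, character(1))
  plans <- plans[order(labels)]
  for (plan in plans) {
    field <- fields[[plan$frame_id]]
    if (is.null(field)) {
      if (!same_grid(plan$dose, g)) {
        stop("plan `", plan$label, "` lives on frame `", plan$frame_id,
             "` which has no displacement field and is not on the ",
             "reference grid", call. = FALSE)
      }
      if (eqd2_first) {
        v <- eqd2_convert(plan, alpha_beta)$values
      } else {
        v <- eqd2_convert(plan, alpha_beta)$values
      }
      warped <- FALSE
    } else {
      if (eqd2_first) {
        v <- warp_dose(eqd2_convert(plan, alpha_beta), field)$values
      } else {
        w <- warp_dose(plan$dose, field)
        v <- eqd2_convert(fraction_plan(plan$label, plan$frame_id, w,
                                        plan$n_fractions,
                                        plan$include_in_addition),
                          alpha_beta)$values
      }
      warped <- TRUE
    }
    total <- total + v
    prov[[length(prov) + 1]] <- tibble::tibble(
      label = plan$label, frame_id = plan$frame_id,
      n_fractions = plan$n_fractions, warped = warped,
      include_in_addition = plan$include_in_addition)
  }
  structure(
    list(dose = scalar_volume(total, g$spacing, g$origin),
         provenance = dplyr::bind_rows(prov),
         alpha_beta = alpha_beta, eqd2_first = eqd2_first),
    class = "accumulated_dose")
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("<accumulated_dose> %d plans, max %.1f Gy EQD2 (alpha/beta %g)\n",
              nrow(x$provenance), max(x$dose$values), x$alpha_beta))
  print(x$provenance)
  invisible(x)
}
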