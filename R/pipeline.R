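#' Generate a complete synthetic phantom course
#'
#' Builds the full study object for one synthetic patient: the reference
#' brachytherapy frame (BT1), further BT frames with inter-fraction
#' organ-filling changes, an applicator-free EBRT frame with a rigid pose
#' offset and relaxed canal anatomy, per-plan physical doses (inverse-square
#' BT dwell doses normalized to the HR-CTV D90 prescription; whole-pelvis box
#' and center-shielded AP/PA doses on the EBRT frame), and the stored
#' ground-truth deformation fields. Deterministic for a fixed seed.
#'
#' @param seed Case seed (drives geometry noise textures).
#' @param spec A [phantom_spec()]; its seed is overridden by `seed`.
#' @param defspec A [deformation_spec()].
#' @param manifest A [course_manifest()].
#' @return An object of class `phantom_course`: a list with `frames` (named
#'   list of `ct`/`structures`/`gt_field`), `plans` (list of
#'   [fraction_plan()]s), `manifest`, and `seed`.
#' @export
generate_phantom_course <- function(seed = 1L,
                                    spec = NULL,
                                    defspec = deformation_spec(),
                                    manifest = course_manifest()) {
  seed <- as.integer(seed)
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  else spec$seed <- seed
  ref <- generate_reference_case(spec)
  frames <- list(bt1 = list(ct = ref$ct, structures = ref$structures,
                            gt_field = NULL, frame_id = "bt1"))
  bt_ids <- if (manifest$n_bt >= 2) paste0("bt", 2:manifest$n_bt) else character(0)
  for (fid in bt_ids) {
    frames[[fid]] <- generate_deformed_frame(ref, defspec, "BT_fraction", fid)
  }
  frames$ebrt <- generate_deformed_frame(ref, defspec, "EBRT", "ebrt")

  plans <- list()
  for (i in seq_len(manifest$n_bt)) {
    fid <- paste0("bt", i)
    dose <- simulate_bt_dose(frames[[fid]]$structures,
                             prescription = manifest$bt_gy_per_fraction)
    plans[[paste0("BT", i)]] <- fraction_plan(paste0("BT", i), fid, dose,
                                              n_fractions = 1L)
  }
  plans$WP <- fraction_plan("WP", "ebrt",
                            simulate_ebrt_wp(frames$ebrt$structures,
                                             total = manifest$wp_gy),
                            n_fractions = manifest$wp_fractions)
  plans$CS <- fraction_plan("CS", "ebrt",
                            simulate_ebrt_cs(frames$ebrt$structures,
                                             total = manifest$cs_gy,
                                             block_width = manifest$cs_block_width_mm,
                                             transmission = manifest$cs_transmission),
                            n_fractions = manifest$cs_fractions)
  structure(list(frames = frames, plans = plans, manifest = manifest,
                 spec = spec, defspec = defspec, seed = seed),
            class = "phantom_course")
}

#' @export
print.phantom_course <- function(x, ...) {
  cat(sprintf("<phantom_course> seed %d: %d frames, %d plans (%s)\n",
              x$seed, length(x$frames), length(x$plans),
              paste(names(x$plans), collapse = ", ")))
  invisible(x)
}

#' Write / read a phantom course as a case directory
#'
#' Serializes a course to NIfTI volumes (CT, per-plan dose, masks,
#' ground-truth fields) plus a JSON manifest, and reads it back. The
#' round-trip preserves grids and values at stored precision.
#'
#' @param course A `phantom_course`.
#' @param dir Case directory.
#' @return `dir` (write) / a `phantom_course` (read).
#' @export
write_case <- function(course, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fid in names(course$frames)) {
    fr <- course$frames[[fid]]
    fdir <- file.path(dir, fid)
    dir.create(fdir, showWarnings = FALSE)
    write_volume(fr$ct, file.path(fdir, "ct.nii.gz"))
    write_structures(fr$structures, fdir)
    if (!is.null(fr$gt_field)) {
      write_field(fr$gt_field, file.path(fdir, "gt_field.nii.gz"))
    }
  }
  plan_meta <- list()
  for (lbl in names(course$plans)) {
    p <- course$plans[[lbl]]
    write_volume(p$dose, file.path(dir, paste0("dose_", lbl, ".nii.gz")))
    plan_meta[[lbl]] <- list(label = p$label, frame_id = p$frame_id,
                             n_fractions = p$n_fractions,
                             include_in_addition = p$include_in_addition)
  }
  jsonlite::write_json(
    list(seed = course$seed, manifest = unclass(course$manifest),
         plans = plan_meta, frames = names(course$frames)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  frames <- list()
  for (fid in meta$frames) {
    fdir <- file.path(dir, fid)
    gt <- file.path(fdir, "gt_field.nii.gz")
    frames[[fid]] <- list(
      ct = read_volume(file.path(fdir, "ct.nii.gz")),
      structures = read_structures(fdir),
      gt_field = if (file.exists(gt)) read_field(gt) else NULL,
      frame_id = fid)
  }
  plans <- list()
  for (lbl in names(meta$plans)) {
    pm <- meta$plans[[lbl]]
    plans[[lbl]] <- fraction_plan(pm$label, pm$frame_id,
                                  read_volume(file.path(dir, paste0("dose_", lbl, ".nii.gz"))),
                                  pm$n_fractions, pm$include_in_addition)
  }
  manifest <- structure(as.list(meta$manifest), class = "course_manifest")
  structure(list(frames = frames, plans = plans, manifest = manifest,
                 spec = NULL, defspec = NULL, seed = meta$seed),
            class = "phantom_course")
}

#' Pipeline configuration
#'
#' @param dir_intensity,dir_hybrid [dir_config()]s for the two DIR settings.
#' @param alpha_beta Alpha/beta ratio (Gy) for EQD2.
#' @param bin_width DVH bin width (Gy).
#' @param metrics_cm3 Evaluated hottest volumes (cm^3).
#' @param organs Organs at risk reported.
#' @param eqd2_first EQD2 conversion before (default) or after warping.
#' @return A list of class `course_config`.
#' @export
course_config <- function(dir_intensity = dir_config("intensity"),
                          dir_hybrid = dir_config("hybrid"),
                          alpha_beta = 3, bin_width = 0.1,
                          metrics_cm3 = c(0.1, 1, 2),
                          organs = c("rectum", "bladder"),
                          eqd2_first = TRUE) {
  structure(list(dir_intensity = dir_intensity, dir_hybrid = dir_hybrid,
                 alpha_beta = alpha_beta, bin_width = bin_width,
                 metrics_cm3 = metrics_cm3, organs = organs,
                 eqd2_first = eqd2_first),
            class = "course_config")
}

align_structures <- function(structs, transform, target_grid) {
  g <- grid_of(target_grid)
  masks <- lapply(structs$masks, function(m) {
    v <- scalar_volume(array(as.numeric(m), dim = dim(m)), structs$spacing,
                       structs$origin)
    transform_volume(v, transform, target_grid = g, mode = "linear",
                     fill = 0)$values >= 0.5
  })
  structure_set(masks, spacing = g$spacing, origin = g$origin, check = FALSE)
}

#' Run the full dose-accumulation workflow on one case
#'
#' Reproduces the reference workflow end to end: rigid uterus fusion of every
#' frame to BT1, applicator HU replacement, deformable registration in both
#' parameter settings (intensity-based and hybrid), voxel-wise EQD2
#' conversion, dose warping and summation on the reference frame, hottest
#' subvolume metrics for both scopes (BT only; BT + EBRT), and the DVH
#' parameter addition baseline. Deterministic given the case and config.
#'
#' @param course A `phantom_course` (or a case directory path).
#' @param config A [course_config()].
#' @return An object of class `accumulation_report`; see [tidy()] /
#'   [glance()] / [autoplot()] methods.
#' @export
run_course <- function(course, config = course_config()) {
  if (is.character(course)) course <- read_case(course)
  stopifnot(inherits(course, "phantom_course"))
  ref <- course$frames[[course$manifest$reference_frame %||% "bt1"]]
  g <- grid_of(ref$ct)
  ref_ct_dir <- if (!is.null(ref$structures$masks$applicator)) {
    replace_applicator_hu(ref$ct, ref$structures$masks$applicator)
  } else ref$ct

  moving_ids <- setdiff(names(course$frames), ref$frame_id)
  fields <- list(rigid = list(), intensity = list(), hybrid = list())
  rigids <- list()
  traces <- list()
  for (fid in moving_ids) {
    fr <- course$frames[[fid]]
    rigid <- tryCatch(
      rigid_register(fr$structures, ref$structures, match_on = "uterus"),
      error = function(e) stop("stage rigid_register failed for frame `",
                               fid, "`: ", conditionMessage(e), call. = FALSE))
    rigids[[fid]] <- rigid
    ct_m <- if (!is.null(fr$structures$masks$applicator)) {
      replace_applicator_hu(fr$ct, fr$structures$masks$applicator)
    } else fr$ct
    aligned_ct <- transform_volume(ct_m, rigid, target_grid = g,
                                   mode = "linear", fill = -1000)
    aligned_structs <- align_structures(fr$structures, rigid, g)
    fields$rigid[[fid]] <- compose_rigid_field(rigid, NULL, grid = g)
    for (mode in c("intensity", "hybrid")) {
      cfg <- if (mode == "intensity") config$dir_intensity else config$dir_hybrid
      u <- tryCatch(
        deformable_register(aligned_ct, ref_ct_dir, aligned_structs,
                            ref$structures, cfg),
        error = function(e) stop("stage deformable_register(", mode,
                                 ") failed for frame `", fid, "`: ",
                                 conditionMessage(e), call. = FALSE))
      traces[[paste(fid, mode, sep = "_")]] <- attr(u, "trace")
      fields[[mode]][[fid]] <- compose_rigid_field(rigid, u)
    }
  }

  organs3 <- intersect(c("uterus", "rectum", "bladder"),
                       names(ref$structures$masks))
  dsc_rows <- list()
  for (fid in moving_ids) {
    for (s in organs3) {
      mv <- course$frames[[fid]]$structures$masks[[s]]
      fx <- ref$structures$masks[[s]]
      for (method in c("rigid", "intensity", "hybrid")) {
        w <- warp_mask(mv, fields[[method]][[fid]], mask_grid = g)
        dsc_rows[[length(dsc_rows) + 1]] <- tibble::tibble(
          frame = fid, structure = s, method = method,
          dsc = if (any(w)) dice(w, fx) else 0)
      }
    }
  }
  dsc <- dplyr::bind_rows(dsc_rows)

  is_bt <- vapply(course$plans, function(p) grepl("^bt", p$frame_id),
                  logical(1))
  scopes <- list(BT_only = course$plans[is_bt],
                 BT_plus_EBRT = course$plans)
  metric_rows <- list()
  for (scope in names(scopes)) {
    plans <- scopes[[scope]]
    for (method in c("intensity", "hybrid")) {
      acc <- accumulate_dose(plans, fields[[method]],
                             alpha_beta = config$alpha_beta,
                             reference_grid = g,
                             eqd2_first = config$eqd2_first)
      for (organ in config$organs) {
        for (vc in config$metrics_cm3) {
          metric_rows[[length(metric_rows) + 1]] <- tibble::tibble(
            scope = scope, organ = organ, metric_cm3 = vc,
            method = paste0(method, "_dir"),
            value_gy = d_cc(acc$dose, ref$structures$masks[[organ]], vc))
        }
      }
    }
    for (organ in config$organs) {
      organ_masks <- lapply(course$frames,
                            function(fr) fr$structures$masks[[organ]])
      for (vc in config$metrics_cm3) {
        metric_rows[[length(metric_rows) + 1]] <- tibble::tibble(
          scope = scope, organ = organ, metric_cm3 = vc, method = "addition",
          value_gy = dvh_parameter_addition(plans, organ_masks, vc,
                                            alpha_beta = config$alpha_beta))
      }
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  wide <- tidyr::pivot_wider(metrics, names_from = "method",
                             values_from = "value_gy")
  differences <- dplyr::bind_rows(
    dplyr::mutate(wide, comparison = "addition_minus_intensity",
                  difference_gy = .data$addition - .data$intensity_dir),
    dplyr::mutate(wide, comparison = "addition_minus_hybrid",
                  difference_gy = .data$addition - .data$hybrid_dir),
    dplyr::mutate(wide, comparison = "hybrid_minus_intensity",
                  difference_gy = .data$hybrid_dir - .data$intensity_dir))
  differences <- differences[, c("scope", "organ", "metric_cm3",
                                 "comparison", "difference_gy")]
  structure(
    list(metrics = metrics, differences = differences, dsc = dsc,
         rigid_transforms = rigids, fields = fields, traces = traces,
         seed = course$seed, alpha_beta = config$alpha_beta,
         scopes = names(scopes)),
    class = "accumulation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.accumulation_report <- function(x, ...) {
  cat(sprintf("<accumulation_report> seed %s, scopes: %s\n",
              x$seed %||% "?", paste(x$scopes, collapse = ", ")))
  w <- tidyr::pivot_wider(x$metrics, names_from = "method",
                          values_from = "value_gy")
  print(as.data.frame(w), digits = 4)
  cat("\nMean DSC by method:\n")
  s <- dplyr::summarise(dplyr::group_by(x$dsc, .data$method),
                        mean_dsc = mean(.data$dsc), .groups = "drop")
  print(as.data.frame(s), digits = 3)
  invisible(x)
}

#' Tidy an accumulation report
#'
#' @param x An `accumulation_report`.
#' @param ... Unused.
#' @return Tibble with one row per (scope, organ, metric, method):
#'   columns `scope`, `organ`, `metric_cm3`, `method`, `value_gy`.
#' @export
tidy.accumulation_report <- function(x, ...) x$metrics

#' @rdname tidy.accumulation_report
#' @export
glance.accumulation_report <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x$dsc, .data$method),
                        dsc = mean(.data$dsc), .groups = "drop")
  tibble::tibble(
    n_frames = length(unique(x$dsc$frame)) + 1L,
    n_metrics = nrow(x$metrics),
    mean_dsc_rigid = s$dsc[s$method == "rigid"],
    mean_dsc_intensity = s$dsc[s$method == "intensity"],
    mean_dsc_hybrid = s$dsc[s$method == "hybrid"],
    alpha_beta = x$alpha_beta)
}

#' @rdname tidy.accumulation_report
#' @param object An `accumulation_report` (autoplot).
#' @export
autoplot.accumulation_report <- function(object, ...) {
  df <- dplyr::mutate(object$metrics,
                      metric = paste0("D ", .data$metric_cm3, " cm3"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value_gy,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(organ ~ scope) +
    ggplot2::labs(x = NULL, y = "Dose (Gy EQD2)", fill = "Method") +
    ggplot2::theme_minimal()
}

#' Cohort summary across case reports
#'
#' Mean, SD and 95% CI per (scope, organ, metric, quantity) over a list of
#' reports, where quantity is each accumulation method and each pairwise
#' difference. No hypothesis testing.
#'
#' @param reports List of `accumulation_report`s with identical scope sets.
#' @return A tibble with columns `scope`, `organ`, `metric_cm3`, `type`
#'   (`"method"` or `"difference"`), `quantity`, `mean_gy`, `sd_gy`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
cohort_summary <- function(reports) {
  if (length(reports) < 1) stop("need at least one report", call. = FALSE)
  scope_sets <- unique(lapply(reports, function(r) sort(r$scopes)))
  if (length(scope_sets) != 1) {
    stop("reports have mixed scopes; summarize homogeneous cohorts only",
         call. = FALSE)
  }
  m <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(reports[[i]]$metrics, case = i, type = "method",
                  quantity = .data$method)
  }))
  d <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(reports[[i]]$differences, case = i, type = "difference",
                  quantity = .data$comparison,
                  value_gy = .data$difference_gy)
  }))
  all <- dplyr::bind_rows(
    m[, c("scope", "organ", "metric_cm3", "type", "quantity", "case", "value_gy")],
    d[, c("scope", "organ", "metric_cm3", "type", "quantity", "case", "value_gy")])
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$scope, .data$organ, .data$metric_cm3,
                    .data$type, .data$quantity),
    mean_gy = mean(.data$value_gy),
    sd_gy = if (dplyr::n() > 1) stats::sd(.data$value_gy) else 0,
    n = dplyr::n(), .groups = "drop")
  half <- ifelse(out$n > 1, 1.96 * out$sd_gy / sqrt(out$n), 0)
  out$ci_lo <- out$mean_gy - half
  out$ci_hi <- out$mean_gy + half
  out
}

#' Export a report (or cohort summary) as CSV tables
#'
#' Writes `metrics.csv` (one row per scope/organ/metric/method),
#' `differences.csv` (pairwise method differences) and `dsc.csv`
#' (per-frame per-structure registration accuracy) into a directory.
#'
#' @param report An `accumulation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "accumulation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$differences, file.path(dir, "differences.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dsc, file.path(dir, "dsc.csv"), row.names = FALSE)
  invisible(dir)
}
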