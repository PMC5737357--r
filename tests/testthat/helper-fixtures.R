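# shared fixtures: coarse (5 mm) phantom with the same world-space anatomy and
# deformation amplitudes as the default case, plus tiny hand-built volumes

test_spec <- function(seed = 1L, noise_sd = 12) {
  phantom_spec(dim = c(48L, 48L, 32L), spacing = c(5, 5, 5),
               seed = seed, noise_sd = noise_sd)
}

make_vol <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  scalar_volume(values, spacing, origin)
}

const_vol <- function(value, dim = c(4, 4, 4), spacing = c(1, 1, 1)) {
  scalar_volume(array(value, dim), spacing)
}

# uniform-voxel plan on a trivial grid
make_plan <- function(label, values, n_fractions, frame_id = "f1",
                      spacing = c(1, 1, 1), ...) {
  fraction_plan(label, frame_id, make_vol(values, spacing), n_fractions, ...)
}

# caches for expensive case objects reused across test files
.fixture_env <- new.env(parent = emptyenv())

cached_case <- function(seed = 1L, noise_sd = 12) {
  key <- paste0("case_", seed, "_", noise_sd)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_reference_case(test_spec(seed, noise_sd))
  }
  .fixture_env[[key]]
}

# full registration sweep over seeds x frames x methods on the coarse phantom;
# computed once and shared by the registration-quality acceptance tests
registration_sweep <- function(seeds = 1:5) {
  key <- paste0("sweep_", paste(seeds, collapse = "_"))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  organs <- c("uterus", "rectum", "bladder")
  rows <- list(); tre_rows <- list()
  fields_seed1 <- list(rigid = list(), intensity = list(), hybrid = list())
  for (seed in seeds) {
    case <- generate_reference_case(test_spec(seed))
    defs <- deformation_spec()
    g <- grid_of(case$ct)
    ref_ct <- replace_applicator_hu(case$ct, case$structures$masks$applicator)
    frames <- list(
      bt2 = generate_deformed_frame(case, defs, "BT_fraction", "bt2"),
      bt3 = generate_deformed_frame(case, defs, "BT_fraction", "bt3"),
      bt4 = generate_deformed_frame(case, defs, "BT_fraction", "bt4"),
      ebrt = generate_deformed_frame(case, defs, "EBRT", "ebrt"))
    for (fid in names(frames)) {
      fr <- frames[[fid]]
      rig <- rigid_register(fr$structures, case$structures, "uterus")
      ct_m <- if (!is.null(fr$structures$masks$applicator)) {
        replace_applicator_hu(fr$ct, fr$structures$masks$applicator)
      } else fr$ct
      aligned_ct <- transform_volume(ct_m, rig, target_grid = g,
                                     mode = "linear", fill = -1000)
      al <- dirdose:::align_structures(fr$structures, rig, g)
      fields <- list(rigid = compose_rigid_field(rig, NULL, grid = g))
      for (mode in c("intensity", "hybrid")) {
        u <- deformable_register(aligned_ct, ref_ct, al, case$structures,
                                 dir_config(mode))
        fields[[mode]] <- compose_rigid_field(rig, u)
      }
      if (seed == seeds[1]) {
        for (method in names(fields)) fields_seed1[[method]][[fid]] <- fields[[method]]
      }
      for (method in names(fields)) {
        for (s in organs) {
          w <- warp_mask(fr$structures$masks[[s]], fields[[method]],
                         mask_grid = g)
          rows[[length(rows) + 1]] <- data.frame(
            seed = seed, frame = fid, method = method, structure = s,
            dsc = if (any(w)) dice(w, case$structures$masks[[s]]) else 0)
        }
        tre_rows[[length(tre_rows) + 1]] <- data.frame(
          seed = seed, frame = fid, method = method,
          tre = registration_tre(fields[[method]], fr$gt_field,
                                 case$structures$masks[organs]))
      }
    }
  }
  out <- list(dsc = do.call(rbind, rows), tre = do.call(rbind, tre_rows),
              fields_seed1 = fields_seed1)
  .fixture_env[[key]] <- out
  out
}
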