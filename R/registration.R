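#' Deformable registration configuration
#'
#' Two parameter settings mirror the clinical workflow: `"intensity"` uses
#' image intensities only, restricted to the whole-body structure
#' (`w_struct` forced to 0); `"hybrid"` additionally drives the match with
#' the contoured uterus, rectum, bladder and body via a soft-Dice structure
#' term. The optimized energy is
#' `E(u) = w_img * S_img(u) + w_struct * S_struct(u) + w_reg * R(u)` with
#' `S_img` one minus the local normalized correlation of HU within the body
#' (implemented as the mean squared difference of locally standardized
#' intensities), `S_struct` the mean over structures of one minus the soft
#' Dice between warped moving and fixed masks, and `R` the discrete bending
#' energy of the field. Optimization is a monotone (backtracking) smoothed
#' gradient descent over a multi-resolution pyramid, fully deterministic.
#'
#' @param mode `"hybrid"` or `"intensity"`.
#' @param w_img Image similarity weight.
#' @param w_struct Structure term weight (ignored/0 in intensity mode).
#' @param w_reg Bending-energy regularization weight.
#' @param structures Structures used; defaults to body only (intensity) or
#'   uterus/rectum/bladder/body (hybrid).
#' @param pyramid Downsampling factors, coarsest last applied first
#'   (default 4x, 2x, 1x).
#' @param iterations Maximum iterations per pyramid level.
#' @param smooth_sigma Gaussian smoothing of the update force, in voxels.
#' @param mask_sigma Gaussian softening of structure masks, in voxels.
#' @param norm_sigma Window (voxels, full resolution) of the local intensity
#'   standardization.
#' @param norm_floor Floor on the local HU standard deviation.
#' @param step_size Relative step length (1 = at most `max_step_vox` voxels
#'   of displacement per iteration before backtracking).
#' @param max_step_vox Cap on the per-iteration displacement update (voxels).
#' @param tol Relative objective-decrease convergence tolerance per level.
#' @param max_backtracks Step halvings tried before stopping a level.
#' @return An object of class `dir_config`.
#' @export
dir_config <- function(mode = c("hybrid", "intensity"),
                       w_img = 1, w_struct = 1, w_reg = 0.1,
                       structures = NULL,
                       pyramid = c(4L, 2L, 1L),
                       iterations = c(100L, 100L, 50L),
                       smooth_sigma = 2, mask_sigma = 2,
                       norm_sigma = 8, norm_floor = 30,
                       step_size = 1, max_step_vox = 0.8,
                       tol = 1e-6, max_backtracks = 4L) {
  mode <- match.arg(mode)
  if (mode == "intensity") {
    w_struct <- 0
    if (is.null(structures)) structures <- "body"
  } else {
    if (is.null(structures)) {
      structures <- c("uterus", "rectum", "bladder", "body")
    }
  }
  if (any(c(w_img, w_struct, w_reg) < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (length(pyramid) != length(iterations)) {
    stop("`pyramid` and `iterations` must have equal length", call. = FALSE)
  }
  structure(
    list(mode = mode, w_img = w_img, w_struct = w_struct, w_reg = w_reg,
         structures = structures, pyramid = as.integer(pyramid),
         iterations = as.integer(iterations),
         smooth_sigma = smooth_sigma, mask_sigma = mask_sigma,
         norm_sigma = norm_sigma, norm_floor = norm_floor,
         step_size = step_size, max_step_vox = max_step_vox,
         tol = tol, max_backtracks = as.integer(max_backtracks)),
    class = "dir_config")
}

#' Replace applicator HU in a CT volume
#'
#' Sets every CT voxel inside the applicator mask to the given HU (default
#' -1000, i.e. air), the preprocessing that removes the metal-like applicator
#' signal before registering brachytherapy frames.
#'
#' @param ct A `scalar_volume` CT.
#' @param applicator Binary mask: 3D array on the CT grid, or a
#'   `scalar_volume` (grid-checked).
#' @param value Replacement HU (default -1000).
#' @return The modified `scalar_volume`.
#' @export
replace_applicator_hu <- function(ct, applicator, value = -1000) {
  stopifnot(inherits(ct, "scalar_volume"))
  if (inherits(applicator, "scalar_volume")) {
    stop_if_grid_mismatch(ct, applicator, "CT and applicator mask")
    m <- applicator$values >= 0.5
  } else {
    if (!identical(dim(applicator), dim(ct$values))) {
      stop("applicator mask grid does not match the CT grid", call. = FALSE)
    }
    m <- as.logical(applicator)
  }
  v <- ct$values
  v[m] <- value
  scalar_volume(v, ct$spacing, ct$origin)
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = |A intersect B| / ((|A| + |B|) / 2)`, volumes by voxel count.
#' 0 means no spatial overlap, 1 perfect agreement. Symmetric; two empty
#' masks are rejected rather than silently returning 0/0.
#'
#' @param deformed,reference 3D logical/0-1 arrays on the same grid (or
#'   `scalar_volume`s of 0/1).
#' @return DSC in `[0, 1]`.
#' @examples
#' a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- TRUE
#' b <- array(FALSE, c(6, 6, 6)); b[2:3, 2:3, 3:4] <- TRUE
#' dice(a, a)  # 1
#' dice(a, b)  # 0.5: 4 shared voxels out of (8 + 8) / 2
#' @export
dice <- function(deformed, reference) {
  a <- if (inherits(deformed, "scalar_volume")) deformed$values >= 0.5
       else as.logical(deformed)
  b <- if (inherits(reference, "scalar_volume")) reference$values >= 0.5
       else as.logical(reference)
  if (!identical(dim(a), dim(b))) {
    stop("masks must share the same grid", call. = FALSE)
  }
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) {
    stop("DSC undefined: both masks are empty", call. = FALSE)
  }
  sum(a & b) / ((na + nb) / 2)
}

# bounding box of a mask, expanded by margin_mm, as a grid spec on the same
# lattice (used to crop rigid-registration objective evaluations)
crop_grid_to_mask <- function(grid, mask, margin_mm) {
  g <- grid_of(grid)
  idx <- arrayInd(which(mask), g$dim)
  mar <- ceiling(margin_mm / g$spacing)
  lo <- pmax(apply(idx, 2, min) - mar, 1)
  hi <- pmin(apply(idx, 2, max) + mar, g$dim)
  list(dim = as.integer(hi - lo + 1), spacing = g$spacing,
       origin = g$origin + (lo - 1) * g$spacing)
}

soft_dice_vec <- function(a, b) {
  2 * sum(a * b) / (sum(a * a) + sum(b * b))
}

#' Automated rigid fusion by structure matching
#'
#' Finds the rigid transform (rotation about the fixed-grid center plus
#' translation) that maximizes the Dice overlap of the `match_on` structure,
#' over a bounded search (translation within `max_translation` mm, rotation
#' within `max_rotation` degrees). The search is initialized at the centroid
#' offset and refined by Nelder-Mead on a Gaussian-softened Dice objective;
#' the returned transform never has lower hard DSC than the identity.
#'
#' @param moving,fixed `structure_set`s containing `match_on`.
#' @param match_on Structure name to match (default `"uterus"`).
#' @param max_translation,max_rotation Search bounds (mm / degrees).
#' @return A `rigid_transform` (content motion applied to the moving frame),
#'   with the achieved DSC in attribute `"dsc"`.
#' @export
rigid_register <- function(moving, fixed, match_on = "uterus",
                           max_translation = 20, max_rotation = 15) {
  stopifnot(inherits(moving, "structure_set"), inherits(fixed, "structure_set"))
  for (s in list(moving, fixed)) {
    if (is.null(s$masks[[match_on]]) || !any(s$masks[[match_on]])) {
      stop("structure `", match_on, "` is missing or empty", call. = FALSE)
    }
  }
  gm <- grid_of(moving); gf <- grid_of(fixed)
  mv <- moving$masks[[match_on]]; fx <- fixed$masks[[match_on]]
  center <- gf$origin + (gf$dim - 1) * gf$spacing / 2

  cm <- colMeans(arrayInd(which(mv), gm$dim))
  cf <- colMeans(arrayInd(which(fx), gf$dim))
  t0 <- (gf$origin + (cf - 1) * gf$spacing) - (gm$origin + (cm - 1) * gm$spacing)
  t0 <- pmin(pmax(t0, -max_translation), max_translation)

  soft_m <- scalar_volume(cpp_gauss3(array(as.numeric(mv), gm$dim), gm$dim,
                                     c(2, 2, 2)), gm$spacing, gm$origin)
  soft_f_full <- cpp_gauss3(array(as.numeric(fx), gf$dim), gf$dim, c(2, 2, 2))
  sub <- crop_grid_to_mask(gf, fx, max_translation + 10)
  soft_f <- resample(scalar_volume(soft_f_full, gf$spacing, gf$origin), sub,
                     mode = "linear", fill = 0)$values
  sub_pts <- grid_world_coords(sub)

  objective <- function(par) {
    tr <- pmin(pmax(par[1:3], -max_translation), max_translation)
    ro <- pmin(pmax(par[4:6], -max_rotation), max_rotation)
    tf <- rigid_transform(ro, tr, center)
    pts <- transform_points(tf, sub_pts, inverse = TRUE)
    w <- cpp_interp3(as.numeric(soft_m$values), dim(soft_m$values),
                     world_to_index0(pts, soft_m), 0, FALSE)
    pen <- sum(pmax(abs(par[1:3]) - max_translation, 0)^2) +
      sum(pmax(abs(par[4:6]) - max_rotation, 0)^2)
    -soft_dice_vec(w, soft_f) + 0.01 * pen
  }
  fit <- stats::optim(c(t0, 0, 0, 0), objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-7))
  cand <- list(
    rigid_transform(c(0, 0, 0), c(0, 0, 0), center),
    rigid_transform(c(0, 0, 0), t0, center),
    rigid_transform(pmin(pmax(fit$par[4:6], -max_rotation), max_rotation),
                    pmin(pmax(fit$par[1:3], -max_translation), max_translation),
                    center)
  )
  mvol <- scalar_volume(array(as.numeric(mv), gm$dim), gm$spacing, gm$origin)
  scores <- vapply(cand, function(tf) {
    w <- transform_volume(mvol, tf, target_grid = gf, mode = "linear",
                          fill = 0)$values >= 0.5
    if (!any(w)) return(0)
    dice(w, fx)
  }, numeric(1))
  best <- cand[[which.max(scores)]]
  attr(best, "dsc") <- max(scores)
  best
}

# --- deformable registration internals -------------------------------------

downsample_volume <- function(vol, f) {
  if (f == 1) return(vol)
  g <- grid_of(vol)
  v <- cpp_gauss3(vol$values, g$dim, rep(f / 2, 3))
  ix <- seq(1, g$dim[1], by = f); iy <- seq(1, g$dim[2], by = f)
  iz <- seq(1, g$dim[3], by = f)
  scalar_volume(v[ix, iy, iz, drop = FALSE], g$spacing * f, g$origin)
}

local_standardize <- function(values, dim, sigma, floor) {
  mu <- cpp_gauss3(values, dim, rep(sigma, 3))
  m2 <- cpp_gauss3(values^2, dim, rep(sigma, 3))
  sd_loc <- sqrt(pmax(m2 - mu^2, floor^2))
  (values - mu) / sd_loc
}

central_gradient <- function(values, dim, spacing) {
  g <- vector("list", 3)
  for (a in 1:3) {
    lo <- values; hi <- values
    n <- dim[a]
    idx_hi <- c(2:n, n); idx_lo <- c(1, 1:(n - 1))
    if (a == 1) { hi <- values[idx_hi, , , drop = FALSE]
                  lo <- values[idx_lo, , , drop = FALSE] }
    if (a == 2) { hi <- values[, idx_hi, , drop = FALSE]
                  lo <- values[, idx_lo, , drop = FALSE] }
    if (a == 3) { hi <- values[, , idx_hi, drop = FALSE]
                  lo <- values[, , idx_lo, drop = FALSE] }
    g[[a]] <- (hi - lo) / (2 * spacing[a])
  }
  g
}

bending_energy <- function(u_mat, dim) {
  total <- cpp_bending_value(u_mat[, 1], dim) +
    cpp_bending_value(u_mat[, 2], dim) +
    cpp_bending_value(u_mat[, 3], dim)
  total / (3 * prod(dim))
}

bending_gradient <- function(u_mat, dim) {
  g <- matrix(0, nrow(u_mat), 3)
  for (k in 1:3) {
    g[, k] <- cpp_bending_grad(u_mat[, k], dim) / (3 * prod(dim))
  }
  g
}

#' Deformable image registration (intensity-based or hybrid)
#'
#' Estimates a dense displacement field (pull-back convention, defined on the
#' fixed grid) that maps the rigidly pre-aligned moving frame onto the fixed
#' frame by minimizing the energy described in [dir_config()]. The
#' optimization is deterministic: zero-field initialization, fixed pyramid
#' schedule, backtracking step control that only ever accepts
#' objective-decreasing updates (so the recorded objective trace is
#' non-increasing within each level).
#'
#' @param moving_ct,fixed_ct `scalar_volume` CTs on the same grid (moving
#'   already rigidly pre-aligned; applicator HU already replaced on BT
#'   frames).
#' @param moving_structs,fixed_structs `structure_set`s with the structures
#'   required by `config$structures`.
#' @param config A [dir_config()].
#' @return A `displacement_field` on the fixed grid, with the per-level
#'   objective traces in attribute `"trace"`.
#' @export
deformable_register <- function(moving_ct, fixed_ct, moving_structs,
                                fixed_structs, config = dir_config()) {
  stopifnot(inherits(config, "dir_config"))
  stop_if_grid_mismatch(moving_ct, fixed_ct, "moving and fixed CT")
  for (s in config$structures) {
    if (is.null(moving_structs$masks[[s]]) || is.null(fixed_structs$masks[[s]])) {
      stop(config$mode, "-mode DIR requires structure `", s,
           "` on both frames", call. = FALSE)
    }
  }
  g_full <- grid_of(fixed_ct)
  struct_names <- setdiff(config$structures, "body")
  if (config$w_struct == 0) struct_names <- character(0)

  u_field <- NULL
  traces <- list()
  for (li in seq_along(config$pyramid)) {
    f <- config$pyramid[li]
    n_iter <- config$iterations[li]
    Fct <- downsample_volume(fixed_ct, f)
    Mct <- downsample_volume(moving_ct, f)
    g <- grid_of(Fct)
    npx <- prod(g$dim)

    Fs <- local_standardize(Fct$values, g$dim, config$norm_sigma / f,
                            config$norm_floor)
    Ms <- local_standardize(Mct$values, g$dim, config$norm_sigma / f,
                            config$norm_floor)
    body_w <- downsample_volume(
      scalar_volume(array(as.numeric(fixed_structs$masks$body), g_full$dim),
                    g_full$spacing, g_full$origin), f)$values
    body_w <- pmin(pmax(body_w, 0), 1)
    sum_w <- sum(body_w)

    msoft_m <- list(); msoft_f <- list(); gradF_msk <- list(); sumF2 <- list()
    for (s in struct_names) {
      mm <- downsample_volume(
        scalar_volume(array(as.numeric(moving_structs$masks[[s]]), g_full$dim),
                      g_full$spacing, g_full$origin), f)$values
      ff <- downsample_volume(
        scalar_volume(array(as.numeric(fixed_structs$masks[[s]]), g_full$dim),
                      g_full$spacing, g_full$origin), f)$values
      msoft_m[[s]] <- cpp_gauss3(mm, g$dim, rep(config$mask_sigma, 3))
      msoft_f[[s]] <- cpp_gauss3(ff, g$dim, rep(config$mask_sigma, 3))
      gradF_msk[[s]] <- central_gradient(msoft_f[[s]], g$dim, g$spacing)
      sumF2[[s]] <- sum(msoft_f[[s]]^2)
    }
    gradF_img <- central_gradient(Fs, g$dim, g$spacing)
    Fs_vec <- as.numeric(Fs); bw_vec <- as.numeric(body_w)

    # carry the field up from the previous (coarser) level
    if (is.null(u_field)) {
      u <- matrix(0, npx, 3)
    } else {
      u <- matrix(0, npx, 3)
      pts <- grid_world_coords(g)
      u[] <- sample_field(u_field, pts)
    }

    channels <- c(list(as.numeric(Ms)), lapply(msoft_m, as.numeric))
    warp_channels <- function(u) {
      W <- cpp_warp_multi(channels, g$dim, u, g$spacing, 0)
      mw <- list()
      for (si in seq_along(struct_names)) {
        mw[[struct_names[si]]] <- W[, si + 1]
      }
      list(Mw = W[, 1], mw = mw)
    }
    energy <- function(u, ch) {
      r <- ch$Mw - Fs_vec
      e_img <- sum(bw_vec * 0.5 * r * r) / sum_w
      e_str <- 0
      if (length(struct_names) > 0) {
        for (s in struct_names) {
          e_str <- e_str + (1 - 2 * sum(ch$mw[[s]] * as.numeric(msoft_f[[s]])) /
                              (sum(ch$mw[[s]]^2) + sumF2[[s]]))
        }
        e_str <- e_str / length(struct_names)
      }
      e_reg <- bending_energy(u, g$dim)
      config$w_img * e_img + config$w_struct * e_str + config$w_reg * e_reg
    }

    ch <- warp_channels(u)
    E <- energy(u, ch)
    trace <- E
    if (!is.finite(E)) {
      stop("non-finite DIR objective at level ", li, ", iteration 0",
           call. = FALSE)
    }
    for (it in seq_len(n_iter)) {
      r <- (ch$Mw - Fs_vec) * bw_vec / sum_w
      G <- matrix(0, npx, 3)
      for (a in 1:3) {
        G[, a] <- config$w_img * r * as.numeric(gradF_img[[a]])
      }
      if (length(struct_names) > 0) {
        for (s in struct_names) {
          mw <- ch$mw[[s]]; fvec <- as.numeric(msoft_f[[s]])
          A <- sum(mw * fvec); B <- sum(mw * mw); C <- sumF2[[s]]
          denom <- (B + C)^2
          ddice <- (2 * fvec * (B + C) - 4 * A * mw) / denom
          coef <- -(config$w_struct / length(struct_names)) * ddice
          for (a in 1:3) {
            G[, a] <- G[, a] + coef * as.numeric(gradF_msk[[s]][[a]])
          }
        }
      }
      if (config$w_reg > 0) {
        G <- G + config$w_reg * bending_gradient(u, g$dim)
      }
      for (a in 1:3) {
        G[, a] <- as.numeric(cpp_gauss3(array(G[, a], g$dim), g$dim,
                                        rep(config$smooth_sigma, 3)))
      }
      gmax <- max(abs(G))
      if (gmax < 1e-15) break
      tau <- config$step_size * config$max_step_vox * min(g$spacing) / gmax
      accepted <- FALSE
      for (bt in 0:config$max_backtracks) {
        u_new <- u - tau * G
        ch_new <- warp_channels(u_new)
        E_new <- energy(u_new, ch_new)
        if (is.finite(E_new) && E_new < E - 1e-12) {
          accepted <- TRUE
          break
        }
        tau <- tau / 2
      }
      if (!accepted) break
      rel <- (E - E_new) / max(abs(E), 1e-12)
      u <- u_new; ch <- ch_new; E <- E_new
      trace <- c(trace, E)
      if (rel < config$tol) break
    }
    traces[[li]] <- trace
    u_field <- displacement_field(array(u, dim = c(g$dim, 3)), g$spacing,
                                  g$origin)
  }
  # ensure the returned field lives on the full fixed grid
  if (!same_grid(u_field, g_full)) {
    pts <- grid_world_coords(g_full)
    u <- sample_field(u_field, pts)
    u_field <- displacement_field(array(u, dim = c(g_full$dim, 3)),
                                  g_full$spacing, g_full$origin)
  }
  attr(u_field, "trace") <- traces
  attr(u_field, "config") <- config
  u_field
}

# surface voxels of a mask: in the mask but with at least one 6-neighbour out
mask_surface <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift <- function(m, a, s) {
    out <- array(FALSE, d)
    n <- d[a]
    if (a == 1) {
      if (s > 0) out[2:n, , ] <- m[1:(n - 1), , ] else out[1:(n - 1), , ] <- m[2:n, , ]
    } else if (a == 2) {
      if (s > 0) out[, 2:n, ] <- m[, 1:(n - 1), ] else out[, 1:(n - 1), ] <- m[, 2:n, ]
    } else {
      if (s > 0) out[, , 2:n] <- m[, , 1:(n - 1)] else out[, , 1:(n - 1)] <- m[, , 2:n]
    }
    out
  }
  for (a in 1:3) for (s in c(-1, 1)) interior <- interior & shift(mask, a, s)
  mask & !interior
}

#' Target registration error against a stored ground-truth field
#'
#' The phantom stores the exact pull-back field `h` used to generate each
#' frame (`moving(y) = reference(y + h(y))`). For an estimated total
#' registration field `T` (reference to moving, rigid and deformable steps
#' composed), the residual at reference point `x` is
#' `|T(x) + h(x + T(x))|`, which vanishes exactly when the registration
#' inverts the generative deformation. Reported as the mean over the surface
#' voxels of the supplied reference mask(s).
#'
#' @param total_field Estimated `displacement_field` (reference grid).
#' @param gt_field Ground-truth generative `displacement_field`.
#' @param masks A single mask array or a list of mask arrays on the reference
#'   grid; surface voxels of their union are evaluated.
#' @return Mean TRE in mm.
#' @export
registration_tre <- function(total_field, gt_field, masks) {
  if (!is.list(masks)) masks <- list(masks)
  surf <- Reduce(`|`, lapply(masks, mask_surface))
  g <- grid_of(total_field)
  idx <- which(surf)
  if (length(idx) == 0) stop("no surface voxels to evaluate", call. = FALSE)
  pts <- (arrayInd(idx, g$dim) - 1)
  pts <- sweep(sweep(pts, 2, g$spacing, `*`), 2, g$origin, `+`)
  Tm <- sample_field(total_field, pts)
  h <- sample_field(gt_field, pts + Tm)
  mean(sqrt(rowSums((Tm + h)^2)))
}
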