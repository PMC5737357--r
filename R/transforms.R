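#' Rigid transform (Euler angles + translation)
#'
#' Represents a rigid body motion applied to image *content* (push-forward):
#' a point `p` of the moving image moves to `R (p - center) + center + t`.
#' Rotation uses intrinsic Euler angles in degrees about the x, y and z axes
#' (applied in that order, `R = Rz Ry Rx`) about `center`, followed by the
#' translation `t` in mm.
#'
#' @param rotation Numeric length 3, Euler angles in degrees (x, y, z).
#' @param translation Numeric length 3, mm.
#' @param center Numeric length 3, rotation center in world mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3, all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.2f, %.2f, %.2f) deg, t (%.2f, %.2f, %.2f) mm\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#'
#' @param transform A `rigid_transform`.
#' @param pts n x 3 matrix of world points (mm).
#' @param inverse Map points through the inverse motion instead.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, pts, inverse = FALSE) {
  R <- rotation_matrix(transform$rotation)
  c0 <- transform$center; t0 <- transform$translation
  pts <- as.matrix(pts)
  if (!inverse) {
    sweep(sweep(pts, 2, c0, `-`) %*% t(R), 2, c0 + t0, `+`)
  } else {
    sweep(sweep(pts, 2, c0 + t0, `-`) %*% R, 2, c0, `+`)
  }
}

#' Apply a rigid transform to a volume
#'
#' Resamples the moving volume onto `target_grid` after moving its content by
#' `transform` (pull-back implementation: target voxel `x` samples the moving
#' volume at the inverse-mapped point).
#'
#' @param volume A `scalar_volume` (the moving image).
#' @param transform A `rigid_transform` (content motion).
#' @param target_grid Output grid (defaults to the volume's own grid).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill Out-of-support fill value.
#' @return A `scalar_volume` on `target_grid`.
#' @export
transform_volume <- function(volume, transform, target_grid = volume,
                             mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  tg <- grid_of(target_grid)
  pts <- transform_points(transform, grid_world_coords(tg), inverse = TRUE)
  vals <- cpp_interp3(as.numeric(volume$values), dim(volume$values),
                      world_to_index0(pts, volume), fill, mode == "nearest")
  scalar_volume(array(vals, dim = tg$dim), tg$spacing, tg$origin)
}

#' Dense displacement field on a reference grid
#'
#' Pull-back convention: for a reference voxel at world point `p`, the moving
#' image is sampled at `p + offset(p)` (offsets in mm). The zero field is the
#' identity mapping.
#'
#' @param offsets 4D array `dim x 3` of per-voxel offsets in mm.
#' @param spacing,origin Grid geometry of the reference grid.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(offsets, spacing, origin = c(0, 0, 0)) {
  if (!is.array(offsets) || length(dim(offsets)) != 4L || dim(offsets)[4] != 3L) {
    stop("`offsets` must be a 4D array with 3 components on the last axis",
         call. = FALSE)
  }
  if (any(!is.finite(offsets))) {
    stop("displacement offsets must be finite everywhere", call. = FALSE)
  }
  structure(list(offsets = offsets, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$offsets)
  mag <- sqrt(x$offsets[, , , 1]^2 + x$offsets[, , , 2]^2 + x$offsets[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| mean %.2f / max %.2f mm\n",
              d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

#' The identity (zero) displacement field on a grid
#' @param grid Grid spec or volume-like object.
#' @return A `displacement_field` of zeros.
#' @export
zero_field <- function(grid) {
  g <- grid_of(grid)
  displacement_field(array(0, dim = c(g$dim, 3)), g$spacing, g$origin)
}

# n x 3 matrix of offsets in column-major voxel order
field_matrix <- function(field) {
  d <- dim(field$offsets)
  matrix(field$offsets, ncol = 3)
}

# sample field offsets (trilinear, componentwise) at world points; outside the
# field support the offset extends from the border
sample_field <- function(field, pts_world) {
  idx <- world_to_index0(pts_world, field)
  d <- dim(field$offsets)[1:3]
  out <- matrix(0, nrow(pts_world), 3)
  for (k in 1:3) {
    out[, k] <- cpp_interp3(as.numeric(field$offsets[, , , k]), d, idx,
                            0, FALSE)
  }
  out
}

#' Warp a volume through a displacement field
#'
#' Pull-back warping: output voxel at world `p` takes the value of `volume`
#' sampled at `p + offset(p)`. The output lives on the field's grid.
#'
#' @param volume A `scalar_volume` (moving image, any overlapping grid).
#' @param field A `displacement_field` on the reference grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill Out-of-support fill value.
#' @return A `scalar_volume` on the field's grid.
#' @export
warp_volume <- function(volume, field, mode = c("linear", "nearest"),
                        fill = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(field, "displacement_field"))
  g <- grid_of(field)
  pts <- grid_world_coords(g) + field_matrix(field)
  vals <- cpp_interp3(as.numeric(volume$values), dim(volume$values),
                      world_to_index0(pts, volume), fill, mode == "nearest")
  scalar_volume(array(vals, dim = g$dim), g$spacing, g$origin)
}

#' Warp a binary mask through a displacement field
#'
#' The 0/1 mask is interpolated trilinearly and re-binarized at 0.5, so an
#' identity field returns the input mask exactly and the output is always
#' binary.
#'
#' @param mask 3D logical/0-1 array, or a `scalar_volume` of 0/1 values.
#' @param field A `displacement_field`; the mask must live on a grid
#'   compatible with the field (same grid when given as a bare array).
#' @param mask_grid Grid of `mask` when `mask` is a bare array; defaults to
#'   the field's grid.
#' @return A logical 3D array on the field's grid.
#' @export
warp_mask <- function(mask, field, mask_grid = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  if (inherits(mask, "scalar_volume")) {
    vol <- scalar_volume(array(as.numeric(mask$values >= 0.5), dim(mask$values)),
                         mask$spacing, mask$origin)
  } else {
    g <- if (is.null(mask_grid)) grid_of(field) else grid_of(mask_grid)
    if (!identical(dim(mask), as.integer(g$dim)) &&
        !identical(dim(mask), g$dim)) {
      stop("mask dimensions do not match its grid", call. = FALSE)
    }
    vol <- scalar_volume(array(as.numeric(mask), dim = dim(mask)),
                         g$spacing, g$origin)
  }
  w <- warp_volume(vol, field, mode = "linear", fill = 0)
  w$values >= 0.5
}

#' Compose a rigid pre-alignment with a deformable field
#'
#' Registration runs deformable matching on the rigidly pre-aligned moving
#' frame; to map the *original* moving frame onto the reference grid the two
#' must be composed. The composed pull-back is
#' `x -> inverse_rigid(x + u(x))`, returned as a single displacement field on
#' the reference grid. With `field = NULL` the result encodes the rigid step
#' alone.
#'
#' @param transform A `rigid_transform` (as applied to the moving content).
#' @param field A `displacement_field` from deformable registration of the
#'   pre-aligned frame, or `NULL`.
#' @param grid Reference grid (required when `field` is `NULL`).
#' @return A `displacement_field` mapping reference points into the original
#'   moving frame.
#' @export
compose_rigid_field <- function(transform, field = NULL, grid = NULL) {
  if (is.null(field) && is.null(grid)) {
    stop("need `grid` when no deformable field is given", call. = FALSE)
  }
  g <- grid_of(if (is.null(field)) grid else field)
  x <- grid_world_coords(g)
  y <- if (is.null(field)) x else x + field_matrix(field)
  z <- transform_points(transform, y, inverse = TRUE)
  displacement_field(array(z - x, dim = c(g$dim, 3)), g$spacing, g$origin)
}

#' Read/write a displacement field as a 3-component NIfTI
#'
#' Stored as a 4D volume whose fourth axis holds the x/y/z offset components
#' in mm.
#'
#' @param field A `displacement_field`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path` (write) / a `displacement_field` (read).
#' @export
write_field <- function(field, path) {
  sp <- field$spacing; or <- field$origin
  xf <- rbind(c(-sp[1], 0, 0, -or[1]),
              c(0, -sp[2], 0, -or[2]),
              c(0, 0, sp[3], or[3]),
              c(0, 0, 0, 1))
  img <- RNifti::asNifti(field$offsets,
                         list(pixdim = c(-1, sp, 1, 0, 0, 0)),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) {
    stop("expected a 4D field with 3 components, got dims ",
         paste(d, collapse = "x"), call. = FALSE)
  }
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4]); origin[1:2] <- -origin[1:2]
  spacing <- RNifti::pixdim(img)[1:3]
  displacement_field(array(as.numeric(img), dim = d), spacing, origin)
}

#' Discrete Jacobian determinant of the map `x + u(x)`
#'
#' Central-difference Jacobian of the deformation on interior voxels; a
#' positive determinant everywhere indicates local invertibility.
#'
#' @param field A `displacement_field`.
#' @return 3D array of determinants (border voxels `NA`).
#' @export
jacobian_determinant <- function(field) {
  u <- field$offsets
  d <- dim(u)[1:3]
  sp <- field$spacing
  J <- array(NA_real_, d)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  g <- vector("list", 9)
  n <- 1
  for (comp in 1:3) {
    uk <- u[, , , comp]
    g[[n]]     <- (uk[ix + 1, iy, iz] - uk[ix - 1, iy, iz]) / (2 * sp[1])
    g[[n + 1]] <- (uk[ix, iy + 1, iz] - uk[ix, iy - 1, iz]) / (2 * sp[2])
    g[[n + 2]] <- (uk[ix, iy, iz + 1] - uk[ix, iy, iz - 1]) / (2 * sp[3])
    n <- n + 3
  }
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  J[ix, iy, iz] <- det
  J
}

#' Invert a displacement field by fixed-point iteration
#'
#' Given a field `h` encoding the map `y -> y + h(y)`, returns the field `T`
#' with `T(x) = -h(x + T(x))`, i.e. the displacement of the inverse map.
#' Useful to turn a generative (moving-to-reference) field into the
#' reference-to-moving field needed for pull-back warping. Converges for
#' smooth fields with displacement gradients below 1.
#'
#' @param field A `displacement_field`.
#' @param iterations Fixed-point iterations (default 20).
#' @return A `displacement_field` on the same grid.
#' @export
invert_field <- function(field, iterations = 20L) {
  g <- grid_of(field)
  x <- grid_world_coords(g)
  Tm <- matrix(0, nrow(x), 3)
  for (i in seq_len(iterations)) {
    Tm <- -sample_field(field, x + Tm)
  }
  displacement_field(array(Tm, dim = c(g$dim, 3)), g$spacing, g$origin)
}
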