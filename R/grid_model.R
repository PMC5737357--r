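#' Scalar volumes on a regular axis-aligned grid
#'
#' A `scalar_volume` holds a 3D array of scalars (HU for CT, Gy for dose)
#' together with the grid geometry: per-axis voxel spacing in mm and the world
#' position (mm) of the *center* of voxel `[1, 1, 1]`. World coordinates follow
#' `world = origin + (index - 1) * spacing` per axis, with axes ordered
#' x = right to left, y = anterior to posterior, z = inferior to superior.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length 3, voxel size in mm; strictly positive.
#' @param origin Numeric length 3, world coordinates (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array, got dimensionality ",
         length(dim(values)), call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite numbers", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<scalar_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

#' Grid geometry of a volume-like object
#'
#' @param x A `scalar_volume`, `structure_set`, `displacement_field`, or a
#'   grid spec list with `dim`, `spacing`, `origin`.
#' @return A list with elements `dim`, `spacing`, `origin`.
#' @export
grid_of <- function(x) {
  if (inherits(x, "scalar_volume")) {
    list(dim = dim(x$values), spacing = x$spacing, origin = x$origin)
  } else if (inherits(x, "structure_set")) {
    list(dim = x$dim, spacing = x$spacing, origin = x$origin)
  } else if (inherits(x, "displacement_field")) {
    list(dim = dim(x$offsets)[1:3], spacing = x$spacing, origin = x$origin)
  } else if (is.list(x) && all(c("dim", "spacing", "origin") %in% names(x))) {
    list(dim = as.integer(x$dim), spacing = as.numeric(x$spacing),
         origin = as.numeric(x$origin))
  } else {
    stop("cannot extract a grid from an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

#' Test whether two objects share a grid
#' @param a,b Volume-like objects accepted by [grid_of()].
#' @param tol Metadata tolerance in mm.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(what, " must share the same grid (dim/spacing/origin)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Voxel volume in cubic centimetres
#' @param x A volume-like object accepted by [grid_of()].
#' @return Voxel volume in cm^3 (`prod(spacing) / 1000`).
#' @export
voxel_volume_cm3 <- function(x) {
  g <- grid_of(x)
  prod(g$spacing) / 1000
}

# world coordinates (n x 3 matrix, mm) of every voxel center, column-major order
grid_world_coords <- function(grid) {
  g <- grid_of(grid)
  idx <- arrayInd(seq_len(prod(g$dim)), g$dim)
  sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

# world (mm) -> fractional 0-based voxel index coordinates of `grid`
world_to_index0 <- function(pts, grid) {
  g <- grid_of(grid)
  sweep(sweep(pts, 2, g$origin, `-`), 2, g$spacing, `/`)
}

#' Named binary structure masks on a shared grid
#'
#' Stores organ/structure masks (`uterus`, `rectum`, `bladder`, `body`,
#' `hrctv`, `applicator`, ...) as logical arrays on one grid. On construction
#' the anatomical invariants are checked: uterus, rectum and bladder must be
#' pairwise disjoint and each a subset of the body.
#'
#' @param masks Named list of 3D logical (or 0/1) arrays with identical dims.
#' @param spacing,origin Grid geometry as for [scalar_volume()].
#' @param check Validate anatomical invariants (default `TRUE`).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0), check = TRUE) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    stop("`masks` must be a named list of arrays", call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    if (!is.array(m) || length(dim(m)) != 3L) {
      stop("each mask must be a 3D array", call. = FALSE)
    }
    array(as.logical(m), dim = dim(m))
  })
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("all masks must share one grid", call. = FALSE)
  x <- structure(
    list(masks = masks, dim = dims[[1]], spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "structure_set"
  )
  if (check) validate_structure_set(x)
  x
}

validate_structure_set <- function(x) {
  organs <- intersect(c("uterus", "rectum", "bladder"), names(x$masks))
  if (length(organs) > 1) {
    for (i in seq_len(length(organs) - 1)) {
      for (j in seq(i + 1, length(organs))) {
        if (any(x$masks[[organs[i]]] & x$masks[[organs[j]]])) {
          stop("structures `", organs[i], "` and `", organs[j],
               "` overlap; they must be disjoint", call. = FALSE)
        }
      }
    }
  }
  if ("body" %in% names(x$masks)) {
    for (o in organs) {
      if (any(x$masks[[o]] & !x$masks$body)) {
        stop("structure `", o, "` extends outside the body", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %d x %d x %d grid\n",
              length(x$masks), x$dim[1], x$dim[2], x$dim[3]))
  vv <- voxel_volume_cm3(x)
  for (nm in names(x$masks)) {
    cat(sprintf("  %-11s %8.1f cm3\n", nm, sum(x$masks[[nm]]) * vv))
  }
  invisible(x)
}

#' Structure volume in cm^3
#' @param structs A `structure_set`.
#' @param name Structure name.
#' @return Volume by voxel count times voxel volume.
#' @export
structure_volume_cm3 <- function(structs, name) {
  if (!name %in% names(structs$masks)) {
    stop("no structure named `", name, "`", call. = FALSE)
  }
  sum(structs$masks[[name]]) * voxel_volume_cm3(structs)
}

#' Read a 3D NIfTI volume
#'
#' Reads a single-channel 3D NIfTI file into a [scalar_volume()], taking the
#' voxel spacing from `pixdim` and the origin from the stored xform
#' translation. Files that are not 3D are rejected.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D volume, got dimensionality ", length(d),
         " in ", path, call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)
  if (any(spacing <= 0)) {
    stop("non-positive spacing in ", path, call. = FALSE)
  }
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  # our writer stores the LPS-flavoured origin negated into the RAS xform
  origin[1:2] <- -origin[1:2]
  scalar_volume(array(as.numeric(img), dim = d), spacing = spacing,
                origin = origin)
}

#' Write a 3D volume to NIfTI
#'
#' Values are stored as 64-bit floats so read/write round-trips are bit exact;
#' spacing and origin are carried in `pixdim` and the sform.
#'
#' @param volume A `scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  sp <- volume$spacing
  or <- volume$origin
  # diagonal sform: RAS x/y are negated relative to our x/y axes
  xf <- rbind(c(-sp[1], 0, 0, -or[1]),
              c(0, -sp[2], 0, -or[2]),
              c(0, 0, sp[3], or[3]),
              c(0, 0, 0, 1))
  img <- RNifti::asNifti(volume$values,
                         list(pixdim = c(-1, sp, 0, 0, 0, 0)),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write and read a structure set as per-structure NIfTI masks
#'
#' Masks are stored as 0/1 volumes named `mask_<structure>.nii.gz` plus a JSON
#' sidecar `structures.json` mapping structure names to files.
#'
#' @param structs A `structure_set`.
#' @param dir Directory to write into (created if missing).
#' @return `dir` (write) or a `structure_set` (read), invisibly for write.
#' @export
write_structures <- function(structs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (nm in names(structs$masks)) {
    f <- paste0("mask_", nm, ".nii.gz")
    vol <- scalar_volume(array(as.numeric(structs$masks[[nm]]),
                               dim = structs$dim),
                         spacing = structs$spacing, origin = structs$origin)
    write_volume(vol, file.path(dir, f))
    files[[nm]] <- f
  }
  jsonlite::write_json(files, file.path(dir, "structures.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_structures
#' @export
read_structures <- function(dir) {
  sidecar <- file.path(dir, "structures.json")
  if (!file.exists(sidecar)) stop("no structures.json in ", dir, call. = FALSE)
  files <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  masks <- list(); spacing <- NULL; origin <- NULL
  for (nm in names(files)) {
    v <- read_volume(file.path(dir, files[[nm]]))
    masks[[nm]] <- v$values >= 0.5
    spacing <- v$spacing; origin <- v$origin
  }
  structure_set(masks, spacing = spacing, origin = origin, check = FALSE)
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: each target voxel center is mapped to world
#' coordinates and the source volume is sampled there. `mode = "linear"`
#' (trilinear) for images and doses; `mode = "nearest"` must be used for
#' masks. Voxels outside the source support receive `fill` (use -1000 for CT,
#' 0 for dose).
#'
#' @param volume A `scalar_volume`.
#' @param target_grid Grid spec or volume-like object defining the output grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill Value for out-of-support voxels.
#' @return A `scalar_volume` on the target grid.
#' @export
resample <- function(volume, target_grid, mode = c("linear", "nearest"),
                     fill = 0) {
  stopifnot(inherits(volume, "scalar_volume"))
  mode <- match.arg(mode)
  tg <- grid_of(target_grid)
  sg <- grid_of(volume)
  # reject disjoint grids: bounding boxes (voxel centers) must overlap
  lo_s <- sg$origin; hi_s <- sg$origin + (sg$dim - 1) * sg$spacing
  lo_t <- tg$origin; hi_t <- tg$origin + (tg$dim - 1) * tg$spacing
  if (any(hi_t < lo_s) || any(lo_t > hi_s)) {
    stop("target grid does not overlap the source grid", call. = FALSE)
  }
  if (same_grid(volume, tg)) {
    return(scalar_volume(volume$values, sg$spacing, sg$origin))
  }
  pts <- world_to_index0(grid_world_coords(tg), volume)
  vals <- cpp_interp3(as.numeric(volume$values), dim(volume$values), pts,
                      fill, mode == "nearest")
  scalar_volume(array(vals, dim = tg$dim), tg$spacing, tg$origin)
}
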