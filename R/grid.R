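#' Regular 3D grid specification
#'
#' Defines the voxel lattice shared by density grids, structure masks, dose
#' grids and deformation fields. World coordinates are in cm with a
#' voxel-center convention: the center of voxel `(i, j, k)` (0-based) is at
#' `origin + c(i, j, k) * spacing`. Axes are x = left-right, y =
#' anterior-posterior, z = cranial-caudal.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing voxel size in cm, scalar or length 3. Default 0.25 cm,
#'   the dose-grid resolution used throughout.
#' @param origin world coordinate (cm) of the center of voxel (0,0,0).
#'   Default centers the grid on the world origin.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(shape, spacing = 0.25, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing %s cm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

voxel_volume_cc <- function(grid) prod(grid$spacing)

#' World coordinates of the grid axes
#' @param grid a [grid_spec()].
#' @return list of numeric vectors `x`, `y`, `z` (cm, voxel centers).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

# Full per-voxel coordinate arrays; heavy (3 arrays of prod(shape)) so only
# built where geometry is evaluated.
grid_coord_arrays <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$shape
  list(x = array(rep(ax$x, times = n[2] * n[3]), dim = n),
       y = array(rep(rep(ax$y, each = n[1]), times = n[3]), dim = n),
       z = array(rep(ax$z, each = n[1] * n[2]), dim = n))
}

# Array of the affine w . v + c over all voxel centers v, computed separably.
grid_affine_array <- function(grid, w, const = 0) {
  ax <- grid_axes(grid)
  n <- grid$shape
  a <- w[1] * ax$x
  b <- w[2] * ax$y
  d <- w[3] * ax$z + const
  array(rep(a, times = n[2] * n[3]) +
          rep(rep(b, each = n[1]), times = n[3]) +
          rep(d, each = n[1] * n[2]), dim = n)
}

same_lattice <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_lattice_mismatch <- function(a, b) {
  if (!same_lattice(a, b)) stop("objects are not on the same lattice", call. = FALSE)
  invisible(TRUE)
}

#' Binary structure mask on a grid
#'
#' @param name structure label (e.g. `"GTV"`, `"ESO"`, `"HRT"`, `"LNG"`,
#'   `"SC"`, `"GRT"`, `"TRA"`, `"BODY"`).
#' @param voxels logical 3D array with `dim == grid$shape`.
#' @param grid the [grid_spec()] the mask lives on.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(name, voxels, grid) {
  stopifnot(is.character(name), length(name) == 1L)
  voxels <- as.logical(voxels)
  dim(voxels) <- NULL
  if (length(voxels) != prod(grid$shape))
    stop("mask size does not match grid shape", call. = FALSE)
  dim(voxels) <- grid$shape
  structure(list(name = name, voxels = voxels, grid = grid),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels, %.2f cc\n",
              x$name, sum(x$voxels), mask_volume_cc(x)))
  invisible(x)
}

#' Mask volume in cc
#' @param mask a [structure_mask()].
#' @export
mask_volume_cc <- function(mask) sum(mask$voxels) * voxel_volume_cc(mask$grid)

#' Mask centroid in world coordinates (cm)
#' @param mask a [structure_mask()].
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  mask$grid$origin + (colMeans(idx) - 1) * mask$grid$spacing
}

#' Euclidean distance map of a mask
#'
#' Distance (cm) from every voxel center to the nearest voxel center inside
#' the mask (0 inside the mask). All-FALSE masks return `Inf` everywhere.
#'
#' @param mask a [structure_mask()] or logical array.
#' @param grid required when `mask` is a bare array.
#' @return numeric 3D array of distances in cm.
#' @export
distance_map <- function(mask, grid = NULL) {
  if (inherits(mask, "structure_mask")) {
    grid <- mask$grid
    vox <- mask$voxels
  } else {
    stopifnot(!is.null(grid))
    vox <- mask
  }
  d <- cpp_edt3(as.logical(vox), grid$shape, grid$spacing)
  d[d > 1e14] <- Inf
  d
}

#' Scalar dose grid (Gy)
#'
#' @param values numeric 3D array of dose in Gy, `dim == grid$shape`.
#' @param grid the [grid_spec()].
#' @param meta provenance list (strategy, phase, normalization factor, ...).
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(values, grid, meta = list()) {
  values <- as.numeric(values)
  if (length(values) != prod(grid$shape))
    stop("dose size does not match grid shape", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative", call. = FALSE)
  dim(values) <- grid$shape
  structure(list(values = values, grid = grid, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %s voxels, max %.2f Gy, mean %.3f Gy\n",
              paste(x$grid$shape, collapse = "x"),
              max(x$values), mean(x$values)))
  invisible(x)
}

#' Displacement field between a breathing phase and the reference phase
#'
#' Pull-back convention: `vectors[i,j,k,]` is the displacement (cm) that maps
#' the reference-phase (phase 0%) world coordinate of voxel `(i,j,k)` to the
#' corresponding point in the source phase. Resampling a source-phase
#' quantity at `x + u(x)` brings it onto the reference anatomy.
#'
#' @param vectors numeric 4D array, `dim = c(grid$shape, 3)` (cm).
#' @param grid the [grid_spec()].
#' @param source_phase 0-based phase index in 0..7.
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(vectors, grid, source_phase) {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  if (!all(dim(vectors)[1:3] == grid$shape))
    stop("field size does not match grid shape", call. = FALSE)
  structure(list(vectors = vectors, grid = grid,
                 source_phase = as.integer(source_phase)),
            class = "deformation_field")
}

#' All-zero deformation field (identity mapping)
#' @param grid the [grid_spec()].
#' @param source_phase 0-based phase index (default 0, the reference phase).
#' @export
zero_field <- function(grid, source_phase = 0L) {
  deformation_field(array(0, dim = c(grid$shape, 3L)), grid, source_phase)
}
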