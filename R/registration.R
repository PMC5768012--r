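# Continuous 0-based index coordinates of x + u(x) for every voxel center x.
.field_sample_coords <- function(field) {
  grid <- field$grid
  n <- grid$shape
  base <- list(
    array(rep(0:(n[1] - 1), times = n[2] * n[3]), dim = n),
    array(rep(rep(0:(n[2] - 1), each = n[1]), times = n[3]), dim = n),
    array(rep(0:(n[3] - 1), each = n[1] * n[2]), dim = n))
  lapply(1:3, function(c) base[[c]] + field$vectors[, , , c] / grid$spacing[c])
}

# Trilinear pull-back of a numeric array through a deformation field.
.pullback <- function(values, field, outside = 0) {
  ci <- .field_sample_coords(field)
  out <- cpp_interp3(as.numeric(values), field$grid$shape,
                     as.numeric(ci[[1]]), as.numeric(ci[[2]]),
                     as.numeric(ci[[3]]), outside)
  dim(out) <- field$grid$shape
  out
}

#' Propagate a contour mask through a deformation field
#'
#' Pull-back resampling of the mask indicator with trilinear interpolation,
#' thresholded at 0.5. Used to carry reference-phase contours to the other
#' breathing phases (and back).
#'
#' @param mask a [structure_mask()].
#' @param field a [deformation_field()] on the same lattice.
#' @return A [structure_mask()] on the same lattice.
#' @export
propagate_mask <- function(mask, field) {
  stop_if_lattice_mismatch(mask$grid, field$grid)
  ind <- .pullback(mask$voxels * 1.0, field, outside = 0)
  structure_mask(mask$name, ind >= 0.5, mask$grid)
}

#' Warp a dose grid onto the reference phase
#'
#' Trilinear pull-back of the dose values through the field; lookups falling
#' outside the grid contribute 0 Gy. No mass/energy conservation correction
#' is applied (plain interpolation).
#'
#' @param dose a [dose_grid()].
#' @param field a [deformation_field()] on the same lattice.
#' @return A [dose_grid()].
#' @export
warp_dose <- function(dose, field) {
  stop_if_lattice_mismatch(dose$grid, field$grid)
  out <- .pullback(dose$values, field, outside = 0)
  dose_grid(out, dose$grid, meta = c(dose$meta, list(warped_from = field$source_phase)))
}

#' Compose two deformation fields
#'
#' Returns the field equivalent to applying `inner` and then `outer` under
#' the pull-back convention: `c(x) = inner(x) + outer(x + inner(x))`, with
#' the outer field interpolated trilinearly at the inner-displaced points
#' (out-of-grid lookups extend with zero displacement). Composing with the
#' zero field returns the other field.
#'
#' @param outer,inner [deformation_field()]s on the same lattice.
#' @return A [deformation_field()] with the source phase of `outer`.
#' @export
compose_fields <- function(outer, inner) {
  stop_if_lattice_mismatch(outer$grid, inner$grid)
  grid <- outer$grid
  ci <- .field_sample_coords(inner)
  vec <- array(0, dim = c(grid$shape, 3L))
  for (c in 1:3) {
    o <- cpp_interp3(as.numeric(outer$vectors[, , , c]), grid$shape,
                     as.numeric(ci[[1]]), as.numeric(ci[[2]]),
                     as.numeric(ci[[3]]), 0)
    vec[, , , c] <- inner$vectors[, , , c] + array(o, dim = grid$shape)
  }
  deformation_field(vec, grid, outer$source_phase)
}

#' Dice overlap coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (1.0).
#'
#' @param a,b [structure_mask()]s on the same lattice.
#' @return overlap fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_lattice_mismatch(a$grid, b$grid)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}
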