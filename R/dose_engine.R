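#' Parameters of the deterministic dose engine
#'
#' The engine is analytic: per beam, the dose at a voxel is the in-plane
#' aperture fluence (aperture indicator convolved with a Gaussian penumbra)
#' attenuated exponentially with radiological depth and scaled by the
#' inverse-square distance from the source,
#' `D(v) = sum_b F_b(v) * exp(-mu * d_rad(v)) * (SAD / r(v))^2`.
#'
#' @param mu_cm linear attenuation coefficient in 1/cm (default 0.045,
#'   megavoltage-like depth falloff in water).
#' @param sigma_cm Gaussian penumbra sd at the isocenter plane in cm
#'   (default 0.3, i.e. an 80-20 penumbra of about 5 mm at isocenter).
#' @param inverse_square apply the inverse-square factor (default TRUE).
#' @param fluence_pixel_cm rasterization pixel of the in-plane fluence map.
#' @return An `engine_params` object.
#' @export
engine_params <- function(mu_cm = 0.045, sigma_cm = 0.3,
                          inverse_square = TRUE, fluence_pixel_cm = 0.05) {
  stopifnot(mu_cm > 0, sigma_cm >= 0, fluence_pixel_cm > 0)
  structure(list(mu_cm = mu_cm, sigma_cm = sigma_cm,
                 inverse_square = inverse_square,
                 fluence_pixel_cm = fluence_pixel_cm),
            class = "engine_params")
}

# Per-beam projection geometry on a grid: depth-from-isocenter u, in-plane
# (unmagnified) coordinates a1/a2, isocenter-plane projections p1/p2, and
# the inverse-square factor. Cached per (grid, beam index) when a cache
# environment is supplied.
.beam_geometry <- function(grid, bm, cache = NULL, key = NULL) {
  if (!is.null(cache) && !is.null(key) && !is.null(cache[[key]]))
    return(cache[[key]])
  ax <- beam_axes(bm)
  u <- grid_affine_array(grid, ax$dir, -sum(ax$dir * bm$iso))
  a1 <- grid_affine_array(grid, ax$e1, -sum(ax$e1 * bm$iso))
  a2 <- grid_affine_array(grid, ax$e2, -sum(ax$e2 * bm$iso))
  m <- bm$sad_cm / (bm$sad_cm + u)
  g <- list(u = u, a1 = a1, a2 = a2, p1 = a1 * m, p2 = a2 * m,
            invsq = bm$sad_cm^2 / ((bm$sad_cm + u)^2 + a1^2 + a2^2))
  if (!is.null(cache) && !is.null(key)) cache[[key]] <- g
  g
}

# Radiological depth (density-weighted path length, cm) of every voxel,
# along rays parallel to the beam axis. The density is resampled onto a
# beam-aligned lattice, integrated cumulatively along the beam direction
# (midpoint rule), and interpolated back at the voxel beam coordinates.
.radiological_depth <- function(grid, bm, density, geom) {
  ax <- beam_axes(bm)
  step <- min(grid$spacing)
  r1 <- range(geom$a1); r2 <- range(geom$a2); rw <- range(geom$u)
  t1 <- seq(r1[1], r1[2] + step, by = step)
  t2 <- seq(r2[1], r2[2] + step, by = step)
  w <- seq(rw[1], rw[2] + step, by = step)
  nw <- length(w); n1 <- length(t1); n2 <- length(t2)
  # world coords of the beam-aligned lattice (w fastest)
  wx <- bm$iso[1] + outer(w * ax$dir[1], t1 * ax$e1[1], `+`)
  wy <- bm$iso[2] + outer(w * ax$dir[2], t1 * ax$e1[2], `+`)
  xi <- (rep(wx, times = n2) +
           rep(t2 * ax$e2[1], each = nw * n1) - grid$origin[1]) / grid$spacing[1]
  yi <- (rep(wy, times = n2) +
           rep(t2 * ax$e2[2], each = nw * n1) - grid$origin[2]) / grid$spacing[2]
  zi_base <- outer(w * ax$dir[3], t1 * ax$e1[3], `+`)
  zi <- (rep(zi_base, times = n2) + bm$iso[3] +
           rep(t2 * ax$e2[3], each = nw * n1) - grid$origin[3]) / grid$spacing[3]
  rho <- cpp_interp3(as.numeric(density), grid$shape, xi, yi, zi, 0)
  rho <- matrix(rho, nrow = nw)
  cum <- rho
  for (i in 2:nw) cum[i, ] <- cum[i, ] + cum[i - 1, ]
  depth <- (cum - rho / 2) * step
  dd <- cpp_interp3(as.numeric(depth), c(nw, n1, n2),
                    (as.numeric(geom$u) - w[1]) / step,
                    (as.numeric(geom$a1) - t1[1]) / step,
                    (as.numeric(geom$a2) - t2[1]) / step, 0)
  array(dd, dim = grid$shape)
}

# Smoothed in-plane fluence map of an aperture; returns NULL when closed.
.fluence_map <- function(ap, params) {
  if (nrow(ap$rows) == 0L) return(NULL)
  px <- params$fluence_pixel_cm
  sg <- params$sigma_cm
  pad <- 4 * sg + 2 * px
  lw <- ap$leaf_width_cm
  p1r <- c(min(ap$rows$left) - pad, max(ap$rows$right) + pad)
  p2r <- c((min(ap$rows$k) - 0.5) * lw - pad, (max(ap$rows$k) + 0.5) * lw + pad)
  g1 <- seq(p1r[1], p1r[2], by = px)
  g2 <- seq(p2r[1], p2r[2], by = px)
  m <- matrix(0, length(g1), length(g2))
  for (i in seq_len(nrow(ap$rows))) {
    r <- ap$rows[i, ]
    # partial-pixel coverage along the leaf-travel axis
    cov <- pmin(1, pmax(0, (pmin(g1 + px / 2, r$right) -
                              pmax(g1 - px / 2, r$left)) / px))
    j <- which(g2 >= (r$k - 0.5) * lw & g2 < (r$k + 0.5) * lw)
    m[, j] <- m[, j] + cov
  }
  m[m > 1] <- 1
  if (sg > 0) {
    hk <- ceiling(4 * sg / px)
    kern <- stats::dnorm(seq(-hk, hk) * px, sd = sg)
    kern <- kern / sum(kern)
    m <- cpp_conv_sep2(m, kern)
  }
  list(map = m, origin = c(g1[1], g2[1]), pixel = px)
}

#' Compute the dose of one plan phase on one phantom phase
#'
#' Deterministic forward calculation: for each beam, the aperture indicator
#' is rasterized in the isocenter plane, convolved with the Gaussian
#' penumbra, sampled at each voxel's source-ray projection onto the
#' isocenter plane (so the penumbra width scales with magnification),
#' attenuated by `exp(-mu * radiological depth)` and weighted by the
#' inverse-square factor. Radiological depth is the density-weighted path
#' length from the body surface along the beam direction.
#'
#' @param apertures list of [aperture()]s, one per beam (a closed aperture
#'   contributes zero dose).
#' @param beams list of [beam()]s.
#' @param density numeric 3D density array (g/cc) on `grid`.
#' @param grid the [grid_spec()].
#' @param params an [engine_params()].
#' @param cache optional environment for memoizing per-beam geometry and
#'   per-(beam, phase) attenuation (supply `phase_key` too).
#' @param phase_key identifier of the phantom phase for depth caching.
#' @return A [dose_grid()] in engine units (normalize with
#'   [normalize_v99()] to prescription Gy).
#' @export
compute_dose <- function(apertures, beams, density, grid,
                         params = engine_params(), cache = NULL,
                         phase_key = NULL) {
  stopifnot(length(apertures) == length(beams))
  if (!all(dim(density) == grid$shape))
    stop("density does not match the grid", call. = FALSE)
  total <- array(0, dim = grid$shape)
  for (b in seq_along(beams)) {
    bm <- beams[[b]]
    geom <- .beam_geometry(grid, bm, cache, key = paste0("geom_", b))
    kern_key <- if (!is.null(phase_key)) paste0("kern_", b, "_", phase_key)
    kern <- if (!is.null(cache) && !is.null(kern_key)) cache[[kern_key]]
    if (is.null(kern)) {
      depth <- .radiological_depth(grid, bm, density, geom)
      kern <- exp(-params$mu_cm * depth)
      if (params$inverse_square) kern <- kern * geom$invsq
      if (!is.null(cache) && !is.null(kern_key)) cache[[kern_key]] <- kern
    }
    ap <- apertures[[b]]
    if (is.null(ap) || nrow(ap$rows) == 0L) next
    fm <- .fluence_map(ap, params)
    fl <- cpp_interp2(fm$map,
                      (as.numeric(geom$p1) - fm$origin[1]) / fm$pixel,
                      (as.numeric(geom$p2) - fm$origin[2]) / fm$pixel, 0)
    total <- total + array(fl, dim = grid$shape) * kern
  }
  dose_grid(total, grid, meta = list(n_beams = length(beams)))
}

#' Normalize a dose grid so the target V99% is 100%
#'
#' Scales the dose by `0.99 * prescription / min(dose over target)`, after
#' which exactly 100% of the target volume receives at least 99% of the
#' prescription (the coldest target voxel sits exactly at 99%). Idempotent.
#'
#' @param dose a [dose_grid()].
#' @param target non-empty [structure_mask()] with positive minimum dose.
#' @param prescription_gy prescription dose in Gy.
#' @return The rescaled [dose_grid()]; the factor is stored in
#'   `meta$norm_factor`.
#' @export
normalize_v99 <- function(dose, target, prescription_gy) {
  stop_if_lattice_mismatch(dose$grid, target$grid)
  if (!any(target$voxels)) stop("empty normalization target", call. = FALSE)
  dmin <- min(dose$values[target$voxels])
  if (dmin <= 0) stop("target minimum dose is zero", call. = FALSE)
  # nudge above the V99 threshold so the coldest voxel cannot round below
  # 0.99 Rx in floating point
  f <- 0.99 * prescription_gy / dmin * (1 + 1e-12)
  dose_grid(dose$values * f, dose$grid,
            meta = c(dose$meta, list(norm_factor = f,
                                     prescription_gy = prescription_gy)))
}
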