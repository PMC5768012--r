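#' Machine geometry presets
#'
#' `"mrl"`: MRI-linac with source-axis distance 143.5 cm and projected MLC
#' leaf width 0.72 cm at isocenter. `"conventional"`: standard linac with
#' SAD 100 cm and 0.5 cm projected leaf width.
#'
#' @param machine `"mrl"` or `"conventional"`.
#' @return list with `sad_cm` and `leaf_width_cm`.
#' @export
machine_params <- function(machine = c("mrl", "conventional")) {
  machine <- match.arg(machine)
  switch(machine,
         mrl = list(sad_cm = 143.5, leaf_width_cm = 0.72),
         conventional = list(sad_cm = 100, leaf_width_cm = 0.5))
}

#' Coplanar isocentric treatment beam
#'
#' Gantry angle 0 places the source on the +y (anterior) axis; positive
#' angles rotate in the axial (x-y) plane. The isocenter-plane axes are
#' `e1` (lateral, along which leaves travel) and `e2 = +z` (cranial-caudal,
#' along which leaf rows stack).
#'
#' @param gantry_deg gantry angle in degrees.
#' @param iso isocenter world coordinates (cm).
#' @param sad_cm source-to-axis distance (cm).
#' @param leaf_width_cm projected MLC leaf width at isocenter (cm).
#' @return A `beam` object.
#' @export
beam <- function(gantry_deg, iso = c(0, 0, 0), sad_cm = 143.5,
                 leaf_width_cm = 0.72) {
  stopifnot(sad_cm > 0, leaf_width_cm > 0)
  structure(list(gantry_deg = gantry_deg, iso = as.numeric(iso),
                 sad_cm = sad_cm, leaf_width_cm = leaf_width_cm),
            class = "beam")
}

# Orthonormal beam frame: dir (travel direction), e1 (lateral in-plane),
# e2 (cranial-caudal in-plane). Source sits at iso - sad * dir.
beam_axes <- function(beam) {
  th <- beam$gantry_deg * pi / 180
  dir <- c(-sin(th), -cos(th), 0)
  e1 <- c(cos(th), -sin(th), 0)
  list(dir = dir, e1 = e1, e2 = c(0, 0, 1))
}

#' MLC aperture in the isocenter plane
#'
#' Leaf rows stack along the cranial-caudal in-plane axis at leaf-width
#' pitch; row `k` is centered at `k * leaf_width`. Only open rows are
#' stored, each with its `[left, right]` lateral opening in cm.
#'
#' @param rows data.frame with columns `k` (integer row index), `left`,
#'   `right` (cm, `left <= right`).
#' @param leaf_width_cm leaf-row pitch (cm).
#' @return An `aperture` object.
#' @export
aperture <- function(rows, leaf_width_cm) {
  stopifnot(is.data.frame(rows), all(c("k", "left", "right") %in% names(rows)))
  if (nrow(rows) > 0) {
    stopifnot(all(rows$left <= rows$right), !anyDuplicated(rows$k))
    rows <- rows[order(rows$k), , drop = FALSE]
  }
  structure(list(rows = rows, leaf_width_cm = leaf_width_cm),
            class = "aperture")
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf("aperture: %d open rows (leaf width %.2f cm), area %.2f cm^2\n",
              nrow(x$rows), x$leaf_width_cm, aperture_area(x)))
  invisible(x)
}

#' Open area of an aperture (cm^2)
#' @param ap an [aperture()].
#' @export
aperture_area <- function(ap) {
  if (nrow(ap$rows) == 0L) return(0)
  sum((ap$rows$right - ap$rows$left) * ap$leaf_width_cm)
}

#' Area-weighted in-plane centroid of an aperture
#' @param ap an [aperture()].
#' @return numeric `(p1, p2)` in cm; `c(NA, NA)` for a closed aperture.
#' @export
aperture_centroid <- function(ap) {
  if (nrow(ap$rows) == 0L) return(c(NA_real_, NA_real_))
  w <- (ap$rows$right - ap$rows$left) * ap$leaf_width_cm
  c(sum((ap$rows$left + ap$rows$right) / 2 * w) / sum(w),
    sum(ap$rows$k * ap$leaf_width_cm * w) / sum(w))
}

#' Isotropic margin expansion of a structure mask
#'
#' Euclidean dilation via the distance transform: the output contains every
#' voxel whose center lies within `margin_cm` of the mask surface. The
#' center-to-center distance map is thresholded at `margin + h/3` (h = mean
#' voxel size): the outermost mask voxel centers sit below the true surface
#' of the solid they discretize, and the one-third-voxel offset removes the
#' resulting volume bias of a plain center-to-center dilation (checked
#' against analytic sphere dilations over random grid alignments). The 5-mm
#' planning target volume (PTV) margin around the GTV is the standard use.
#'
#' @param mask a [structure_mask()].
#' @param margin_cm non-negative margin in cm.
#' @return A [structure_mask()] containing the input.
#' @export
expand_margin <- function(mask, margin_cm) {
  if (margin_cm < 0) stop("margin must be >= 0", call. = FALSE)
  if (margin_cm == 0) return(mask)
  d <- distance_map(mask)
  h <- mean(mask$grid$spacing)
  structure_mask(mask$name, d <= margin_cm + h / 3 + 1e-9, mask$grid)
}

#' Internal target volume from per-phase GTVs
#'
#' Union of the GTV over all breathing phases, then isotropic expansion by
#' the setup margin: the fixed target of the ITV motion-management approach.
#'
#' @param gtv_masks list of per-phase GTV [structure_mask()]s (common lattice).
#' @param margin_cm isotropic margin in cm (default 0.5, the 5-mm PTV margin).
#' @return A [structure_mask()] named `"ITV"`.
#' @export
build_itv <- function(gtv_masks, margin_cm = 0.5) {
  stopifnot(length(gtv_masks) >= 1L)
  grid <- gtv_masks[[1]]$grid
  for (m in gtv_masks) {
    stop_if_lattice_mismatch(grid, m$grid)
    if (!any(m$voxels)) stop("empty GTV mask in ITV construction", call. = FALSE)
  }
  uni <- Reduce(`|`, lapply(gtv_masks, `[[`, "voxels"))
  expand_margin(structure_mask("ITV", uni, grid), margin_cm)
}

#' Beam's-eye-view aperture around a target
#'
#' Every target voxel center is ray-projected from the point source through
#' the isocenter plane (perpendicular to the beam axis). Per leaf row, the
#' opening is the `[min, max]` lateral extent of the projected points whose
#' cranial-caudal coordinate falls in that row; rows receiving no points
#' stay closed.
#'
#' @param target non-empty [structure_mask()].
#' @param beam a [beam()].
#' @return An [aperture()].
#' @export
bev_aperture <- function(target, beam) {
  idx <- which(target$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty target", call. = FALSE)
  grid <- target$grid
  w <- sweep((idx - 1) %*% diag(grid$spacing), 2, grid$origin, `+`)
  ax <- beam_axes(beam)
  rel <- sweep(w, 2, beam$iso, `-`)
  u <- rel %*% ax$dir
  m <- beam$sad_cm / (beam$sad_cm + u)
  p1 <- (rel %*% ax$e1) * m
  p2 <- (rel %*% ax$e2) * m
  lw <- beam$leaf_width_cm
  k <- floor(p2 / lw + 0.5)
  left <- tapply(p1, k, min)
  right <- tapply(p1, k, max)
  rows <- data.frame(k = as.integer(names(left)),
                     left = as.numeric(left), right = as.numeric(right))
  aperture(rows, lw)
}

#' Virtual couch shift of an aperture
#'
#' Translates the aperture in the isocenter plane by the in-plane projection
#' of a target displacement while the beam isocenter stays fixed: the MLC
#' follows the target instead of the couch moving. The cranial-caudal
#' component is re-quantized to the leaf-row grid (round to nearest row,
#' ties toward cranial); the lateral component shifts the leaf openings
#' continuously.
#'
#' @param ap an [aperture()].
#' @param displacement 3-vector target displacement in world cm.
#' @param beam the [beam()] the aperture belongs to.
#' @return An [aperture()].
#' @export
vcs_shift <- function(ap, displacement, beam) {
  stopifnot(all(is.finite(displacement)), length(displacement) == 3L)
  ax <- beam_axes(beam)
  d1 <- sum(displacement * ax$e1)
  d2 <- sum(displacement * ax$e2)
  rows <- ap$rows
  if (nrow(rows) > 0) {
    rows$left <- rows$left + d1
    rows$right <- rows$right + d1
    rows$k <- as.integer(rows$k + floor(d2 / ap$leaf_width_cm + 0.5))
  }
  aperture(rows, ap$leaf_width_cm)
}

#' Treatment plan: beams, apertures, prescription
#'
#' @param strategy `"ITV"` (one fixed aperture per beam) or `"4DMRL"`
#'   (8 per-phase tracked apertures per beam).
#' @param beams list of [beam()]s (identical isocenter).
#' @param apertures per beam: a single [aperture()] (ITV) or a list of 8
#'   per-phase apertures (4DMRL).
#' @param prescription_gy prescription dose in Gy.
#' @param fractions number of fractions (metadata).
#' @param margin_cm PTV margin used to build the targets.
#' @return A `treatment_plan` object.
#' @export
treatment_plan <- function(strategy = c("ITV", "4DMRL"), beams, apertures,
                           prescription_gy, fractions, margin_cm = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(length(beams) == length(apertures), length(beams) >= 1L)
  iso <- beams[[1]]$iso
  for (b in beams) stopifnot(max(abs(b$iso - iso)) < 1e-9)
  if (strategy == "4DMRL") {
    for (a in apertures) stopifnot(is.list(a), length(a) == 8L)
  } else {
    for (a in apertures) stopifnot(inherits(a, "aperture"))
  }
  structure(list(strategy = strategy, beams = beams, apertures = apertures,
                 prescription_gy = prescription_gy, fractions = fractions,
                 margin_cm = margin_cm),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("treatment_plan [%s]: %d beams, %g Gy / %d fx\n",
              x$strategy, length(x$beams), x$prescription_gy, x$fractions))
  invisible(x)
}

# Aperture set of a plan for one beam at one phase (0-based).
plan_aperture <- function(plan, beam_idx, phase = 0L) {
  a <- plan$apertures[[beam_idx]]
  if (plan$strategy == "ITV") a else a[[phase + 1L]]
}

#' Build an ITV or tracked (4D-MRL) plan for a phantom
#'
#' ITV strategy: one fixed beam's-eye-view aperture per beam around the ITV
#' (union of all phase GTVs plus margin). 4DMRL strategy: the phase-0
#' aperture targets the phase-0 PTV (GTV + margin) and the apertures of the
#' other phases are virtual-couch-shift copies translated by the GTV
#' centroid displacement of that phase, emulating MLC tumor tracking with a
#' fixed isocenter.
#'
#' @param phantom a `phantom4d`.
#' @param strategy `"ITV"` or `"4DMRL"`.
#' @param beam_config list: `machine` ("mrl"/"conventional"), `n_beams`
#'   (default 7 equispaced coplanar beams) or explicit `angles_deg`;
#'   optional `iso` (defaults to the phase-0 GTV centroid).
#' @param prescription_gy,fractions prescription; default from the phantom
#'   entry.
#' @param margin_cm PTV margin (default 0.5 cm).
#' @return A [treatment_plan()].
#' @export
make_plan <- function(phantom, strategy = c("ITV", "4DMRL"),
                      beam_config = list(), prescription_gy = NULL,
                      fractions = NULL, margin_cm = 0.5) {
  strategy <- match.arg(strategy)
  cfg <- utils::modifyList(list(machine = "mrl", n_beams = 7L,
                                angles_deg = NULL, iso = NULL), beam_config)
  mp <- machine_params(cfg$machine)
  if (is.null(cfg$angles_deg))
    cfg$angles_deg <- seq(0, 360, length.out = cfg$n_beams + 1L)[seq_len(cfg$n_beams)]
  if (is.null(prescription_gy)) prescription_gy <- phantom$entry$prescription_gy
  if (is.null(fractions)) fractions <- phantom$entry$fractions
  gtv0 <- phantom_mask(phantom, "GTV", 0L)
  iso <- if (is.null(cfg$iso)) mask_centroid(gtv0) else cfg$iso
  beams <- lapply(cfg$angles_deg, beam, iso = iso, sad_cm = mp$sad_cm,
                  leaf_width_cm = mp$leaf_width_cm)
  if (strategy == "ITV") {
    itv <- build_itv(lapply(0:7, function(p) phantom_mask(phantom, "GTV", p)),
                     margin_cm)
    apertures <- lapply(beams, function(b) bev_aperture(itv, b))
  } else {
    ptv0 <- expand_margin(gtv0, margin_cm)
    c0 <- mask_centroid(gtv0)
    shifts <- lapply(0:7, function(p) {
      if (p == 0L) c(0, 0, 0) else mask_centroid(phantom_mask(phantom, "GTV", p)) - c0
    })
    apertures <- lapply(beams, function(b) {
      ap0 <- bev_aperture(ptv0, b)
      lapply(shifts, function(s) vcs_shift(ap0, s, b))
    })
  }
  treatment_plan(strategy, beams, apertures, prescription_gy, fractions,
                 margin_cm)
}
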