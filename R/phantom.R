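#' Breathing phase labels of an 8-phase amplitude-binned 4D set
#'
#' Phase 0% is maximum inhale (the reference phase), phase 50% is end exhale.
#' @return numeric vector of the 8 phase labels in percent.
#' @export
phase_labels <- function() c(0, 12.5, 25, 37.5, 50, 62.5, 75, 87.5)

# Fraction of the full inhale->exhale excursion reached at each amplitude-
# binned phase: 0% phase has zero displacement, 50% the full amplitude, and
# the two limbs share amplitude levels (amplitude binning is blind to limb).
phase_fractions <- function() c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25)

#' Describe one phantom of a synthetic cohort
#'
#' Bundles the geometry and motion parameters that one synthetic 4D phantom
#' realizes: tumor volume and motion amplitude, organ-at-risk (OAR) placement
#' by signed minimum distance at maximum inhale (`d_inh`) and relative organ
#' motion (`rom`), the prescription, and the breathing-trace parameters.
#'
#' Each OAR is placed in the axial plane at the planar angle `angle_deg`
#' (measured from +x) so that the signed minimum GTV-OAR distance at phase 0%
#' equals `d_inh` (negative values overlap the tumor). Over the breathing
#' cycle the OAR approaches the tumor in-plane so that the distance at end
#' exhale is `d_inh - rom`; its trajectory also carries the tumor's in-plane
#' motion component so the requested ROM is realized exactly even for
#' laterally moving tumors.
#'
#' @param name phantom identifier.
#' @param prescription_gy prescription dose in Gy (e.g. 50).
#' @param fractions number of fractions (metadata; doses are total-course Gy).
#' @param tumor list: `volume_cc`, `amplitude_cm`, optional `direction`
#'   (default cranial-caudal `c(0,0,1)`) and `center` (cm).
#' @param oars named list (names in ESO/HRT/SC/GRT/TRA or custom); each entry
#'   a list with `d_inh`, `rom`, optional `type` ("tube" or "ellipsoid"),
#'   `radius` / `semiaxes`, `angle_deg`, `density`.
#' @param body planar semi-axes (cm) of the elliptic-cylinder BODY.
#' @param lungs logical, include the two low-density lung ellipsoids.
#' @param breathing list of [generate_breathing_trace()] parameters.
#' @param grid list with `shape` and `spacing` for the phantom lattice.
#' @param noise_sd density texture noise (g/cc) inside the BODY.
#' @param field_sigma_cm Gaussian falloff (cm) of the ground-truth field.
#' @return A `phantom_entry` list.
#' @export
phantom_entry <- function(name = "phantom",
                          prescription_gy = 50, fractions = 5,
                          tumor = list(volume_cc = 10, amplitude_cm = 1,
                                       direction = c(0, 0, 1),
                                       center = c(0, 0, 0)),
                          oars = list(),
                          body = c(11, 10.8),
                          lungs = TRUE,
                          breathing = list(period_s = 5, amplitude = 1,
                                           exponent_n = 2, variability = 0.15,
                                           duration_s = 120,
                                           sample_rate_hz = 250),
                          grid = list(shape = c(96, 96, 96), spacing = 0.25),
                          noise_sd = 0.02,
                          field_sigma_cm = 2) {
  tumor <- utils::modifyList(
    list(volume_cc = 10, amplitude_cm = 1, direction = c(0, 0, 1),
         center = c(0, 0, 0)), tumor)
  oar_defaults <- list(
    ESO = list(type = "tube", radius = 0.5, angle_deg = 205, density = 1.0),
    HRT = list(type = "ellipsoid", semiaxes = c(3.5, 4, 5), angle_deg = 145,
               density = 1.05),
    SC  = list(type = "tube", radius = 0.6, angle_deg = 270, density = 1.3),
    GRT = list(type = "tube", radius = 1.2, angle_deg = 25, density = 1.05),
    TRA = list(type = "tube", radius = 0.9, angle_deg = 90, density = 1.0))
  oars <- lapply(stats::setNames(names(oars), names(oars)), function(nm) {
    base <- if (nm %in% names(oar_defaults)) oar_defaults[[nm]] else
      list(type = "tube", radius = 0.5, angle_deg = 0, density = 1.0)
    utils::modifyList(base, oars[[nm]])
  })
  structure(list(name = name, prescription_gy = prescription_gy,
                 fractions = fractions, tumor = tumor, oars = oars,
                 body = body, lungs = isTRUE(lungs), breathing = breathing,
                 grid = grid, noise_sd = noise_sd,
                 field_sigma_cm = field_sigma_cm),
            class = "phantom_entry")
}

# Planar support radius of a structure toward the tumor (distance from its
# center to its surface along the placement direction).
.oar_support <- function(oar) {
  if (oar$type == "tube") oar$radius else oar$semiaxes[1]
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

# Structure indicator at explicitly given sample coordinates.
.structure_indicator <- function(def, disp, sx, sy, sz) {
  cx <- def$center[1] + disp[1]
  cy <- def$center[2] + disp[2]
  cz <- def$center[3] + disp[3]
  switch(def$type,
    sphere = (sx - cx)^2 + (sy - cy)^2 + (sz - cz)^2 <= def$radius^2,
    tube = (sx - cx)^2 + (sy - cy)^2 <= def$radius^2,
    ellipsoid = {
      u <- def$axis_u; a <- def$semiaxes
      dx <- sx - cx; dy <- sy - cy; dz <- sz - cz
      pu <- dx * u[1] + dy * u[2]
      pv <- -dx * u[2] + dy * u[1]
      (pu / a[1])^2 + (pv / a[2])^2 + (dz / a[3])^2 <= 1
    },
    stop("unknown structure type: ", def$type))
}

# Rasterize a structure at a given center displacement. 2x2x2 supersampling
# with a majority vote: a voxel is included when at least half of its
# sub-cell centers fall inside the analytic surface, which keeps voxelized
# volumes stable (< a few %) under sub-voxel rigid motion.
.structure_voxels <- function(def, disp, co, grid) {
  q <- grid$spacing / 4
  count <- NULL
  for (ox in c(-1, 1)) for (oy in c(-1, 1)) for (oz in c(-1, 1)) {
    ind <- .structure_indicator(def, disp,
                                co$x + ox * q[1], co$y + oy * q[2],
                                co$z + oz * q[3])
    count <- if (is.null(count)) ind + 0L else count + ind
  }
  count >= 4L
}

# Error if a structure's voxels touch the grid boundary on its bounded axes.
.check_in_grid <- function(vox, def, phase_label, grid) {
  n <- grid$shape
  axes <- if (def$type == "tube") 1:2 else 1:3
  touch <- FALSE
  if (1 %in% axes) touch <- touch || any(vox[1, , ]) || any(vox[n[1], , ])
  if (2 %in% axes) touch <- touch || any(vox[, 1, ]) || any(vox[, n[2], ])
  if (3 %in% axes) touch <- touch || any(vox[, , 1]) || any(vox[, , n[3]])
  if (touch)
    stop(sprintf("structure '%s' leaves the grid at phase %s%%",
                 def$name, format(phase_label)), call. = FALSE)
  invisible(TRUE)
}

#' Generate a seeded synthetic 4D phantom
#'
#' Builds an 8-phase amplitude-binned 4D phantom: per phase a density grid
#' (g/cc) and a set of structure masks (GTV, OARs, lungs, BODY), plus the
#' ground-truth per-structure trajectories from which deformation fields are
#' derived. Phase 0% (maximum inhale) is the reference phase and has zero
#' displacement; phase 50% (end exhale) carries the full motion amplitude.
#' The generator is a pure function of `(entry, seed)`.
#'
#' @param entry a [phantom_entry()].
#' @param seed integer seed for the density texture.
#' @return A `phantom4d` object: `grid`, `phases` (8 lists with `density` and
#'   `masks`), `motion` (per-structure 8x3 displacement matrices, cm), and
#'   the generating `entry`.
#' @export
generate_phantom <- function(entry, seed = 1L) {
  stopifnot(inherits(entry, "phantom_entry"))
  if (entry$tumor$amplitude_cm < 0) stop("tumor amplitude must be >= 0")
  grid <- grid_spec(entry$grid$shape, entry$grid$spacing)
  co <- grid_coord_arrays(grid)
  f <- phase_fractions()

  r_t <- (3 * entry$tumor$volume_cc / (4 * pi))^(1 / 3)
  t_dir <- .unit(entry$tumor$direction)
  t_center <- entry$tumor$center
  tumor_traj <- outer(f, entry$tumor$amplitude_cm * t_dir)

  defs <- list(GTV = list(name = "GTV", type = "sphere", radius = r_t,
                          center = t_center, density = 1.0,
                          traj = tumor_traj))
  for (nm in names(entry$oars)) {
    oar <- entry$oars[[nm]]
    if (oar$rom < 0) stop("OAR ROM must be >= 0")
    ang <- oar$angle_deg * pi / 180
    u_hat <- c(cos(ang), sin(ang), 0)
    s <- oar$d_inh + r_t + .oar_support(oar)
    if (s <= 0)
      stop(sprintf("OAR '%s': requested d_inh places it beyond the tumor center", nm))
    center <- c(t_center[1:2] + s * u_hat[1:2], if (oar$type == "tube") 0 else t_center[3])
    # in-plane co-motion with the tumor plus an approach of `rom` by exhale
    traj <- cbind(tumor_traj[, 1:2, drop = FALSE], 0) -
      outer(f, oar$rom * u_hat)
    defs[[nm]] <- list(name = nm, type = oar$type, radius = oar$radius,
                       semiaxes = oar$semiaxes, axis_u = u_hat[1:2],
                       center = center, density = oar$density, traj = traj)
  }

  body_vox <- (co$x / entry$body[1])^2 + (co$y / entry$body[2])^2 <= 1
  lung_defs <- NULL
  if (entry$lungs) {
    lung_defs <- list(
      list(center = c(-5.5, 0, 0), semiaxes = c(4.2, 7, 9)),
      list(center = c(5.5, 0, 0), semiaxes = c(4.2, 7, 9)))
  }

  # one anatomy-fixed density texture, shared by all phases
  noise <- withr::with_seed(as.integer(seed),
    array(stats::rnorm(prod(grid$shape), 0, entry$noise_sd),
          dim = grid$shape))

  phases <- vector("list", 8L)
  labels <- phase_labels()
  memo <- new.env(parent = emptyenv())
  for (p in 1:8) {
    masks <- list(BODY = structure_mask("BODY", body_vox, grid))
    dens <- array(0.0012, dim = grid$shape)
    dens[body_vox] <- 1.0
    lung_vox <- NULL
    if (!is.null(lung_defs)) {
      lung_vox <- array(FALSE, dim = grid$shape)
      for (ld in lung_defs) {
        lung_vox <- lung_vox |
          ((co$x - ld$center[1]) / ld$semiaxes[1])^2 +
          ((co$y - ld$center[2]) / ld$semiaxes[2])^2 +
          ((co$z - ld$center[3]) / ld$semiaxes[3])^2 <= 1
      }
      lung_vox <- lung_vox & body_vox
    }
    other_union <- array(FALSE, dim = grid$shape)
    for (nm in names(defs)) {
      def <- defs[[nm]]
      # amplitude binning visits each displacement twice (one per limb):
      # memoize rasterizations per displacement
      key <- paste0(nm, "|", paste(signif(def$traj[p, ], 10), collapse = ","))
      vox <- memo[[key]]
      if (is.null(vox)) {
        vox <- .structure_voxels(def, def$traj[p, ], co, grid)
        memo[[key]] <- vox
      }
      .check_in_grid(vox, def, labels[p], grid)
      vox <- vox & body_vox
      if (!any(vox))
        stop(sprintf("structure '%s' is empty at phase %s%%", nm, labels[p]))
      masks[[nm]] <- structure_mask(nm, vox, grid)
      other_union <- other_union | vox
    }
    if (!is.null(lung_vox)) {
      lung_vox <- lung_vox & !other_union
      masks[["LNG"]] <- structure_mask("LNG", lung_vox, grid)
      dens[lung_vox] <- 0.26
    }
    for (nm in names(defs)) dens[masks[[nm]]$voxels] <- defs[[nm]]$density
    dens <- dens + noise * body_vox
    dens[dens < 0.001] <- 0.001
    phases[[p]] <- list(density = dens, masks = masks)
  }

  traj_list <- lapply(defs, `[[`, "traj")
  if (!is.null(lung_defs)) traj_list$LNG <- matrix(0, 8, 3)
  traj_list$BODY <- matrix(0, 8, 3)
  motion <- list(traj = traj_list,
                 tumor_amplitude_cm = entry$tumor$amplitude_cm,
                 phase_fractions = f)
  structure(list(grid = grid, phases = phases, motion = motion,
                 entry = entry, seed = as.integer(seed),
                 cache = new.env(parent = emptyenv())),
            class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  cat(sprintf("phantom4d '%s': %s grid, 8 phases, GTV %.1f cc, amplitude %.2f cm\n",
              x$entry$name, paste(x$grid$shape, collapse = "x"),
              mask_volume_cc(x$phases[[1]]$masks$GTV),
              x$motion$tumor_amplitude_cm))
  invisible(x)
}

#' Extract a structure mask from a phantom phase
#' @param phantom a `phantom4d`.
#' @param name structure name.
#' @param phase 0-based phase index (0..7).
#' @export
phantom_mask <- function(phantom, name, phase = 0L) {
  m <- phantom$phases[[phase + 1L]]$masks[[name]]
  if (is.null(m)) stop("no structure '", name, "' in phantom")
  m
}

# Cached distance map of a structure's motion envelope (union over phases).
.envelope_distance <- function(phantom, name) {
  key <- paste0("env_", name)
  if (!is.null(phantom$cache[[key]])) return(phantom$cache[[key]])
  env <- Reduce(`|`, lapply(phantom$phases, function(ph) ph$masks[[name]]$voxels))
  d <- distance_map(env, phantom$grid)
  phantom$cache[[key]] <- d
  d
}

# Analytic displacement field built from per-structure rigid translations
# blended by inverse-square-distance (Shepard) weights to each structure's
# motion envelope, modulated by a Gaussian falloff (sd field_sigma_cm) and
# normalized against a constant background weight so displacement decays to
# zero away from the structures. Inside an envelope the distance is 0 and
# the structure's own weight dominates, so the field equals that
# structure's translation there — including zero inside static organs,
# which anatomy-driven registration would also hold still. The lungs and
# BODY are left out of the blend (deformable background tissue).
.gt_field <- function(phantom, translations, source_phase) {
  grid <- phantom$grid
  sigma <- phantom$entry$field_sigma_cm
  eps <- 1e-3   # cm^2; caps the weight inside an envelope at 1/eps
  w0 <- 0.25    # background weight: sets the far-field decay profile
  anchors <- setdiff(names(translations), c("BODY", "LNG"))
  moving <- anchors[vapply(translations[anchors],
                           function(t) any(t != 0), logical(1))]
  n <- grid$shape
  if (length(moving) == 0L) return(zero_field(grid, source_phase))
  num <- list(array(0, n), array(0, n), array(0, n))
  den <- array(w0, n)
  for (nm in anchors) {
    d <- .envelope_distance(phantom, nm)
    w <- exp(-d^2 / (2 * sigma^2)) / (d^2 + eps)
    t_s <- translations[[nm]]
    for (c in 1:3) if (t_s[c] != 0) num[[c]] <- num[[c]] + t_s[c] * w
    den <- den + w
  }
  vec <- array(0, dim = c(n, 3L))
  for (c in 1:3) vec[, , , c] <- num[[c]] / den
  deformation_field(vec, grid, source_phase)
}

#' Ground-truth deformation field of a breathing phase
#'
#' Returns the analytic displacement field mapping reference-phase (0%) world
#' coordinates to the corresponding points of phase `phase` (pull-back
#' convention). Per-structure rigid translations are blended by a Gaussian
#' falloff (sd `field_sigma_cm`) of the distance to each moving structure's
#' motion envelope, so the field equals the structure translation inside the
#' envelope and decays to zero in the far background. Phase 0 yields the
#' identically zero field.
#'
#' @param phantom a `phantom4d`.
#' @param phase 0-based phase index in 0..7.
#' @return A [deformation_field()].
#' @export
ground_truth_field <- function(phantom, phase) {
  phase <- as.integer(phase)
  if (phase < 0L || phase > 7L) stop("phase must be in 0..7")
  if (phase == 0L) return(zero_field(phantom$grid, 0L))
  tr <- lapply(phantom$motion$traj, function(m) m[phase + 1L, ])
  .gt_field(phantom, tr, phase)
}

# Incremental ground-truth field from phase `from` to phase `to` (used to
# emulate a cascaded phase-to-phase registration).
.gt_field_between <- function(phantom, from, to) {
  tr <- lapply(phantom$motion$traj,
               function(m) m[to + 1L, ] - m[from + 1L, ])
  .gt_field(phantom, tr, to)
}
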