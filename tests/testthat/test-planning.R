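test_that("margin expansion matches analytic sphere dilation", {
  g <- small_grid(49)
  sph <- sphere_mask(g, 1)
  expect_identical(expand_margin(sph, 0)$voxels, sph$voxels)
  ex <- expand_margin(sph, 0.5)
  expect_true(all(ex$voxels[sph$voxels]))   # PTV contains the GTV
  expect_equal(mask_volume_cc(ex), 4 / 3 * pi * 1.5^3, tolerance = 0.05)
  expect_error(expand_margin(sph, -0.1), ">= 0")
})

test_that("ITV union of displaced spheres matches the lens closed form", {
  g <- grid_spec(c(49, 49, 61), 0.25)
  m1 <- sphere_mask(g, 1)
  m2 <- sphere_mask(g, 1, center = c(0, 0, 1.74))
  itv <- build_itv(list(m1, m2), margin_cm = 0)
  r <- 1; d <- 1.74
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  expect_equal(mask_volume_cc(itv), 2 * (4 / 3) * pi * r^3 - lens,
               tolerance = 0.05)
  expect_true(all(itv$voxels[m1$voxels]))
  expect_true(all(itv$voxels[m2$voxels]))

  # static tumor: ITV = margin-expanded GTV
  itv_static <- build_itv(list(m1, m1), margin_cm = 0.5)
  expect_identical(itv_static$voxels, expand_margin(m1, 0.5)$voxels)
  empty <- structure_mask("GTV", array(FALSE, g$shape), g)
  expect_error(build_itv(list(m1, empty)), "empty")
})

test_that("beam's-eye-view apertures trace the projected target silhouette", {
  g <- small_grid(49)
  sph <- sphere_mask(g, 1)
  b <- beam(0, c(0, 0, 0), sad_cm = 143.5, leaf_width_cm = 0.72)
  ap <- bev_aperture(sph, b)
  for (i in seq_len(nrow(ap$rows))) {
    z <- ap$rows$k[i] * ap$leaf_width_cm
    chord <- if (abs(z) < 1) sqrt(1 - z^2) else 0
    expect_lt(abs(ap$rows$right[i] - chord), ap$leaf_width_cm / 2)
    expect_lt(abs(-ap$rows$left[i] - chord), ap$leaf_width_cm / 2)
  }
  expect_error(bev_aperture(structure_mask("E", array(FALSE, g$shape), g), b),
               "empty")

  # laterally displaced target moves the aperture centroid by the offset
  sph2 <- sphere_mask(g, 1, center = c(1, 0, 0))
  ap2 <- bev_aperture(sph2, b)
  expect_equal(aperture_centroid(ap2)[1] - aperture_centroid(ap)[1], 1.0,
               tolerance = 0.1)
})

test_that("MRL and conventional leaf widths both cover the projected disk", {
  g <- small_grid(49)
  sph <- sphere_mask(g, 1)
  ap_mrl <- bev_aperture(sph, beam(0, sad_cm = 143.5, leaf_width_cm = 0.72))
  ap_con <- bev_aperture(sph, beam(0, sad_cm = 100, leaf_width_cm = 0.5))
  disk <- pi * 1^2
  leaf_row_area <- function(lw) lw * 2  # one row spanning the disk diameter
  expect_gt(aperture_area(ap_mrl), 0.95 * disk)
  expect_gt(aperture_area(ap_con), 0.95 * disk)
  expect_lt(abs(aperture_area(ap_mrl) - aperture_area(ap_con)),
            leaf_row_area(0.72) + leaf_row_area(0.5))
})

test_that("virtual couch shift translates apertures on the leaf grid", {
  g <- small_grid(49)
  ap <- bev_aperture(sphere_mask(g, 1), beam(0))
  b <- beam(0)
  expect_identical(vcs_shift(ap, c(0, 0, 0), b)$rows, ap$rows)

  # cranial displacement shifts rows by the nearest whole leaf pitch
  ap_z <- vcs_shift(ap, c(0, 0, 1), b)
  expect_equal(ap_z$rows$k, ap$rows$k + round(1 / 0.72))
  expect_equal(ap_z$rows$left, ap$rows$left)

  # lateral displacement shifts openings continuously
  ap_x <- vcs_shift(ap, c(1, 0, 0), b)
  expect_equal(ap_x$rows$left, ap$rows$left + 1)
  expect_equal(ap_x$rows$right, ap$rows$right + 1)
  expect_equal(ap_x$rows$k, ap$rows$k)
})

test_that("plans carry prescriptions and track or encompass the target", {
  e <- tiny_entry(amplitude = 1.5, prescription_gy = 52, fractions = 4)
  ph <- generate_phantom(e, 2)
  plan_itv <- make_plan(ph, "ITV", beam_config = list(n_beams = 3))
  plan_mrl <- make_plan(ph, "4DMRL", beam_config = list(n_beams = 3))
  expect_equal(plan_itv$prescription_gy, 52)
  expect_equal(plan_itv$fractions, 4)
  expect_length(plan_mrl$apertures[[1]], 8L)
  expect_s3_class(plan_itv$apertures[[1]], "aperture")

  # tracked apertures keep a constant open area across phases
  areas <- vapply(plan_mrl$apertures[[1]], aperture_area, numeric(1))
  expect_lt(max(areas) - min(areas), 1e-9)

  # the fixed ITV aperture is larger than any tracked aperture
  expect_gt(aperture_area(plan_itv$apertures[[1]]), max(areas))

  # isocenter shared across beams and phases by construction
  isos <- t(vapply(plan_mrl$beams, `[[`, numeric(3), "iso"))
  expect_equal(max(apply(isos, 2, function(x) diff(range(x)))), 0)
})

test_that("static phantoms make tracked and ITV plans identical", {
  e <- tiny_entry(amplitude = 0)
  ph <- generate_phantom(e, 2)
  plan_itv <- make_plan(ph, "ITV", beam_config = list(n_beams = 3))
  plan_mrl <- make_plan(ph, "4DMRL", beam_config = list(n_beams = 3))
  for (b in 1:3) {
    for (p in 1:8) {
      expect_equal(plan_mrl$apertures[[b]][[p]]$rows,
                   plan_itv$apertures[[b]]$rows)
    }
  }
})

test_that("target coverage gap between ITV and tracking grows with amplitude", {
  union_ptv <- function(ph, margin = 0.5) {
    masks <- lapply(0:7, function(p)
      expand_margin(phantom_mask(ph, "GTV", p), margin))
    sum(Reduce(`|`, lapply(masks, `[[`, "voxels"))) *
      prod(ph$grid$spacing)
  }
  vols <- vapply(c(0.5, 1.0, 1.5), function(a) {
    ph <- generate_phantom(tiny_entry(amplitude = a), 2)
    itv <- build_itv(lapply(0:7, function(p) phantom_mask(ph, "GTV", p)), 0.5)
    c(union = union_ptv(ph), itv = mask_volume_cc(itv),
      ptv0 = mask_volume_cc(expand_margin(phantom_mask(ph, "GTV", 0), 0.5)))
  }, numeric(3))
  # union of tracked per-phase PTVs is non-decreasing in amplitude and
  # equals the ITV (dilation commutes with union under rigid translation)
  expect_true(all(diff(vols["union", ]) > 0))
  expect_equal(vols["union", ], vols["itv", ], tolerance = 1e-9)
  # the per-phase tracked target stays constant, so the ITV - tracked gap grows
  gap <- vols["itv", ] - vols["ptv0", ]
  expect_true(all(diff(gap) > 0))
})
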