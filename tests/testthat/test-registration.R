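constant_field <- function(grid, t, phase = 1L) {
  vec <- array(0, dim = c(grid$shape, 3L))
  for (c in 1:3) vec[, , , c] <- t[c]
  deformation_field(vec, grid, phase)
}

test_that("identity field leaves masks and doses unchanged", {
  g <- small_grid(33)
  m <- sphere_mask(g, 1)
  z <- zero_field(g)
  expect_identical(propagate_mask(m, z)$voxels, m$voxels)
  d <- dose_grid(array(runif(prod(g$shape)), g$shape), g)
  expect_equal(warp_dose(d, z)$values, d$values)
})

test_that("integer-voxel translations shift masks exactly", {
  g <- small_grid(41)
  m <- sphere_mask(g, 1)
  f <- constant_field(g, c(0.5, 0, 0))  # 2 voxels along +x
  shifted <- propagate_mask(m, f)
  direct <- sphere_mask(g, 1, center = c(-0.5, 0, 0))
  expect_equal(dice(shifted, direct), 1.0)
})

test_that("sub-voxel translation round trips preserve the mask", {
  g <- small_grid(41)
  m <- sphere_mask(g, 1)
  f <- constant_field(g, c(0.075, 0, 0))   # 0.3 voxel
  back <- propagate_mask(propagate_mask(m, f),
                         constant_field(g, c(-0.075, 0, 0)))
  expect_gte(dice(back, m), 0.95)
  # rigid sub-voxel translation changes the volume by < 5%
  once <- propagate_mask(m, f)
  expect_lt(abs(mask_volume_cc(once) / mask_volume_cc(m) - 1), 0.05)
  # a half-voxel shift and its inverse compose to the identity field
  fh <- constant_field(g, c(0.125, 0, 0))
  fi <- constant_field(g, c(-0.125, 0, 0))
  comp <- compose_fields(fi, fh)
  expect_gte(dice(propagate_mask(m, comp), m), 0.999)
})

test_that("warping preserves constant doses and translates dose blobs", {
  e <- tiny_entry(amplitude = 1)
  ph <- generate_phantom(e, 2)
  g <- ph$grid
  f <- ground_truth_field(ph, 4)
  d <- dose_grid(array(10, g$shape), g)
  w <- warp_dose(d, f)
  interior <- array(FALSE, g$shape)
  interior[5:44, 5:44, 5:44] <- TRUE
  expect_lt(max(abs(w$values[interior] - 10)) / 10, 1e-6)

  # Gaussian blob under a constant translation: peak moves by -t
  co <- coords(g)
  t <- c(0.5, 0.25, -0.5)
  blob <- exp(-((co$x)^2 + (co$y)^2 + (co$z)^2) / (2 * 0.8^2))
  wb <- warp_dose(dose_grid(blob, g), constant_field(g, t))
  peak <- which(wb$values == max(wb$values), arr.ind = TRUE)[1, ]
  peak_world <- g$origin + (peak - 1) * g$spacing
  expect_lt(max(abs(peak_world - (-t))), max(g$spacing) / 2 + 1e-9)
  expect_lt(abs(max(wb$values) - max(blob)) / max(blob), 0.01)
})

test_that("field composition has the zero field as identity and adds translations", {
  g <- small_grid(33)
  f <- constant_field(g, c(0.3, -0.2, 0.1))
  z <- zero_field(g)
  expect_equal(compose_fields(f, z)$vectors, f$vectors)
  expect_equal(compose_fields(z, f)$vectors, f$vectors)

  f2 <- constant_field(g, c(-0.1, 0.4, 0.2))
  comp <- compose_fields(f2, f)
  interior <- array(FALSE, g$shape)
  interior[4:30, 4:30, 4:30] <- TRUE
  for (c in 1:3) {
    got <- comp$vectors[, , , c][interior]
    expect_lt(max(abs(got - (f$vectors[, , , c][interior] +
                               f2$vectors[1, 1, 1, c]))), 1e-12)
  }
})

test_that("cascading phase-to-phase fields matches the direct field", {
  e <- tiny_entry(amplitude = 1, n = 64)
  e$body <- c(7, 7)
  ph <- generate_phantom(e, 3)
  direct <- ground_truth_field(ph, 4)
  casc <- track4d:::.gt_field_between(ph, 0, 1)
  for (p in 2:4)
    casc <- compose_fields(track4d:::.gt_field_between(ph, p - 1, p), casc)
  expect_lt(max(abs(casc$vectors - direct$vectors)), max(ph$grid$spacing))
})

test_that("dice handles identical, disjoint and nested structures", {
  g <- small_grid(41)
  a <- sphere_mask(g, 1)
  expect_equal(dice(a, a), 1.0)
  b <- sphere_mask(g, 1, center = c(0, 0, 3))
  expect_equal(dice(a, b), 0.0)
  empty <- structure_mask("E", array(FALSE, g$shape), g)
  expect_equal(dice(empty, empty), 1.0)
  # nested spheres with volume ratio 2: dice = 2 V1 / (V1 + V2) = 2/3
  big <- sphere_mask(g, 2^(1 / 3))
  expect_equal(dice(a, big), 2 / 3, tolerance = 0.03)
})

test_that("lattice mismatches are rejected", {
  g1 <- small_grid(33)
  g2 <- small_grid(35)
  m1 <- sphere_mask(g1, 1)
  expect_error(propagate_mask(m1, zero_field(g2)), "lattice")
  expect_error(warp_dose(dose_grid(array(1, g1$shape), g1), zero_field(g2)),
               "lattice")
  expect_error(compose_fields(zero_field(g1), zero_field(g2)), "lattice")
  expect_error(dice(m1, sphere_mask(g2, 1)), "lattice")
})
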