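test_that("a static phantom has eight identical phases and is seed-reproducible", {
  e <- tiny_entry(amplitude = 0, oars = list(ESO = list(d_inh = 1, rom = 0)))
  ph <- generate_phantom(e, 5)
  expect_length(ph$phases, 8L)
  for (p in 2:8) {
    expect_identical(ph$phases[[p]]$density, ph$phases[[1]]$density)
    expect_identical(ph$phases[[p]]$masks$GTV$voxels,
                     ph$phases[[1]]$masks$GTV$voxels)
    expect_identical(ph$phases[[p]]$masks$ESO$voxels,
                     ph$phases[[1]]$masks$ESO$voxels)
  }
  ph2 <- generate_phantom(e, 5)
  expect_identical(ph$phases, ph2$phases)
  ph3 <- generate_phantom(e, 6)
  expect_false(identical(ph$phases[[1]]$density, ph3$phases[[1]]$density))
})

test_that("requested tumor amplitude is realized by the GTV centroids", {
  e <- tiny_entry(amplitude = 1.74, volume = 15.19)
  ph <- generate_phantom(e, 2)
  c0 <- mask_centroid(phantom_mask(ph, "GTV", 0))
  c4 <- mask_centroid(phantom_mask(ph, "GTV", 4))
  voxel_diag <- sqrt(sum(ph$grid$spacing^2))
  expect_lt(abs(sqrt(sum((c4 - c0)^2)) - 1.74), voxel_diag)
  # phase 0 is the reference: zero displacement by construction
  expect_equal(ph$motion$traj$GTV[1, ], c(0, 0, 0))
})

test_that("OAR placement reproduces requested d_inh and ROM", {
  e <- tiny_entry(amplitude = 0.25, volume = 21.33,
                  oars = list(ESO = list(d_inh = 1.1, rom = 0),
                              TRA = list(d_inh = 0.6, rom = 0.4)))
  ph <- generate_phantom(e, 3)
  tol <- 2 * max(ph$grid$spacing)
  for (nm in c("ESO", "TRA")) {
    rr <- rom(phantom_mask(ph, "GTV", 0), phantom_mask(ph, "GTV", 4),
              phantom_mask(ph, nm, 0), phantom_mask(ph, nm, 4))
    want <- e$oars[[nm]]
    expect_lt(abs(rr$d_inh - want$d_inh), tol)
    expect_lt(abs(rr$d_exh - (want$d_inh - want$rom)), tol)
    expect_lt(abs(rr$rom - want$rom), tol)
  }
})

test_that("structures that would leave the grid raise a named error", {
  e <- tiny_entry(amplitude = 4)
  e$tumor$center <- c(0, 0, 3)
  expect_error(generate_phantom(e, 1), "GTV.*phase")
})

test_that("mask volumes are stable across phases under rigid motion", {
  e <- tiny_entry(amplitude = 1.5,
                  oars = list(ESO = list(d_inh = 1, rom = 0.5),
                              HRT = list(d_inh = 0.5, rom = 0.4,
                                         semiaxes = c(1.5, 1.8, 2))))
  ph <- generate_phantom(e, 4)
  # closed 3D structures stay within 5% under sub-voxel rigid motion
  for (nm in c("GTV", "HRT")) {
    v <- vapply(0:7, function(p) mask_volume_cc(phantom_mask(ph, nm, p)),
                numeric(1))
    expect_lt(max(abs(v / v[1] - 1)), 0.05)
  }
  # infinite tubes rasterize as 2D disks, whose area quantization at
  # 0.25 cm is coarser; bounded but looser
  v <- vapply(0:7, function(p) mask_volume_cc(phantom_mask(ph, "ESO", p)),
              numeric(1))
  expect_lt(max(abs(v / v[1] - 1)), 0.15)
})

test_that("ground-truth fields are zero at phase 0 and rigid inside the envelope", {
  e <- tiny_entry(amplitude = 1)
  ph <- generate_phantom(e, 2)
  f0 <- ground_truth_field(ph, 0)
  expect_equal(max(abs(f0$vectors)), 0)
  expect_error(ground_truth_field(ph, 8), "phase")

  f4 <- ground_truth_field(ph, 4)
  gtv0 <- phantom_mask(ph, "GTV", 0)
  t4 <- ph$motion$traj$GTV[5, ]
  for (c in 1:3) {
    err <- abs(f4$vectors[, , , c][gtv0$voxels] - t4[c])
    expect_lt(max(err), 0.01)
  }
})

test_that("warping the exhale GTV through its field recovers the inhale GTV", {
  e <- tiny_entry(amplitude = 1.5, oars = list(ESO = list(d_inh = 1, rom = 0.5)))
  ph <- generate_phantom(e, 2)
  for (p in c(2L, 4L)) {
    f <- ground_truth_field(ph, p)
    back <- propagate_mask(phantom_mask(ph, "GTV", p), f)
    expect_gte(dice(back, phantom_mask(ph, "GTV", 0)), 0.95)
  }
})

test_that("breathing-trace generation is deterministic with controlled periods", {
  tr <- generate_breathing_trace(period_s = 5, variability = 0,
                                 duration_s = 60, sample_rate_hz = 25, seed = 1)
  segs <- segment_periods(tr)
  durs <- vapply(segs, `[[`, numeric(1), "duration_s")
  expect_true(all(abs(durs - 5) <= 1 / 25 + 1e-9))

  tr2 <- generate_breathing_trace(period_s = 5, variability = 0,
                                  duration_s = 60, sample_rate_hz = 25, seed = 1)
  expect_identical(tr$amplitudes, tr2$amplitudes)

  trv <- generate_breathing_trace(period_s = 5, variability = 0.2,
                                  duration_s = 60, sample_rate_hz = 25, seed = 3)
  dv <- vapply(segment_periods(trv), `[[`, numeric(1), "duration_s")
  expect_gt(stats::sd(dv), 0)
  expect_lt(abs(mean(dv) - 5) / 5, 0.10)

  expect_error(generate_breathing_trace(period_s = 5, duration_s = 8,
                                        sample_rate_hz = 25, seed = 1),
               "2 breathing periods")
})
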