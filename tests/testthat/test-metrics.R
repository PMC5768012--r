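test_that("DVH curves are exact for uniform doses and consistent for ramps", {
  g <- grid_spec(c(10, 10, 10), 0.25)
  vals <- array(10, g$shape)
  m <- structure_mask("T", array(TRUE, g$shape), g)
  curve <- dvh(dose_grid(vals, g), m)
  expect_equal(curve$volume_cc[1], 1000 * 0.015625)      # volume at 0 Gy
  expect_equal(curve$volume_cc[curve$dose_gy == 5], 15.625)
  expect_equal(curve$volume_cc[which(curve$dose_gy > 10)[1]], 0)
  expect_true(all(diff(curve$volume_cc) <= 0))

  # linear ramp covering 0-20 Gy: half the volume above 10 Gy
  ramp <- array(seq(0, 20, length.out = 1000), g$shape)
  cr <- dvh(dose_grid(ramp, g), m, bin_width_gy = 0.1)
  v10 <- cr$volume_cc[which.min(abs(cr$dose_gy - 10))]
  expect_equal(v10, 0.5 * 15.625, tolerance = 0.01)

  # Dmean equals the DVH integral within one bin width
  withr::with_seed(2, {
    rnd <- array(runif(1000, 0, 30), g$shape)
    crnd <- dvh(dose_grid(rnd, g), m, bin_width_gy = 0.1)
    expect_true(all(diff(crnd$volume_cc) <= 0))
    integral_mean <- sum(crnd$volume_cc) * 0.1 / crnd$volume_cc[1]
    expect_lt(abs(integral_mean - mean(rnd)), 0.1)
  })
  expect_error(dvh(dose_grid(vals, g),
                   structure_mask("E", array(FALSE, g$shape), g)), "empty")
})

test_that("TG-101 metrics compare against the built-in limits", {
  g <- grid_spec(c(20, 20, 20), 0.25)
  eso <- structure_mask("ESO", array(TRUE, g$shape), g)
  rep10 <- tg101_metrics(dose_grid(array(10, g$shape), g), list(ESO = eso))
  r <- rep10[rep10$oar == "ESO", ]
  expect_equal(r$value[r$metric == "V19.5Gy"], 0)
  expect_equal(r$value[r$metric == "Dmax"], 10)
  expect_true(all(r$pass[r$metric %in% c("V19.5Gy", "Dmax")]))

  rep40 <- tg101_metrics(dose_grid(array(40, g$shape), g), list(ESO = eso))
  r40 <- rep40[rep40$oar == "ESO", ]
  expect_false(r40$pass[r40$metric == "Dmax"])

  # heart: half of 20 cc at 40 Gy -> V32Gy = 10 cc, below the 15 cc limit
  nh <- 1280  # 20 cc at 0.015625 cc/voxel
  hv <- array(FALSE, g$shape)
  hv[seq_len(nh)] <- TRUE
  hrt <- structure_mask("HRT", hv, g)
  dv <- array(0, g$shape)
  dv[seq_len(nh / 2)] <- 40
  reph <- tg101_metrics(dose_grid(dv, g), list(HRT = hrt))
  rh <- reph[reph$oar == "HRT", ]
  expect_equal(rh$value[rh$metric == "V32Gy"], 10)
  expect_true(rh$pass[rh$metric == "V32Gy"])
  # missing OARs are flagged with NA, not dropped
  expect_true(all(is.na(reph$value[reph$oar == "SC"])))
})

test_that("signed distances match sphere geometry including overlap", {
  g <- grid_spec(c(41, 41, 61), 0.25)
  tol <- 2 * 0.25
  a <- sphere_mask(g, 1)
  b_far <- sphere_mask(g, 1, center = c(0, 0, 4))
  expect_lt(abs(signed_min_distance(a, b_far) - 2), tol)
  # symmetry for disjoint masks
  expect_equal(signed_min_distance(a, b_far), signed_min_distance(b_far, a))

  b_over <- sphere_mask(g, 1, center = c(0, 0, 1.5))
  expect_lt(abs(signed_min_distance(a, b_over) - (-0.5)), tol)
  # identical masks overlap fully: negative by convention
  expect_lt(signed_min_distance(a, a), 0)
  expect_error(signed_min_distance(a, structure_mask("E", array(FALSE, g$shape), g)),
               "empty")
})

test_that("relative organ motion follows the inhale/exhale distance change", {
  g <- grid_spec(c(41, 41, 61), 0.25)
  tol <- 2 * 0.25
  gtv0 <- sphere_mask(g, 1)
  oar <- sphere_mask(g, 1, center = c(0, 0, 4), name = "OAR")

  r_static <- rom(gtv0, gtv0, oar, oar)
  expect_equal(r_static$rom, 0)

  gtv50 <- sphere_mask(g, 1, center = c(0, 0, 1))  # 1 cm toward the OAR
  r_move <- rom(gtv0, gtv50, oar, oar)
  expect_lt(abs(r_move$d_inh - 2), tol)
  expect_lt(abs(r_move$d_exh - 1), tol)
  expect_lt(abs(r_move$rom - 1), tol)

  # co-moving GTV and OAR: no relative motion
  oar50 <- sphere_mask(g, 1, center = c(0, 0, 5), name = "OAR")
  r_co <- rom(gtv0, gtv50, oar, oar50)
  expect_lt(r_co$rom, tol)

  # whole-scene translation leaves ROM unchanged
  sh <- c(0.5, -0.25, 0.75)
  r_shift <- rom(sphere_mask(g, 1, center = sh),
                 sphere_mask(g, 1, center = c(0, 0, 1) + sh),
                 sphere_mask(g, 1, center = c(0, 0, 4) + sh, name = "OAR"),
                 sphere_mask(g, 1, center = c(0, 0, 4) + sh, name = "OAR"))
  expect_lt(abs(r_shift$rom - r_move$rom), tol)
})

test_that("sparing regression recovers a known slope and its significance", {
  withr::with_seed(10, {
    recs <- data.frame(rom = runif(30, 0, 1.5))
    recs$sparing <- 0.02 * recs$rom + rnorm(30, sd = 0.002)
    fit <- sparing_regression(recs)
    expect_gt(fit$slope, 0.015)
    expect_lt(fit$slope, 0.025)
    expect_lt(fit$p_value, 0.001)
    expect_equal(fit$n, 30)
  })
  # exactly collinear points: essentially zero residuals
  col <- data.frame(rom = c(0.1, 0.5, 1, 1.5), sparing = 0.03 * c(0.1, 0.5, 1, 1.5))
  fitc <- suppressWarnings(sparing_regression(col))
  expect_lt(max(abs(residuals(fitc$fit))), 1e-12)
  expect_lt(fitc$p_value, 1e-10)

  expect_error(sparing_regression(data.frame(rom = 1:2, sparing = 1:2)), "3")
  expect_error(sparing_regression(data.frame(rom = rep(1, 5),
                                             sparing = rnorm(5))), "variance")
})

test_that("slope recovery is nearly unbiased and type-I error is controlled", {
  n_seeds <- 200
  slopes <- numeric(n_seeds)
  pvals_null <- numeric(n_seeds)
  true_slope <- 0.02
  for (s in seq_len(n_seeds)) {
    withr::with_seed(1000 + s, {
      rom_v <- runif(30, 0, 1.5)
      y <- true_slope * rom_v + rnorm(30, sd = 0.1 * true_slope)
      slopes[s] <- sparing_regression(
        data.frame(rom = rom_v, sparing = y))$slope
      y0 <- rnorm(30, sd = 0.01)
      pvals_null[s] <- sparing_regression(
        data.frame(rom = rom_v, sparing = y0))$p_value
    })
  }
  expect_lt(abs(mean(slopes) - true_slope) / true_slope, 0.10)
  rej <- mean(pvals_null < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.10)
})

test_that("proximity profiles bin sparing by OAR distance", {
  recs <- data.frame(
    d_inh = c(-0.5, 0.4, 1.0, 1.7, 2.5, 4, 6),
    sparing = c(0.05, 0.04, 0.03, 0.02, 0.001, 0.0, -0.001))
  prof <- proximity_profile(recs)
  expect_true("overlap" %in% prof$bin)
  near <- prof$mean_sparing[prof$bin == "[0,1.5)"]
  far <- prof$mean_sparing[prof$bin == ">=2"]
  expect_gt(near, far)
  expect_lt(abs(far), 0.01)

  # empty bins are absent rather than zero
  recs2 <- data.frame(d_inh = c(3, 4, 5), sparing = c(0, 0, 0))
  prof2 <- proximity_profile(recs2)
  expect_false("overlap" %in% prof2$bin)
  expect_equal(nrow(prof2), 1L)
})

test_that("irradiated-volume reduction handles identity and degenerate cases", {
  g <- grid_spec(c(20, 20, 20), 0.25)
  body <- structure_mask("BODY", array(TRUE, g$shape), g)
  d <- dose_grid(array(30, g$shape), g)
  r <- irradiated_volume_reduction(d, d, body, 50)
  expect_equal(r$reduction_pct, 0)
  cold <- dose_grid(array(1, g$shape), g)
  expect_error(irradiated_volume_reduction(cold, cold, body, 50), "zero")
  expect_error(irradiated_volume_reduction(d, d, body, 50,
                                           threshold_fraction = 1.2))
})
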