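# Shared fixtures: all geometry is built in code at test time.

# Odd-sized grid puts a voxel center exactly at the world origin.
small_grid <- function(n = 49, spacing = 0.25) grid_spec(rep(n, 3L), spacing)

coords <- function(grid) track4d:::grid_coord_arrays(grid)

sphere_mask <- function(grid, r, center = c(0, 0, 0), name = "GTV") {
  co <- coords(grid)
  structure_mask(name,
                 (co$x - center[1])^2 + (co$y - center[2])^2 +
                   (co$z - center[3])^2 <= r^2, grid)
}

box_mask <- function(grid, half, center = c(0, 0, 0), name = "T") {
  co <- coords(grid)
  structure_mask(name,
                 abs(co$x - center[1]) <= half[1] &
                   abs(co$y - center[2]) <= half[2] &
                   abs(co$z - center[3]) <= half[3], grid)
}

cosine_trace <- function(period = 5, duration = 16, rate = 100, sign = 1) {
  t <- seq(0, duration, by = 1 / rate)
  breathing_trace(t, sign * cos(2 * pi * t / period))
}

# Time fraction a pure cosine spends with amplitude in [a, b] (arcsine law).
arcsine_level <- function(a, b) (asin(b) - asin(a)) / pi

# Noise-free cosine phase PDF from the arcsine closed form.
cosine_pdf_closed_form <- function() {
  lv <- c(arcsine_level(0.6, 1),        # phase 0%
          arcsine_level(0.2, 0.6) / 2,  # 12.5% (descending limb)
          arcsine_level(-0.2, 0.2) / 2, # 25%
          arcsine_level(-0.6, -0.2) / 2,# 37.5%
          arcsine_level(-1, -0.6),      # 50%
          arcsine_level(-0.6, -0.2) / 2,# 62.5%
          arcsine_level(-0.2, 0.2) / 2, # 75%
          arcsine_level(0.2, 0.6) / 2)  # 87.5%
  lv / sum(lv)
}

# Compact phantom entry fitting a 12 cm field of view.
tiny_entry <- function(name = "tiny", amplitude = 1, volume = 8,
                       oars = list(), lungs = FALSE, n = 48,
                       noise_sd = 0.02, direction = c(0, 0, 1),
                       prescription_gy = 50, fractions = 5) {
  phantom_entry(name = name, prescription_gy = prescription_gy,
                fractions = fractions,
                tumor = list(volume_cc = volume, amplitude_cm = amplitude,
                             direction = direction),
                oars = oars, body = c(5.2, 5.2), lungs = lungs,
                grid = list(shape = rep(n, 3L), spacing = 0.25),
                noise_sd = noise_sd)
}

uniform_pdf <- function() phase_pdf(rep(1 / 8, 8))

# Water slab on a fine lateral grid for dose-engine profile checks.
water_grid <- function(shape = c(41, 121, 41), spacing = c(0.25, 0.25, 0.25)) {
  grid_spec(shape, spacing)
}
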