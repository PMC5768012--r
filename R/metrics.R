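#' Cumulative dose-volume histogram
#'
#' Absolute cumulative DVH: for each dose edge, the structure volume (cc)
#' receiving at least that dose. The value at 0 Gy equals the structure
#' volume.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same lattice.
#' @param bin_width_gy uniform bin width in Gy (default 0.1).
#' @return A `dvh_curve`: list with `dose_gy` (edges) and `volume_cc`
#'   (non-increasing).
#' @export
dvh <- function(dose, mask, bin_width_gy = 0.1) {
  stop_if_lattice_mismatch(dose$grid, mask$grid)
  if (!any(mask$voxels)) stop("empty mask", call. = FALSE)
  d <- dose$values[mask$voxels]
  vv <- voxel_volume_cc(mask$grid)
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  counts <- vapply(edges, function(e) sum(d >= e), numeric(1))
  structure(list(dose_gy = edges, volume_cc = counts * vv,
                 structure = mask$name),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve '%s': volume %.2f cc, max dose %.2f Gy\n",
              x$structure, x$volume_cc[1], max(x$dose_gy)))
  invisible(x)
}

#' Volume (cc) receiving at least a dose
#' @param dose a [dose_grid()].
#' @param mask a [structure_mask()].
#' @param dose_gy threshold in Gy.
#' @export
volume_at_dose <- function(dose, mask, dose_gy) {
  stop_if_lattice_mismatch(dose$grid, mask$grid)
  sum(dose$values[mask$voxels] >= dose_gy) * voxel_volume_cc(mask$grid)
}

# AAPM TG-101-style SABR limits used for the OAR pass/fail table.
.tg101_limits <- function() {
  data.frame(
    oar = c("ESO", "ESO", "HRT", "HRT", "LNG", "LNG", "SC", "SC",
            "GRT", "GRT", "TRA", "TRA"),
    metric = c("V19.5Gy", "Dmax", "V32Gy", "Dmax", "V12.5Gy", "V13.5Gy",
               "V23Gy", "Dmax", "V47Gy", "Dmax", "V16.5Gy", "Dmax"),
    threshold_gy = c(19.5, NA, 32, NA, 12.5, 13.5, 23, NA, 47, NA, 16.5, NA),
    limit = c(5, 35, 15, 38, 1500, 1000, 0.35, 30, 10, 53, 4, 40),
    unit = c("cc", "Gy", "cc", "Gy", "cc", "cc", "cc", "Gy", "cc", "Gy",
             "cc", "Gy"),
    stringsAsFactors = FALSE)
}

#' TG-101 organ-at-risk metric table
#'
#' Computes the SABR-relevant dose metrics per OAR — volumes above the
#' organ-specific thresholds (Vx in cc), maximum single-voxel dose and mean
#' dose — and compares them against built-in TG-101 limits (esophagus
#' V19.5Gy < 5 cc, Dmax < 35 Gy; heart V32Gy < 15 cc, Dmax < 38 Gy; lungs
#' V12.5Gy < 1500 cc, V13.5Gy < 1000 cc; spinal canal V23Gy < 0.35 cc,
#' Dmax < 30 Gy; great vessels V47Gy < 10 cc, Dmax < 53 Gy;
#' trachea/bronchus V16.5Gy < 4 cc, Dmax < 40 Gy). OARs named in the limits
#' table but missing from `masks` are flagged with `NA` values.
#'
#' @param dose a [dose_grid()].
#' @param masks named list of [structure_mask()]s (subset of ESO, HRT, LNG,
#'   SC, GRT, TRA; other names are reported without limits).
#' @return A `tg101_report` data.frame: `oar`, `metric`, `value`, `limit`,
#'   `unit`, `pass`.
#' @export
tg101_metrics <- function(dose, masks) {
  lim <- .tg101_limits()
  rows <- NULL
  for (i in seq_len(nrow(lim))) {
    nm <- lim$oar[i]
    m <- masks[[nm]]
    if (is.null(m) || !any(m$voxels)) {
      rows <- rbind(rows, data.frame(oar = nm, metric = lim$metric[i],
                                     value = NA_real_, limit = lim$limit[i],
                                     unit = lim$unit[i], pass = NA))
      next
    }
    val <- if (is.na(lim$threshold_gy[i])) max(dose$values[m$voxels])
           else volume_at_dose(dose, m, lim$threshold_gy[i])
    rows <- rbind(rows, data.frame(oar = nm, metric = lim$metric[i],
                                   value = val, limit = lim$limit[i],
                                   unit = lim$unit[i],
                                   pass = val < lim$limit[i]))
  }
  # mean doses (reported, no TG-101 limit)
  for (nm in intersect(names(masks), unique(lim$oar))) {
    m <- masks[[nm]]
    if (is.null(m) || !any(m$voxels)) next
    rows <- rbind(rows, data.frame(oar = nm, metric = "Dmean",
                                   value = mean(dose$values[m$voxels]),
                                   limit = NA_real_, unit = "Gy", pass = NA))
  }
  class(rows) <- c("tg101_report", "data.frame")
  rows
}

# Interior 6-neighbour boundary voxels of a mask.
.mask_boundary <- function(vox) {
  n <- dim(vox)
  inner <- vox
  shift_all <- function(v) {
    acc <- array(TRUE, dim = n)
    pad <- function(a, axis, dir) {
      idx <- lapply(n, seq_len)
      src <- lapply(n, seq_len)
      if (dir > 0) { idx[[axis]] <- 2:n[axis]; src[[axis]] <- 1:(n[axis] - 1) }
      else { idx[[axis]] <- 1:(n[axis] - 1); src[[axis]] <- 2:n[axis] }
      out <- array(FALSE, dim = n)
      out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (axis in 1:3) for (dir in c(-1, 1)) acc <- acc & pad(v, axis, dir)
    acc
  }
  vox & !shift_all(vox)
}

#' Signed minimum distance between two structures
#'
#' Disjoint masks: the minimum Euclidean distance (cm) between them
#' (positive). Overlapping masks: negative, with magnitude the maximum
#' penetration depth — the largest distance from a boundary voxel of one
#' mask, lying inside the other, to the other's exterior. This is the
#' distance used for `d_inh` (GTV-OAR proximity at maximum inhale) and
#' `d_exh`; overlapping OARs get the negative values seen in clinical
#' proximity tables.
#'
#' @param a,b non-empty [structure_mask()]s on the same lattice.
#' @return signed distance in cm.
#' @export
signed_min_distance <- function(a, b) {
  stop_if_lattice_mismatch(a$grid, b$grid)
  if (!any(a$voxels) || !any(b$voxels)) stop("empty mask", call. = FALSE)
  inter <- a$voxels & b$voxels
  if (!any(inter)) {
    da <- distance_map(a)
    h <- mean(a$grid$spacing)
    # center-to-center minima overestimate the surface gap by about one
    # voxel (two ~h/3 surface offsets plus lateral quantization; measured
    # on random analytic sphere pairs); keep disjoint results positive
    return(max(min(da[b$voxels]) - h, h / 4))
  }
  depth_in_a <- distance_map(!a$voxels, a$grid)
  depth_in_b <- distance_map(!b$voxels, b$grid)
  ba <- .mask_boundary(b$voxels) & a$voxels
  bb <- .mask_boundary(a$voxels) & b$voxels
  pen <- max(if (any(ba)) max(depth_in_a[ba]) else 0,
             if (any(bb)) max(depth_in_b[bb]) else 0)
  if (pen == 0) pen <- min(a$grid$spacing)  # fully interior overlap
  -pen
}

#' Relative organ motion between maximum inhale and end exhale
#'
#' `ROM = |d_exh - d_inh|`, where `d_inh` is the signed minimum distance
#' between the GTV and the OAR at phase 0% (maximum inhale) and `d_exh` the
#' same at phase 50% (end exhale). Captures how much the OAR moves relative
#' to the tumor over the breathing cycle.
#'
#' @param gtv_phase0,gtv_phase50 GTV masks at phases 0% and 50%.
#' @param oar_phase0,oar_phase50 OAR masks at phases 0% and 50%.
#' @return A `rom_result`: list with `d_inh`, `d_exh`, `rom` (cm).
#' @export
rom <- function(gtv_phase0, gtv_phase50, oar_phase0, oar_phase50) {
  d_inh <- signed_min_distance(gtv_phase0, oar_phase0)
  d_exh <- signed_min_distance(gtv_phase50, oar_phase50)
  structure(list(d_inh = d_inh, d_exh = d_exh, rom = abs(d_exh - d_inh)),
            class = "rom_result")
}

#' Linear regression of mean-dose sparing on relative organ motion
#'
#' Ordinary least squares of `sparing` (mean-dose difference ITV minus
#' tracked, normalized to the prescription) on `rom`, with the two-sided
#' t-test p-value on the slope. A positive, significant slope indicates
#' that tracking benefits OARs more the more they move relative to the
#' tumor.
#'
#' @param records data.frame with columns `sparing` and `rom` (>= 3 rows,
#'   non-degenerate `rom`).
#' @return list: `slope`, `intercept`, `p_value`, `r_squared`, `n`, `fit`
#'   (the `lm` object).
#' @export
sparing_regression <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sparing", "rom") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (stats::var(records$rom) == 0)
    stop("ROM has zero variance", call. = FALSE)
  fit <- stats::lm(sparing ~ rom, data = records)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(s$coefficients["rom", "Pr(>|t|)"]),
       r_squared = s$r.squared, n = nrow(records), fit = fit)
}

#' Mean sparing binned by OAR-to-target proximity
#'
#' Bins the sparing records by `d_inh`: overlapping OARs (`d_inh < 0`) get
#' their own bin, then `[0, 1.5)`, `[1.5, 2)` and `[2, Inf)` cm by default.
#' Empty bins are absent from the result (not reported as zero).
#'
#' @param records data.frame with columns `sparing` and `d_inh`.
#' @param edges inner bin edges in cm (default `c(0, 1.5, 2)`).
#' @return data.frame: `bin`, `n`, `mean_sparing`.
#' @export
proximity_profile <- function(records, edges = c(0, 1.5, 2)) {
  stopifnot(is.data.frame(records),
            all(c("sparing", "d_inh") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  full <- c(-Inf, edges, Inf)
  labs <- c("overlap",
            paste0("[", full[2:(length(full) - 2)], ",",
                   full[3:(length(full) - 1)], ")"),
            paste0(">=", edges[length(edges)]))
  bin <- cut(records$d_inh, breaks = full, right = FALSE, labels = labs)
  agg <- stats::aggregate(records$sparing, list(bin = bin), mean, drop = TRUE)
  n <- as.integer(table(bin)[as.character(agg$bin)])
  data.frame(bin = as.character(agg$bin), n = n, mean_sparing = agg$x)
}

#' Irradiated-volume reduction of tracking versus ITV
#'
#' The irradiated volume is the BODY volume receiving at least
#' `threshold_fraction` of the prescription; the reduction is
#' `(V_ITV - V_tracked) / V_ITV * 100` percent.
#'
#' @param itv_dose,mrl_dose accumulated [dose_grid()]s of the two arms on
#'   the same lattice.
#' @param body the BODY [structure_mask()].
#' @param prescription_gy prescription dose in Gy.
#' @param threshold_fraction fraction of prescription (in (0,1), default
#'   0.5) defining "irradiated".
#' @return list: `v_itv_cc`, `v_mrl_cc`, `reduction_pct`.
#' @export
irradiated_volume_reduction <- function(itv_dose, mrl_dose, body,
                                        prescription_gy,
                                        threshold_fraction = 0.5) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  stop_if_lattice_mismatch(itv_dose$grid, mrl_dose$grid)
  thr <- threshold_fraction * prescription_gy
  v_itv <- volume_at_dose(itv_dose, body, thr)
  v_mrl <- volume_at_dose(mrl_dose, body, thr)
  if (v_itv == 0) stop("ITV irradiated volume is zero", call. = FALSE)
  list(v_itv_cc = v_itv, v_mrl_cc = v_mrl,
       reduction_pct = (v_itv - v_mrl) / v_itv * 100)
}
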