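# NIfTI image carrying the grid geometry (spacing + origin in the qform).
.as_nifti <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  m <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- grid$spacing
  img
}

.grid_from_nifti <- function(img) {
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  grid_spec(dim(img)[1:3], sp, origin = xf[1:3, 4])
}

#' Read/write dose grids, masks and fields as NIfTI
#'
#' Volumes are written with the grid spacing and origin in the qform (cm,
#' voxel-center convention). Deformation fields are 4D volumes with the
#' displacement components (cm) in the 4th dimension.
#'
#' @param dose,mask,field the object to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_dose_nifti <- function(dose, path) {
  RNifti::writeNifti(.as_nifti(dose$values, dose$grid), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_dose_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dose_grid(as.array(img), .grid_from_nifti(img))
}

#' @rdname nifti_io
#' @param name structure name to give the mask read back.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(.as_nifti(mask$voxels * 1L, mask$grid), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, name = "mask") {
  img <- RNifti::readNifti(path)
  structure_mask(name, as.array(img) > 0.5, .grid_from_nifti(img))
}

#' @rdname nifti_io
#' @param source_phase phase index to attach to a field read back.
#' @export
write_field_nifti <- function(field, path) {
  RNifti::writeNifti(.as_nifti(field$vectors, field$grid), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_field_nifti <- function(path, source_phase = NA_integer_) {
  img <- RNifti::readNifti(path)
  vec <- as.array(img)
  vec <- array(as.numeric(vec), dim = dim(vec))
  deformation_field(vec, .grid_from_nifti(img), source_phase)
}

#' Write a 4D phantom as per-phase NIfTI volumes
#'
#' One density volume and one mask volume per structure per phase, named
#' `phase<p>_density.nii.gz` and `phase<p>_<structure>.nii.gz`.
#'
#' @param phantom a `phantom4d`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- phase_labels()
  for (p in 1:8) {
    ph <- phantom$phases[[p]]
    RNifti::writeNifti(.as_nifti(ph$density, phantom$grid),
                       file.path(dir, sprintf("phase%02d_density.nii.gz", p - 1)))
    for (nm in names(ph$masks))
      write_mask_nifti(ph$masks[[nm]],
                       file.path(dir, sprintf("phase%02d_%s.nii.gz", p - 1, nm)))
  }
  invisible(dir)
}

#' Read/write breathing traces as 2-column CSV
#'
#' Columns `time_s` and `amplitude`.
#' @param trace a [breathing_trace()].
#' @param path CSV file path.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times,
                              amplitude = trace$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  breathing_trace(df[[1]], df[[2]])
}

#' Read/write phase PDFs
#'
#' CSV has columns `phase_pct` and `weight`; JSON is an object with the
#' phase labels as keys.
#' @param pdf a [phase_pdf()].
#' @param path file path.
#' @name pdf_io
NULL

#' @rdname pdf_io
#' @export
write_pdf_csv <- function(pdf, path) {
  utils::write.csv(data.frame(phase_pct = phase_labels(),
                              weight = as.numeric(pdf)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pdf_io
#' @export
read_pdf_csv <- function(path) {
  df <- utils::read.csv(path)
  phase_pdf(df$weight[order(df$phase_pct)])
}

#' @rdname pdf_io
#' @export
write_pdf_json <- function(pdf, path) {
  jsonlite::write_json(as.list(stats::setNames(as.numeric(pdf),
                                               paste0(phase_labels(), "%"))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a treatment plan to JSON
#'
#' Stores strategy, prescription, beam geometry (gantry angle, isocenter,
#' SAD, leaf width) and the per-phase leaf-row openings.
#'
#' @param plan a [treatment_plan()].
#' @param path JSON file path.
#' @name plan_io
NULL

.aperture_to_list <- function(ap) {
  list(leaf_width_cm = ap$leaf_width_cm,
       rows = lapply(seq_len(nrow(ap$rows)), function(i)
         list(k = ap$rows$k[i], left = ap$rows$left[i],
              right = ap$rows$right[i])))
}

.aperture_from_list <- function(l) {
  rows <- if (length(l$rows) == 0L)
    data.frame(k = integer(), left = numeric(), right = numeric())
  else do.call(rbind, lapply(l$rows, function(r)
    data.frame(k = as.integer(r$k), left = r$left, right = r$right)))
  aperture(rows, l$leaf_width_cm)
}

#' @rdname plan_io
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    strategy = plan$strategy,
    prescription_gy = plan$prescription_gy,
    fractions = plan$fractions,
    margin_cm = plan$margin_cm,
    beams = lapply(plan$beams, function(b)
      list(gantry_deg = b$gantry_deg, iso = b$iso, sad_cm = b$sad_cm,
           leaf_width_cm = b$leaf_width_cm)),
    apertures = lapply(plan$apertures, function(a) {
      if (inherits(a, "aperture")) .aperture_to_list(a)
      else lapply(a, .aperture_to_list)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname plan_io
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path)
  beams <- lapply(obj$beams, function(b)
    beam(b$gantry_deg, unlist(b$iso), b$sad_cm, b$leaf_width_cm))
  apertures <- lapply(obj$apertures, function(a) {
    if (!is.null(a$leaf_width_cm)) .aperture_from_list(a)
    else lapply(a, .aperture_from_list)
  })
  treatment_plan(obj$strategy, beams, apertures, obj$prescription_gy,
                 obj$fractions, obj$margin_cm)
}

#' Read a phantom cohort description from YAML
#'
#' The YAML file holds a list of phantom entries under `cohort:`, each with
#' the [phantom_entry()] fields (`name`, `prescription_gy`, `fractions`,
#' `tumor`, `oars`, `breathing`, ...).
#'
#' @param path YAML file path.
#' @return list of [phantom_entry()]s.
#' @export
read_cohort_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$cohort)) y$cohort else y
  lapply(entries, function(e) do.call(phantom_entry, e))
}

#' Write a cohort report as CSV + JSON
#'
#' Emits `records.csv` (per-OAR sparing records), `tg101.csv` (both arms'
#' metric tables with pass/fail), and `report.json` (regression, proximity
#' profile, irradiated-volume reductions).
#'
#' @param report a `cohort_report` from [run_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$records))
    utils::write.csv(report$records, file.path(dir, "records.csv"),
                     row.names = FALSE)
  tg <- NULL
  for (nm in names(report$entries)) {
    e <- report$entries[[nm]]
    for (arm in names(e$tg101)) {
      t <- e$tg101[[arm]]
      t$entry <- nm
      t$arm <- arm
      tg <- rbind(tg, t)
    }
  }
  if (!is.null(tg))
    utils::write.csv(tg, file.path(dir, "tg101.csv"), row.names = FALSE)
  summary <- list(
    seed = report$seed,
    failed = report$failed,
    regression = if (!is.null(report$regression))
      report$regression[c("slope", "intercept", "p_value", "r_squared", "n")],
    proximity = report$proximity,
    irradiated = lapply(report$entries, function(e)
      c(list(amplitude_cm = e$amplitude_cm), e$irradiated)))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
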