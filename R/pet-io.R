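#' SUV calibration metadata
#'
#' Describes how the stored voxel values relate to standardized uptake values
#' (SUV). When \code{input_units} is \code{"Bq_per_mL"}, voxels are activity
#' concentrations and are converted at ingest by
#' \code{SUV = concentration / (injected dose [Bq] / body weight [g])};
#' when it is \code{"SUV"} the data are taken as already calibrated.
#'
#' @param input_units \code{"SUV"} or \code{"Bq_per_mL"}.
#' @param injected_dose_MBq injected activity in MBq (required for
#'   \code{"Bq_per_mL"}). Typical dosing is 3 MBq of FET per kg body weight.
#' @param body_weight_kg body weight in kg (required for \code{"Bq_per_mL"}).
#' @return An object of class \code{calibration_info}.
#' @examples
#' calibration_info("Bq_per_mL", injected_dose_MBq = 210, body_weight_kg = 70)
#' @export
calibration_info <- function(input_units = c("SUV", "Bq_per_mL"),
                             injected_dose_MBq = NULL,
                             body_weight_kg = NULL) {
  input_units <- match.arg(input_units)
  if (input_units == "Bq_per_mL") {
    if (is.null(injected_dose_MBq) || is.null(body_weight_kg))
      stop("calibration error: injected_dose_MBq and body_weight_kg are ",
           "required when input_units is Bq_per_mL")
    if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
      stop("calibration error: injected_dose_MBq must be positive")
    if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
      stop("calibration error: body_weight_kg must be positive")
  }
  structure(list(input_units = input_units,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg),
            class = "calibration_info")
}

#' @rdname calibration_info
#' @param path JSON sidecar with fields \code{input_units},
#'   \code{injected_dose_MBq}, \code{body_weight_kg}.
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_info(input_units = x$input_units %||% "SUV",
                   injected_dose_MBq = x$injected_dose_MBq,
                   body_weight_kg = x$body_weight_kg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SUV scale factor: voxel / (dose_Bq / weight_g); identity for SUV input
suv_factor <- function(calibration) {
  if (calibration$input_units == "SUV") return(1)
  dose_bq <- calibration$injected_dose_MBq * 1e6
  weight_g <- calibration$body_weight_kg * 1e3
  1 / (dose_bq / weight_g)
}

#' Dynamic PET series container
#'
#' A 4D SUV image: \code{voxels[frame, z, y, x]} with voxel spacing in mm and
#' a \code{\link{frame_schema}}. All quantification in the package operates
#' on SUV; unit conversion happens only when reading data in.
#'
#' @param voxels 4D numeric array, dimension order (frame, z, y, x).
#' @param spacing_mm numeric length-3, (dz, dy, dx) in mm.
#' @param schema a \code{\link{frame_schema}} whose length matches
#'   \code{dim(voxels)[1]}.
#' @param calibration a \code{\link{calibration_info}} (recorded provenance;
#'   voxels are already SUV).
#' @return An object of class \code{dynamic_pet_series}.
#' @export
dynamic_pet_series <- function(voxels, spacing_mm, schema,
                               calibration = calibration_info("SUV")) {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4D (frame, z, y, x) array")
  if (dim(voxels)[1L] != nrow(schema))
    stop(sprintf("frame-count mismatch: image has %d frames, schema has %d",
                 dim(voxels)[1L], nrow(schema)))
  check_spacing(spacing_mm)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("all SUV values must be finite and >= 0")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 schema = schema, calibration = calibration),
            class = "dynamic_pet_series")
}

check_spacing <- function(spacing_mm) {
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be three positive values (dz, dy, dx)")
  invisible(spacing_mm)
}

#' 3D SUV image
#'
#' @param voxels 3D numeric array (z, y, x) of SUV.
#' @param spacing_mm (dz, dy, dx) in mm.
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D (z, y, x) array")
  check_spacing(spacing_mm)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("all SUV values must be finite and >= 0")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm)),
            class = "volume_image")
}

#' Boolean region mask on a voxel grid
#'
#' @param voxels 3D logical array (z, y, x).
#' @param spacing_mm (dz, dy, dx) in mm.
#' @return An object of class \code{region_mask}.
#' @export
region_mask <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3L) stop("mask must be a 3D (z, y, x) array")
  check_spacing(spacing_mm)
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm)),
            class = "region_mask")
}

# grids must agree voxel-for-voxel; no resampling is ever performed
check_same_grid <- function(a_dim, a_sp, b_dim, b_sp, what = "mask") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("grid mismatch: %s shape (%s) vs image shape (%s)",
                 what, paste(b_dim, collapse = "x"),
                 paste(a_dim, collapse = "x")))
  if (max(abs(a_sp - b_sp)) > 1e-6)
    stop(sprintf("grid mismatch: %s spacing (%s) vs image spacing (%s) mm",
                 what, paste(signif(b_sp, 6), collapse = ", "),
                 paste(signif(a_sp, 6), collapse = ", ")))
  invisible(TRUE)
}

# NIfTI stores (x, y, z[, t]); internally we use (frame, z, y, x).
nifti_to_internal_4d <- function(arr) aperm(arr, c(4L, 3L, 2L, 1L))
nifti_to_internal_3d <- function(arr) aperm(arr, c(3L, 2L, 1L))
internal_to_nifti_4d <- function(arr) aperm(arr, c(4L, 3L, 2L, 1L))
internal_to_nifti_3d <- function(arr) aperm(arr, c(3L, 2L, 1L))

#' Read a dynamic PET series from NIfTI
#'
#' Reads a 4D NIfTI volume and a frame-timing CSV, applies SUV calibration if
#' the stored values are activity concentrations, and returns a
#' \code{\link{dynamic_pet_series}}.
#'
#' @param image_path 4D NIfTI file (.nii/.nii.gz).
#' @param frame_table_path frame-timing CSV (see
#'   \code{\link{read_frame_table}}).
#' @param calibration a \code{\link{calibration_info}}.
#' @return A \code{\link{dynamic_pet_series}} in SUV units.
#' @export
read_dynamic_series <- function(image_path, frame_table_path,
                                calibration = calibration_info("SUV")) {
  nii <- RNifti::readNifti(image_path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI image, got ", length(dim(arr)), " dimensions: ",
         image_path)
  schema <- read_frame_table(frame_table_path)
  if (dim(arr)[4L] != nrow(schema))
    stop(sprintf(
      "frame-count mismatch: image has %d frames but frame table has %d rows",
      dim(arr)[4L], nrow(schema)))
  sp <- rev(RNifti::pixdim(nii)[1:3])  # (dx,dy,dz) -> (dz,dy,dx)
  vox <- nifti_to_internal_4d(arr) * suv_factor(calibration)
  dynamic_pet_series(vox, sp, schema, calibration)
}

#' @rdname read_dynamic_series
#' @param series a \code{dynamic_pet_series} to write.
#' @param path output NIfTI path; the schema is written alongside as
#'   \code{<path>.frames.csv} unless \code{frame_table_path} is given.
#' @export
write_dynamic_series <- function(series, path, frame_table_path = NULL) {
  arr <- internal_to_nifti_4d(series$voxels)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(rev(series$spacing_mm), 1)
  RNifti::writeNifti(nii, path)
  if (is.null(frame_table_path)) frame_table_path <- paste0(path, ".frames.csv")
  write_frame_table(series$schema, frame_table_path)
  invisible(path)
}

#' Read a region mask congruent with a reference series
#'
#' Nonzero voxels become TRUE. The mask grid (shape and spacing) must match
#' the reference exactly; no resampling is performed.
#'
#' @param path 3D NIfTI file.
#' @param reference a \code{\link{dynamic_pet_series}} or
#'   \code{\link{volume_image}} defining the expected grid.
#' @return A \code{\link{region_mask}}.
#' @export
read_mask <- function(path, reference) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI mask, got ", length(dim(arr)),
         " dimensions: ", path)
  ref_dim <- spatial_dim(reference)
  sp <- rev(RNifti::pixdim(nii)[1:3])
  vox <- nifti_to_internal_3d(arr) != 0
  check_same_grid(ref_dim, reference$spacing_mm, dim(vox), sp, "mask")
  region_mask(vox, reference$spacing_mm)
}

#' @rdname read_mask
#' @param mask a \code{region_mask} to write.
#' @export
write_mask <- function(mask, path) {
  arr <- internal_to_nifti_3d(array(as.integer(mask$voxels),
                                    dim = dim(mask$voxels)))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- rev(mask$spacing_mm)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

spatial_dim <- function(x) {
  if (inherits(x, "dynamic_pet_series")) dim(x$voxels)[-1L] else dim(x$voxels)
}

#' Read a patient cohort table
#'
#' Reads and validates a cohort CSV with survival endpoints, molecular and
#' clinical covariates and (optionally) the five PET parameters. Expected
#' columns: \code{patient_id, os_months, os_event, pfs_months, pfs_event,
#' idh, mgmt, kps, resection, age_years, who_grade} and optionally
#' \code{tbr_max, tbr_mean, mtv_ml, ttp_min, slope_suv_per_h}.
#'
#' @param path cohort CSV path.
#' @return A validated data frame of class \code{pet_cohort}, one row per
#'   patient.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tab, src = path)
}

#' @rdname read_cohort
#' @param cohort a data frame to validate (or write).
#' @param src label used in error messages.
#' @export
validate_cohort <- function(cohort, src = "cohort") {
  if (nrow(cohort) == 0L) stop("no records in ", src)
  need <- c("patient_id", "os_months", "os_event", "pfs_months", "pfs_event",
            "idh", "mgmt", "kps", "resection", "age_years", "who_grade")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("missing cohort columns: ", paste(miss, collapse = ", "))
  levels_ok <- list(idh = c("mutant", "wildtype"),
                    mgmt = c("methylated", "unmethylated"),
                    resection = c("biopsy", "partial", "complete"),
                    who_grade = c("III", "IV"))
  for (i in seq_len(nrow(cohort))) {
    row_err <- function(msg) stop(sprintf("%s row %d: %s", src, i, msg))
    if (!is.finite(cohort$os_months[i]) || cohort$os_months[i] < 0)
      row_err("os_months must be a non-negative number")
    if (!is.finite(cohort$pfs_months[i]) || cohort$pfs_months[i] < 0)
      row_err("pfs_months must be a non-negative number")
    if (cohort$pfs_months[i] > cohort$os_months[i] + 1e-9)
      row_err("pfs_months may not exceed os_months")
    if (!cohort$os_event[i] %in% c(0, 1))
      row_err("os_event must be 0 (censored) or 1 (death)")
    if (!cohort$pfs_event[i] %in% c(0, 1))
      row_err("pfs_event must be 0 or 1")
    if (!is.finite(cohort$kps[i]) || cohort$kps[i] < 0 || cohort$kps[i] > 100)
      row_err("kps must be in [0, 100]")
    for (v in names(levels_ok))
      if (!cohort[[v]][i] %in% levels_ok[[v]])
        row_err(sprintf("unknown %s level '%s' (allowed: %s)", v,
                        cohort[[v]][i], paste(levels_ok[[v]], collapse = ", ")))
  }
  class(cohort) <- c("pet_cohort", "data.frame")
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dynamic_pet_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Dynamic PET series: %d frames, %dx%dx%d voxels (z,y,x), %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  cat(sprintf("  acquisition 0-%g min, SUV range %.3g-%.3g\n",
              max(x$schema$end_s) / 60, min(x$voxels), max(x$voxels)))
  invisible(x)
}
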