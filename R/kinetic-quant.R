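#' Extract a time-activity curve with a spherical VOI
#'
#' Computes the frame-wise mean SUV over a spherical volume of interest
#' (default 2 mL, radius about 7.82 mm) centred on a voxel — conventionally
#' the maximum-uptake voxel of the 20-40 min summed image. Voxel membership
#' is by centre-in-sphere using physical distances; parts of the sphere
#' outside the field of view are clipped.
#'
#' @param series a \code{\link{dynamic_pet_series}}.
#' @param centre_voxel (z, y, x) index of the VOI centre.
#' @param voi_volume_ml VOI volume in mL (default 2).
#' @return An object of class \code{time_activity_curve}: a data frame with
#'   \code{frame_index}, \code{start_s}, \code{end_s}, \code{mid_min},
#'   \code{end_min}, \code{mean_suv}.
#' @export
extract_tac <- function(series, centre_voxel, voi_volume_ml = 2) {
  r <- (3 * voi_volume_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  sp <- series$spacing_mm
  d <- dim(series$voxels)[-1L]
  nz <- floor(r / sp[1L]); ny <- floor(r / sp[2L]); nx <- floor(r / sp[3L])
  off <- expand.grid(oz = -nz:nz, oy = -ny:ny, ox = -nx:nx)
  off <- off[(off$oz * sp[1L])^2 + (off$oy * sp[2L])^2 +
               (off$ox * sp[3L])^2 <= r^2 + 1e-9, ]
  zz <- centre_voxel[1L] + off$oz
  yy <- centre_voxel[2L] + off$oy
  xx <- centre_voxel[3L] + off$ox
  keep <- zz >= 1L & zz <= d[1L] & yy >= 1L & yy <= d[2L] &
    xx >= 1L & xx <= d[3L]
  if (!any(keep)) stop("VOI sphere lies fully outside the image")
  idx <- cbind(zz[keep], yy[keep], xx[keep])
  nfr <- nrow(series$schema)
  means <- vapply(seq_len(nfr), function(f) {
    mean(series$voxels[f, , , ][idx])
  }, numeric(1))
  time_activity_curve(series$schema, means)
}

#' Construct a time-activity curve from a schema and frame means
#'
#' @param schema a \code{\link{frame_schema}}.
#' @param mean_suv frame-wise mean SUV, same length as the schema.
#' @return A \code{time_activity_curve} data frame.
#' @export
time_activity_curve <- function(schema, mean_suv) {
  if (length(mean_suv) != nrow(schema))
    stop("mean_suv length must equal the number of frames")
  if (!all(is.finite(mean_suv)) || any(mean_suv < 0))
    stop("mean_suv must be finite and >= 0")
  out <- data.frame(frame_index = schema$frame_index,
                    start_s = schema$start_s, end_s = schema$end_s,
                    mid_min = frame_mid_min(schema),
                    end_min = frame_end_min(schema),
                    mean_suv = as.numeric(mean_suv))
  class(out) <- c("time_activity_curve", "data.frame")
  out
}

#' Time-to-peak of a time-activity curve
#'
#' TTP is the elapsed time from the start of the dynamic acquisition through
#' the frame with the maximum mean SUV, i.e. that frame's end time. When the
#' earliest maximum falls in the final frame — a steadily increasing curve
#' with no identifiable peak — \code{peak_identified} is FALSE and TTP is the
#' acquisition end (50 min on the default schema). Ties at the maximum take
#' the earlier frame.
#'
#' @param tac a \code{\link{time_activity_curve}}.
#' @param use_mid_time use frame mid times instead of end times (sensitivity
#'   analysis; default FALSE).
#' @return A list with \code{ttp_min} (minutes) and \code{peak_identified}.
#' @export
compute_ttp <- function(tac, use_mid_time = FALSE) {
  if (nrow(tac) < 2L) stop("TTP needs at least 2 frames")
  k <- which.max(tac$mean_suv)  # earliest frame attaining the global max
  if (all(tac$mean_suv == tac$mean_suv[1L]))
    warning("constant TAC: TTP set to the first frame's end time")
  tvec <- if (use_mid_time) tac$mid_min else tac$end_min
  if (k == nrow(tac))
    list(ttp_min = tac$end_min[nrow(tac)], peak_identified = FALSE)
  else
    list(ttp_min = tvec[k], peak_identified = TRUE)
}

#' Late-phase slope of a time-activity curve
#'
#' Ordinary least-squares slope of mean SUV against frame mid time over the
#' frames whose mid time falls inside the late-phase window (default
#' 20-50 min post-injection), expressed as SUV change per hour.
#'
#' @param tac a \code{\link{time_activity_curve}}.
#' @param window_min (start, end) of the late phase in minutes.
#' @return Slope in SUV/h.
#' @export
compute_slope <- function(tac, window_min = c(20, 50)) {
  sel <- tac$mid_min >= window_min[1] & tac$mid_min <= window_min[2]
  if (sum(sel) < 2L)
    stop("slope needs at least 2 frames with mid time inside [",
         window_min[1], ", ", window_min[2], "] min; found ", sum(sel))
  fit <- stats::lm(mean_suv ~ mid_min, data = tac[sel, ])
  unname(stats::coef(fit)[2L]) * 60
}

#' Full static + kinetic quantification of one dynamic PET study
#'
#' Runs the complete per-patient quantification: summed 20-40 min image,
#' reference statistics, maximum-uptake voxel, TBR_max, 2D auto-contour
#' (TBR_mean), 3D auto-contour (MTV), 2 mL-VOI time-activity curve, TTP and
#' late-phase slope. A reference TAC over the reference mask is extracted and
#' returned for inspection; it enters no derived parameter.
#'
#' @param series a \code{\link{dynamic_pet_series}}.
#' @param ref_mask a non-empty \code{\link{region_mask}} over healthy brain.
#' @param config a \code{\link{pipeline_config}} supplying the analysis
#'   constants.
#' @return A list of class \code{patient_quantification} with elements
#'   \code{static} (\code{\link{static_params}}), \code{kinetic}
#'   (\code{ttp_min}, \code{slope_suv_per_h}, \code{peak_identified}),
#'   \code{tac}, and \code{reference_tac}.
#' @export
quantify_patient <- function(series, ref_mask, config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(config$smoothing_fwhm_mm) && config$smoothing_fwhm_mm > 0)
    series <- smooth_series(series, config$smoothing_fwhm_mm)
  image <- stage("sum_frames", sum_frames(series, config$summed_window_min))
  st <- stage("static_quant",
              static_params(image, ref_mask,
                            tbr_threshold = config$tbr_threshold,
                            roi_diameter_mm = config$roi_diameter_mm))
  tac <- stage("extract_tac",
               extract_tac(series, st$max_voxel, config$voi_volume_ml))
  ttp <- stage("compute_ttp", compute_ttp(tac, config$ttp_use_mid_time))
  slope <- stage("compute_slope", compute_slope(tac, config$slope_window_min))
  ref_tac <- stage("reference_tac", mask_tac(series, ref_mask))
  structure(list(
    static = st,
    kinetic = list(ttp_min = ttp$ttp_min, slope_suv_per_h = slope,
                   peak_identified = ttp$peak_identified),
    tac = tac, reference_tac = ref_tac
  ), class = "patient_quantification")
}

# frame-wise mean SUV over an arbitrary mask (used for the reference TAC)
mask_tac <- function(series, mask) {
  sel <- mask$voxels
  means <- vapply(seq_len(nrow(series$schema)), function(f) {
    mean(series$voxels[f, , , ][sel])
  }, numeric(1))
  time_activity_curve(series$schema, means)
}

#' Optional isotropic Gaussian pre-smoothing of a dynamic series
#'
#' Separable Gaussian filter applied frame by frame, parameterized by full
#' width at half maximum in mm. Off by default in the pipeline; intended for
#' cross-scanner harmonization experiments.
#'
#' @param series a \code{\link{dynamic_pet_series}}.
#' @param fwhm_mm kernel FWHM in mm.
#' @return The smoothed series.
#' @export
smooth_series <- function(series, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vox <- series$voxels
  for (f in seq_len(dim(vox)[1L]))
    vox[f, , , ] <- gauss3d(vox[f, , , ], sigma_mm / series$spacing_mm)
  dynamic_pet_series(vox, series$spacing_mm, series$schema,
                     series$calibration)
}

# separable 1D Gaussian convolution along each axis, reflecting boundaries
gauss3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    arr <- apply_along(arr, ax, function(v) {
      n <- length(v)
      pad <- c(v[half:1], v, v[n:(n - half + 1L)])
      stats::convolve(pad, rev(k), type = "filter")
    })
  }
  arr
}

apply_along <- function(arr, ax, fun) {
  out <- apply(arr, setdiff(1:3, ax), fun)
  # apply() puts the function axis first; permute back
  perm <- order(c(ax, setdiff(1:3, ax)))
  aperm(out, perm)
}

#' @export
print.patient_quantification <- function(x, ...) {
  print(x$static)
  cat("Kinetic FET PET parameters\n")
  cat(sprintf("  TTP   %.1f min (%s)\n  slope %.4f SUV/h\n",
              x$kinetic$ttp_min,
              if (x$kinetic$peak_identified) "peak identified"
              else "no identifiable peak; acquisition end used",
              x$kinetic$slope_suv_per_h))
  invisible(x)
}

#' Export a time-activity curve (tumour and reference) as CSV
#'
#' @param tac tumour \code{\link{time_activity_curve}}.
#' @param path output CSV.
#' @param reference_tac optional reference-region TAC on the same schema.
#' @export
write_tac <- function(tac, path, reference_tac = NULL) {
  out <- data.frame(frame_index = tac$frame_index, start_s = tac$start_s,
                    end_s = tac$end_s, mid_min = tac$mid_min,
                    tumour_mean_suv = tac$mean_suv)
  if (!is.null(reference_tac))
    out$reference_mean_suv <- reference_tac$mean_suv
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
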