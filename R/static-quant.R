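#' Duration-weighted summed image over an acquisition window
#'
#' Averages the frames that fall fully inside \code{window_min} (default the
#' standard 20-40 min evaluation window), weighting each frame by its
#' duration. The window must coincide with frame boundaries of the schema.
#'
#' @param series a \code{\link{dynamic_pet_series}}.
#' @param window_min (start, end) in minutes post-injection.
#' @return A \code{\link{volume_image}} of mean SUV over the window.
#' @export
sum_frames <- function(series, window_min = c(20, 40)) {
  bnd_min <- c(series$schema$start_s, max(series$schema$end_s)) / 60
  if (!all(window_min %in% bnd_min))
    stop("window (", paste(window_min, collapse = "-"),
         " min) must align with frame boundaries; available boundaries: ",
         paste(bnd_min, collapse = ", "), " min")
  inside <- series$schema$start_s / 60 >= window_min[1] &
    series$schema$end_s / 60 <= window_min[2]
  if (!any(inside)) stop("no frames inside window")
  w <- (series$schema$end_s - series$schema$start_s)[inside]
  w <- w / sum(w)
  idx <- which(inside)
  out <- array(0, dim = dim(series$voxels)[-1L])
  for (k in seq_along(idx)) out <- out + w[k] * series$voxels[idx[k], , , ]
  volume_image(out, series$spacing_mm)
}

#' Healthy-brain reference statistics
#'
#' Mean SUV over a reference region (in practice a crescent-shaped ROI in the
#' centrum semiovale of the unaffected hemisphere, supplied as a mask). This
#' mean is the denominator of every tumour-to-brain ratio.
#'
#' @param image a \code{\link{volume_image}}.
#' @param ref_mask a non-empty \code{\link{region_mask}} on the same grid.
#' @return A list with \code{mean_suv} and \code{voxel_count}
#'   (class \code{reference_stats}).
#' @export
reference_stats <- function(image, ref_mask) {
  check_same_grid(dim(image$voxels), image$spacing_mm,
                  dim(ref_mask$voxels), ref_mask$spacing_mm, "reference mask")
  n <- sum(ref_mask$voxels)
  if (n == 0L) stop("reference mask is empty")
  m <- mean(image$voxels[ref_mask$voxels])
  if (m <= 0)
    stop("reference mean SUV is ", m,
         "; a positive reference mean is required for TBR computation")
  structure(list(mean_suv = m, voxel_count = n), class = "reference_stats")
}

#' Locate the maximum-uptake voxel
#'
#' @param image a \code{\link{volume_image}}.
#' @param search_mask optional \code{\link{region_mask}} restricting the
#'   search (whole field of view if NULL).
#' @return Integer (z, y, x) index of the maximum SUV voxel; ties are broken
#'   toward the lowest (z, y, x) lexicographic index.
#' @export
find_max_voxel <- function(image, search_mask = NULL) {
  vox <- image$voxels
  if (!is.null(search_mask)) {
    check_same_grid(dim(vox), image$spacing_mm,
                    dim(search_mask$voxels), search_mask$spacing_mm,
                    "search mask")
    if (!any(search_mask$voxels)) stop("search mask is empty")
    vox <- ifelse(search_mask$voxels, vox, -Inf)
  }
  mx <- max(vox)
  cand <- which(vox == mx, arr.ind = TRUE)  # cols: z, y, x
  # column-major which() is (z, y, x)-fastest-first; re-rank lexicographically
  o <- order(cand[, 1L], cand[, 2L], cand[, 3L])
  as.integer(cand[o[1L], ])
}

# voxel offsets of the in-plane disc: centre distance <= radius
disc_offsets <- function(radius_mm, dy, dx) {
  ny <- floor(radius_mm / dy); nx <- floor(radius_mm / dx)
  off <- expand.grid(oy = -ny:ny, ox = -nx:nx)
  off[(off$oy * dy)^2 + (off$ox * dx)^2 <= radius_mm^2 + 1e-9, ]
}

#' Maximum tumour-to-brain ratio
#'
#' Mean SUV over a circular in-plane ROI (default diameter 1.6 cm) centred on
#' the maximum-uptake voxel, divided by the healthy-brain reference mean.
#' The disc lives in the transversal slice of the max voxel; voxel membership
#' is by centre-in-disc using physical in-plane distances.
#'
#' @param image a \code{\link{volume_image}}.
#' @param ref a \code{\link{reference_stats}}.
#' @param max_voxel (z, y, x) index from \code{\link{find_max_voxel}}.
#' @param roi_diameter_mm ROI diameter in mm (default 16).
#' @return TBR_max, a unitless ratio.
#' @export
tbr_max <- function(image, ref, max_voxel, roi_diameter_mm = 16) {
  stopifnot(ref$mean_suv > 0)
  d <- dim(image$voxels)
  off <- disc_offsets(roi_diameter_mm / 2,
                      image$spacing_mm[2L], image$spacing_mm[3L])
  yy <- max_voxel[2L] + off$oy
  xx <- max_voxel[3L] + off$ox
  keep <- yy >= 1L & yy <= d[2L] & xx >= 1L & xx <= d[3L]
  if (!all(keep))
    warning("TBR_max ROI extends beyond image bounds; clipped to the image")
  vals <- image$voxels[cbind(max_voxel[1L], yy[keep], xx[keep])]
  mean(vals) / ref$mean_suv
}

# Seeded connected component by iterative dilation on a logical array.
# connectivity: face neighbours in-plane (4-conn, 2D) or in 3D (6-conn).
seeded_component <- function(above, seed, three_d = TRUE) {
  d <- dim(above)
  comp <- array(FALSE, dim = d)
  comp[seed[1L], seed[2L], seed[3L]] <- TRUE
  shift <- function(m, dz, dy, dx) {
    out <- array(FALSE, dim = d)
    zs <- seq_len(d[1L]) - dz; ys <- seq_len(d[2L]) - dy
    xs <- seq_len(d[3L]) - dx
    okz <- zs >= 1L & zs <= d[1L]; oky <- ys >= 1L & ys <= d[2L]
    okx <- xs >= 1L & xs <= d[3L]
    out[okz, oky, okx] <- m[zs[okz], ys[oky], xs[okx]]
    out
  }
  steps <- list(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0))
  if (three_d) steps <- c(steps, list(c(1, 0, 0), c(-1, 0, 0)))
  repeat {
    grown <- comp
    for (s in steps) grown <- grown | shift(comp, s[1L], s[2L], s[3L])
    grown <- grown & above
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' 2D threshold auto-contour and mean tumour-to-brain ratio
#'
#' In the transversal slice containing the maximum-uptake voxel, delineates
#' the 4-connected component of voxels with SUV at or above
#' \code{tbr_threshold} times the reference mean that contains the max voxel.
#' TBR_mean is the mean SUV of that component divided by the reference mean.
#'
#' @inheritParams tbr_max
#' @param tbr_threshold tumour-to-brain ratio threshold (default 1.6).
#' @return A list with \code{mask} (a \code{\link{region_mask}}, nonzero only
#'   in the max slice), \code{tbr_mean}, and \code{tumour_detected}. When the
#'   max voxel itself is below threshold, \code{tumour_detected} is FALSE and
#'   \code{mask}/\code{tbr_mean} are NULL/NA.
#' @export
autocontour_2d <- function(image, ref, max_voxel, tbr_threshold = 1.6) {
  stopifnot(ref$mean_suv > 0)
  thr <- tbr_threshold * ref$mean_suv
  if (image$voxels[max_voxel[1L], max_voxel[2L], max_voxel[3L]] < thr)
    return(list(mask = NULL, tbr_mean = NA_real_, tumour_detected = FALSE))
  above <- array(FALSE, dim = dim(image$voxels))
  z <- max_voxel[1L]
  above[z, , ] <- image$voxels[z, , ] >= thr
  comp <- seeded_component(above, max_voxel, three_d = FALSE)
  list(mask = region_mask(comp, image$spacing_mm),
       tbr_mean = mean(image$voxels[comp]) / ref$mean_suv,
       tumour_detected = TRUE)
}

#' 3D threshold auto-contour and metabolic tumour volume
#'
#' Delineates the 6-connected 3D component of voxels with SUV at or above
#' \code{tbr_threshold} times the reference mean that contains the
#' maximum-uptake voxel; the metabolic tumour volume (MTV) is its voxel count
#' times the voxel volume, in mL.
#'
#' @inheritParams autocontour_2d
#' @return A list with \code{mask}, \code{mtv_ml}, and
#'   \code{tumour_detected}; \code{mtv_ml} is 0 when no tumour is detected.
#' @export
mtv_3d <- function(image, ref, max_voxel, tbr_threshold = 1.6) {
  stopifnot(ref$mean_suv > 0)
  thr <- tbr_threshold * ref$mean_suv
  if (image$voxels[max_voxel[1L], max_voxel[2L], max_voxel[3L]] < thr)
    return(list(mask = NULL, mtv_ml = 0, tumour_detected = FALSE))
  above <- image$voxels >= thr
  comp <- seeded_component(above, max_voxel, three_d = TRUE)
  vol_ml <- sum(comp) * prod(image$spacing_mm) / 1000
  list(mask = region_mask(comp, image$spacing_mm),
       mtv_ml = vol_ml, tumour_detected = TRUE)
}

#' Static PET parameters for one study
#'
#' Convenience wrapper: computes the summed-image static parameters TBR_max,
#' TBR_mean and MTV from an evaluation image and a reference mask.
#'
#' @inheritParams reference_stats
#' @param tbr_threshold contour threshold (default 1.6).
#' @param roi_diameter_mm TBR_max ROI diameter in mm (default 16).
#' @return A list of class \code{static_params}: \code{tbr_max},
#'   \code{tbr_mean}, \code{mtv_ml}, \code{max_voxel},
#'   \code{tumour_detected}.
#' @export
static_params <- function(image, ref_mask, tbr_threshold = 1.6,
                          roi_diameter_mm = 16) {
  ref <- reference_stats(image, ref_mask)
  mv <- find_max_voxel(image)
  ac2 <- autocontour_2d(image, ref, mv, tbr_threshold)
  ac3 <- mtv_3d(image, ref, mv, tbr_threshold)
  structure(list(
    tbr_max = tbr_max(image, ref, mv, roi_diameter_mm),
    tbr_mean = ac2$tbr_mean,
    mtv_ml = ac3$mtv_ml,
    max_voxel = mv,
    tumour_detected = ac2$tumour_detected,
    reference = ref,
    mtv_mask = ac3$mask,
    contour_2d_mask = ac2$mask
  ), class = "static_params")
}

#' @export
print.static_params <- function(x, ...) {
  cat("Static FET PET parameters\n")
  cat(sprintf("  TBR_max  %.3f\n  TBR_mean %s\n  MTV      %.3f mL\n",
              x$tbr_max,
              if (is.na(x$tbr_mean)) "NA (no tumour detected)"
              else sprintf("%.3f", x$tbr_mean),
              x$mtv_ml))
  cat(sprintf("  max voxel (z,y,x) = (%s); tumour detected: %s\n",
              paste(x$max_voxel, collapse = ", "), x$tumour_detected))
  invisible(x)
}
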