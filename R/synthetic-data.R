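#' Parametric time-activity curve model
#'
#' Continuous tracer-uptake model
#' \deqn{u(t) = b + A (1 - e^{-t/\tau}) e^{-w t}}
#' with baseline \code{b} (SUV), amplitude \code{A} (SUV), uptake time
#' constant \code{tau_up} (min) and washout rate \code{w} (per min). With
#' \code{w > 0} the curve peaks at \eqn{t^* = \tau \log(1 + 1/(w\tau))} and
#' washes out (the early-peak phenotype typical of aggressive gliomas); with
#' \code{w = 0} it increases monotonically toward a plateau (the
#' steadily-increasing phenotype).
#'
#' @param class "washout" or "plateau".
#' @param amplitude A, SUV.
#' @param tau_up uptake time constant, minutes.
#' @param washout w, per minute; must be 0 for the plateau class and > 0 for
#'   the washout class.
#' @param baseline b, SUV.
#' @return An object of class \code{tac_model}.
#' @export
tac_model <- function(class = c("washout", "plateau"), amplitude = 3.5,
                      tau_up = if (class == "washout") 3 else 11,
                      washout = NULL, baseline = 0) {
  class <- match.arg(class)
  if (is.null(washout))
    washout <- if (class == "washout") 0.015 else 0
  if (class == "plateau" && washout != 0)
    stop("plateau class requires washout = 0")
  if (class == "washout" && washout <= 0)
    stop("washout class requires washout > 0")
  if (amplitude <= baseline || baseline < 0)
    stop("need amplitude > baseline >= 0")
  if (tau_up <= 0) stop("tau_up must be positive")
  structure(list(class = class, amplitude = amplitude, tau_up = tau_up,
                 washout = washout, baseline = baseline),
            class = "tac_model")
}

#' @rdname tac_model
#' @param peak_min desired continuous peak time in minutes.
#' @return \code{washout_for_peak}: the washout rate (per min) that places
#'   the continuous peak of the model at \code{peak_min} for the given
#'   \code{tau_up}.
#' @export
washout_for_peak <- function(peak_min, tau_up) {
  # u'(t*) = 0  =>  w = 1 / (tau (e^{t*/tau} - 1))
  1 / (tau_up * (expm1(peak_min / tau_up)))
}

#' @rdname tac_model
#' @param model a \code{tac_model}.
#' @param t_min time(s) in minutes.
#' @return \code{tac_value}: u(t) in SUV.
#' @export
tac_value <- function(model, t_min) {
  model$baseline + model$amplitude *
    (1 - exp(-t_min / model$tau_up)) * exp(-model$washout * t_min)
}

#' @rdname tac_model
#' @param schema a \code{\link{frame_schema}}.
#' @return \code{tac_frame_means}: the exact time-average of u(t) over each
#'   frame of the schema (closed form), in SUV.
#' @export
tac_frame_means <- function(model, schema = default_frame_schema()) {
  t0 <- schema$start_s / 60; t1 <- schema$end_s / 60
  # int_{t0}^{t1} e^{-a t} dt = (e^{-a t0} - e^{-a t1}) / a,  -> t1-t0 as a->0
  I <- function(a) {
    if (abs(a) < 1e-12) t1 - t0 else (exp(-a * t0) - exp(-a * t1)) / a
  }
  w <- model$washout
  model$baseline + model$amplitude *
    (I(w) - I(w + 1 / model$tau_up)) / (t1 - t0)
}

# noiseless discretized ground truth for a model on a schema
tac_ground_truth <- function(model, schema = default_frame_schema(),
                             slope_window_min = c(20, 50)) {
  tac <- time_activity_curve(schema, tac_frame_means(model, schema))
  ttp <- suppressWarnings(compute_ttp(tac))
  list(class = model$class, ttp_min = ttp$ttp_min,
       peak_identified = ttp$peak_identified,
       slope_suv_per_h = compute_slope(tac, slope_window_min),
       peak_min_continuous = if (model$washout > 0)
         model$tau_up * log(1 + 1 / (model$washout * model$tau_up))
       else Inf)
}

#' Generate a digital dynamic PET phantom
#'
#' Builds a dynamic series on the 16-frame schema consisting of a brain-like
#' background ellipsoid and an embedded spherical tumour, each following its
#' own continuous time-activity model. Frame values are the exact
#' time-average of the continuous curve over each frame interval, plus
#' i.i.d. Gaussian noise truncated at zero. A contralateral crescent-shaped
#' reference mask inside the background is returned together with the ground
#' truth of the noiseless discretized kinetics and the analytic tumour
#' volume.
#'
#' @param tumour_model a \code{\link{tac_model}} for the tumour (or NULL for
#'   a tumour-free phantom).
#' @param background_model a \code{\link{tac_model}} for healthy background.
#' @param fov_mm field of view (z, y, x) in mm.
#' @param spacing_mm voxel spacing (dz, dy, dx) in mm.
#' @param tumour_centre_mm tumour centre in mm from the volume centre
#'   (z, y, x); the default places it in one hemisphere.
#' @param tumour_radius_mm tumour sphere radius in mm.
#' @param noise_sigma Gaussian noise standard deviation, SUV.
#' @param schema frame schema (default 16 frames, 0-50 min).
#' @param seed integer seed.
#' @return A list with \code{series} (\code{\link{dynamic_pet_series}}),
#'   \code{reference_mask}, \code{tumour_mask} (true extent), and
#'   \code{ground_truth} (true kinetic class, noiseless discretized TTP and
#'   late-phase slope, analytic tumour volume in mL).
#' @export
generate_phantom <- function(tumour_model = tac_model("washout"),
                             background_model = tac_model(
                               "plateau", amplitude = 1, tau_up = 3,
                               washout = 0),
                             fov_mm = c(72, 96, 96),
                             spacing_mm = c(3, 3, 3),
                             tumour_centre_mm = c(0, 0, 22),
                             tumour_radius_mm = 10,
                             noise_sigma = 0,
                             schema = default_frame_schema(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(tumour_model) &&
      background_model$amplitude >= tumour_model$amplitude / 1.6)
    stop("background amplitude must be below tumour amplitude / 1.6 ",
         "for the lesion to be contourable")
  n <- pmax(3L, as.integer(round(fov_mm / spacing_mm)))
  # physical voxel-centre coordinates relative to the volume centre
  ax <- function(i) (seq_len(n[i]) - (n[i] + 1) / 2) * spacing_mm[i]
  zc <- ax(1); yc <- ax(2); xc <- ax(3)
  Z <- array(zc, dim = n)
  Y <- aperm(array(yc, dim = n[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(xc, dim = n[c(3, 2, 1)]), c(3, 2, 1))
  semi <- fov_mm / 2 - spacing_mm  # background ellipsoid semi-axes
  bg <- (Z / semi[1])^2 + (Y / semi[2])^2 + (X / semi[3])^2 <= 1
  tum <- array(FALSE, dim = n)
  hot <- NULL
  if (!is.null(tumour_model)) {
    # snap the tumour centre to the nearest voxel centre so that the
    # hottest voxel (and hence ROI/VOI placement) sits exactly at the centre
    d2 <- (Z - tumour_centre_mm[1])^2 + (Y - tumour_centre_mm[2])^2 +
      (X - tumour_centre_mm[3])^2
    hot <- arrayInd(which.min(d2), n)[1, ]
    tc <- c(Z[hot[1], hot[2], hot[3]], Y[hot[1], hot[2], hot[3]],
            X[hot[1], hot[2], hot[3]])
    tum <- (Z - tc[1])^2 + (Y - tc[2])^2 + (X - tc[3])^2 <=
      tumour_radius_mm^2
    if (!any(tum)) stop("tumour sphere contains no voxel centre")
    if (any(tum & !bg)) stop("tumour sphere extends outside the background")
  }
  # contralateral crescent: an in-plane half-annulus in the central slab,
  # on the opposite side (x) of the tumour, inside background only
  rin <- 0.45 * min(semi[2:3]); rout <- 0.8 * min(semi[2:3])
  rho <- sqrt(Y^2 + X^2)
  side <- if (!is.null(tumour_model) && tumour_centre_mm[3] >= 0) X < 0
          else X > 0
  crescent <- bg & !tum & side & rho >= rin & rho <= rout &
    abs(Z) <= max(spacing_mm[1], 0.15 * fov_mm[1])
  if (!any(crescent)) stop("reference crescent is empty; enlarge the FOV")

  bg_tac <- tac_frame_means(background_model, schema)
  tum_tac <- if (is.null(tumour_model)) NULL
             else tac_frame_means(tumour_model, schema)
  nfr <- nrow(schema)
  vox <- array(0, dim = c(nfr, n))
  for (f in seq_len(nfr)) {
    sl <- array(0, dim = n)
    sl[bg] <- bg_tac[f]
    if (!is.null(tumour_model)) {
      sl[tum] <- tum_tac[f]
      # infinitesimal boost marks the centre voxel as the unique hottest
      # voxel, as in a real lesion; ties at the maximum would otherwise put
      # the ROI/VOI centre at the ball's pole
      sl[hot[1], hot[2], hot[3]] <- tum_tac[f] * (1 + 1e-9)
    }
    if (noise_sigma > 0)
      sl <- pmax(0, sl + array(stats::rnorm(prod(n), 0, noise_sigma),
                               dim = n))
    vox[f, , , ] <- sl
  }
  series <- dynamic_pet_series(vox, spacing_mm, schema)
  gt <- if (is.null(tumour_model)) {
    list(class = "none", tumour_volume_ml = 0)
  } else {
    c(tac_ground_truth(tumour_model, schema),
      list(tumour_volume_ml = 4 / 3 * pi * tumour_radius_mm^3 / 1000,
           tumour_voxel_volume_ml = sum(tum) * prod(spacing_mm) / 1000,
           centre_voxel = as.integer(hot)))
  }
  list(series = series,
       reference_mask = region_mask(crescent, spacing_mm),
       tumour_mask = region_mask(tum, spacing_mm),
       ground_truth = gt)
}

#' Configuration for a synthetic survival cohort
#'
#' Defines the generative model of a cohort whose prognosis is driven by the
#' tumour's kinetic class: patients with an early-peak (washout) curve draw
#' survival from the unfavourable exponentials, patients with a
#' steadily-increasing (plateau) curve from the favourable ones. Default
#' medians are OS 29 vs 12 months and PFS 13 vs 7 months (favourable vs
#' unfavourable); covariate frequencies default to a typical newly diagnosed
#' malignant-astrocytoma case mix.
#'
#' @param n_patients cohort size.
#' @param proportion_washout probability of the unfavourable washout class.
#' @param os_median_months named c(plateau=, washout=) exponential OS
#'   medians, months.
#' @param pfs_median_months likewise for PFS.
#' @param censor_window_months administrative censoring time drawn uniformly
#'   from this (min, max) window, months; use NULL for no censoring.
#' @param noise_sigma TAC noise standard deviation, SUV.
#' @param washout_rate_range washout-class washout rates drawn uniformly
#'   from this range (per min); with uptake time constants of 2-4 min this
#'   places continuous peaks at about 7-13 min, the typical early-peak
#'   range.
#' @param amplitude_range tumour TAC amplitude range, SUV.
#' @param covariate_probs list of class-independent covariate frequencies:
#'   \code{idh_wildtype}, \code{mgmt_methylated}, \code{kps_100},
#'   \code{resection} (complete/partial/biopsy probabilities),
#'   \code{grade_iv}.
#' @param mgmt_log_hr additional log hazard for MGMT-unmethylated patients
#'   (applied to both endpoints; 0 = survival depends on kinetic class only).
#' @param seed integer seed (mandatory).
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 45,
                          proportion_washout = 0.5,
                          os_median_months = c(plateau = 29, washout = 12),
                          pfs_median_months = c(plateau = 13, washout = 7),
                          censor_window_months = c(24, 96),
                          noise_sigma = 0.05,
                          washout_rate_range = c(0.010, 0.018),
                          amplitude_range = c(2.8, 4),
                          covariate_probs = list(
                            idh_wildtype = 45 / 60,
                            mgmt_methylated = 35 / 60,
                            kps_100 = 29 / 60,
                            resection = c(complete = 29, partial = 10,
                                          biopsy = 21) / 60,
                            grade_iv = 45 / 60),
                          mgmt_log_hr = 0,
                          seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducible cohort generation")
  stopifnot(n_patients >= 1, proportion_washout >= 0,
            proportion_washout <= 1, all(os_median_months > 0),
            all(pfs_median_months > 0), noise_sigma >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

r_trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic survival cohort with ground truth
#'
#' Fast (tabular) mode, the default, draws each patient's kinetic class,
#' simulates a noisy 16-frame tumour TAC from the class's continuous model
#' and derives \code{ttp_min} and \code{slope_suv_per_h} by running the
#' package's own estimators on it; TBR and MTV are drawn from
#' class-conditional distributions. Survival times are class-conditional
#' exponentials (rate \eqn{\log 2 / \mathrm{median}}), PFS clipped to OS,
#' with uniform administrative censoring. Image mode additionally builds a
#' digital phantom per patient and runs the full image quantification
#' (slow; intended for small n).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param mode "fast" or "image".
#' @return A list with \code{cohort} (a validated \code{pet_cohort} data
#'   frame) and \code{ground_truth} (per-patient true class, noiseless
#'   discretized TTP/slope, true survival draws, and the config).
#' @export
generate_cohort <- function(config, mode = c("fast", "image")) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  n <- config$n_patients
  cls <- ifelse(stats::runif(n) < config$proportion_washout,
                "washout", "plateau")
  cp <- config$covariate_probs
  idh <- ifelse(stats::runif(n) < cp$idh_wildtype, "wildtype", "mutant")
  mgmt <- ifelse(stats::runif(n) < cp$mgmt_methylated,
                 "methylated", "unmethylated")
  kps <- ifelse(stats::runif(n) < cp$kps_100, 100L,
                sample(seq(60L, 90L, 10L), n, replace = TRUE))
  resection <- sample(names(cp$resection), n, replace = TRUE,
                      prob = cp$resection)
  age <- round(r_trunc_norm(n, 55, 12, 21, 78), 1)
  grade <- ifelse(stats::runif(n) < cp$grade_iv, "IV", "III")

  ttp <- slope <- true_ttp <- true_slope <- peak_cont <- numeric(n)
  tbrx <- tbrm <- mtv <- numeric(n)
  schema <- default_frame_schema()
  models <- vector("list", n)
  for (i in seq_len(n)) {
    A <- stats::runif(1, config$amplitude_range[1], config$amplitude_range[2])
    m <- if (cls[i] == "washout") {
      tac_model("washout", amplitude = A,
                tau_up = stats::runif(1, 2, 4),
                washout = stats::runif(1, config$washout_rate_range[1],
                                       config$washout_rate_range[2]))
    } else {
      tac_model("plateau", amplitude = A, tau_up = stats::runif(1, 8, 15),
                washout = 0)
    }
    models[[i]] <- m
    gt <- tac_ground_truth(m, schema)
    true_ttp[i] <- gt$ttp_min; true_slope[i] <- gt$slope_suv_per_h
    peak_cont[i] <- gt$peak_min_continuous
    if (mode == "fast") {
      noisy <- pmax(0, tac_frame_means(m, schema) +
                      stats::rnorm(nrow(schema), 0, config$noise_sigma))
      tac <- time_activity_curve(schema, noisy)
      ttp[i] <- suppressWarnings(compute_ttp(tac))$ttp_min
      slope[i] <- compute_slope(tac)
      # fast mode has no image: TBR/MTV drawn class-conditionally
      if (cls[i] == "washout") {
        tbrx[i] <- max(1.7, stats::rnorm(1, 3.2, 0.6))
        mtv[i] <- stats::rlnorm(1, log(16), 0.5)
      } else {
        tbrx[i] <- max(1.7, stats::rnorm(1, 2.3, 0.5))
        mtv[i] <- stats::rlnorm(1, log(9), 0.6)
      }
      tbrm[i] <- max(1.6, tbrx[i] - abs(stats::rnorm(1, 0.6, 0.2)))
    } else {
      ph <- generate_phantom(tumour_model = m,
                             noise_sigma = config$noise_sigma)
      q <- quantify_patient(ph$series, ph$reference_mask)
      ttp[i] <- q$kinetic$ttp_min
      slope[i] <- q$kinetic$slope_suv_per_h
      tbrx[i] <- q$static$tbr_max; tbrm[i] <- q$static$tbr_mean
      mtv[i] <- q$static$mtv_ml
    }
  }
  os_med <- config$os_median_months[cls]
  pfs_med <- config$pfs_median_months[cls]
  extra_hr <- exp(config$mgmt_log_hr * (mgmt == "unmethylated"))
  os_true <- stats::rexp(n, log(2) / os_med * extra_hr)
  pfs_raw <- stats::rexp(n, log(2) / pfs_med * extra_hr)
  pfs_true <- pmin(pfs_raw, os_true)
  if (!is.null(config$censor_window_months)) {
    cw <- config$censor_window_months
    cens <- stats::runif(n, cw[1], cw[2])
  } else cens <- rep(Inf, n)
  os_months <- round(pmin(os_true, cens), 2)
  os_event <- as.integer(os_true <= cens)
  pfs_months <- round(pmin(pfs_true, cens), 2)
  pfs_event <- as.integer(pfs_true <= cens)

  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    os_months = os_months, os_event = os_event,
    pfs_months = pfs_months, pfs_event = pfs_event,
    idh = idh, mgmt = mgmt, kps = kps, resection = resection,
    age_years = age, who_grade = grade,
    tbr_max = round(tbrx, 3), tbr_mean = round(tbrm, 3),
    mtv_ml = round(mtv, 3), ttp_min = ttp,
    slope_suv_per_h = round(slope, 5))
  cohort <- validate_cohort(cohort, src = "generated cohort")
  ground_truth <- list(
    per_patient = data.frame(
      patient_id = cohort$patient_id, kinetic_class = cls,
      true_ttp_min = true_ttp, true_slope_suv_per_h = true_slope,
      continuous_peak_min = peak_cont,
      os_true_months = os_true, pfs_true_months = pfs_true),
    models = models,
    config = config)
  list(cohort = cohort, ground_truth = ground_truth)
}
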