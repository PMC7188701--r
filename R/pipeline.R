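#' Pipeline configuration
#'
#' Central container for every analysis constant. Defaults are the standard
#' dynamic FET protocol values: 20-40 min evaluation window, TBR threshold
#' 1.6, 1.6 cm TBR_max ROI, 2 mL kinetic VOI, 20-50 min late-phase slope
#' window, and a favourable-OS landmark of 24 months.
#'
#' @param summed_window_min evaluation window for the static image, minutes.
#' @param tbr_threshold auto-contour tumour-to-brain ratio threshold.
#' @param roi_diameter_mm TBR_max circular ROI diameter, mm.
#' @param voi_volume_ml kinetic VOI volume, mL.
#' @param slope_window_min late-phase regression window, minutes.
#' @param favourable_os_cutoff_months favourable-OS landmark, months.
#' @param subgroup optional named character vector filtering the cohort
#'   before analysis, e.g. \code{c(idh = "wildtype")}; NULL analyses all
#'   patients.
#' @param thresholds named numeric vector of user-fixed dichotomization
#'   thresholds per PET parameter (e.g. \code{c(ttp_min = 25)}); parameters
#'   not listed use their ROC-derived optimum.
#' @param ttp_use_mid_time use frame mid times for TTP (default FALSE: frame
#'   end times).
#' @param smoothing_fwhm_mm optional Gaussian pre-smoothing FWHM in mm
#'   (NULL/0 = off).
#' @param alpha significance level gating entry into the multivariate model.
#' @param seed integer seed recorded in reports.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(summed_window_min = c(20, 40),
                            tbr_threshold = 1.6,
                            roi_diameter_mm = 16,
                            voi_volume_ml = 2,
                            slope_window_min = c(20, 50),
                            favourable_os_cutoff_months = 24,
                            subgroup = NULL,
                            thresholds = NULL,
                            ttp_use_mid_time = FALSE,
                            smoothing_fwhm_mm = NULL,
                            alpha = 0.05,
                            seed = NULL) {
  stopifnot(length(summed_window_min) == 2L, tbr_threshold > 0,
            roi_diameter_mm > 0, voi_volume_ml > 0,
            length(slope_window_min) == 2L,
            favourable_os_cutoff_months > 0, alpha > 0, alpha < 1)
  structure(list(summed_window_min = summed_window_min,
                 tbr_threshold = tbr_threshold,
                 roi_diameter_mm = roi_diameter_mm,
                 voi_volume_ml = voi_volume_ml,
                 slope_window_min = slope_window_min,
                 favourable_os_cutoff_months = favourable_os_cutoff_months,
                 subgroup = subgroup, thresholds = thresholds,
                 ttp_use_mid_time = ttp_use_mid_time,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

pet_parameters <- function() {
  c("tbr_max", "tbr_mean", "mtv_ml", "ttp_min", "slope_suv_per_h")
}

# clinical factors at their conventional cuts: TRUE = putatively favourable
clinical_factor_defs <- function() {
  list(
    age = list(label = "age < 70", fn = function(d) d$age_years < 70),
    resection = list(label = "complete resection",
                     fn = function(d) d$resection == "complete"),
    idh = list(label = "IDH mutant", fn = function(d) d$idh == "mutant"),
    mgmt = list(label = "MGMT methylated",
                fn = function(d) d$mgmt == "methylated"),
    kps = list(label = "KPS 100", fn = function(d) d$kps >= 100)
  )
}

#' Full prognostic analysis of a PET-parameter cohort
#'
#' Reproduces the three-stage biomarker workflow: (1) ROC of each PET
#' parameter against the favourable-OS label with the
#' sensitivity-specificity-product optimal cutoff; (2) univariate
#' Kaplan-Meier/log-rank comparisons for PFS and OS, dichotomizing each PET
#' parameter at its ROC-derived (or user-fixed) threshold and each clinical
#' factor at its conventional cut (age 70, complete resection, IDH, MGMT,
#' KPS 100); (3) a multivariate Cox model for OS over the factors that were
#' univariately significant for OS, with TTP and MTV entered continuously
#' and the remaining factors dichotomized.
#'
#' @param cohort a \code{pet_cohort} data frame (see
#'   \code{\link{read_cohort}}) including the PET parameter columns.
#' @param config a \code{\link{pipeline_config}}; \code{config$subgroup}
#'   filters the cohort first (e.g. IDH-wildtype only).
#' @return A list of class \code{survival_report}: \code{t2_roc},
#'   \code{t3_univariate}, \code{t4_cox} data frames, \code{cox}
#'   (\code{\link{cox_fit}} result or NULL), \code{n_analysed},
#'   \code{config}, and \code{notes}.
#' @export
run_survival_analysis <- function(cohort, config = pipeline_config()) {
  cohort <- validate_cohort(as.data.frame(cohort))
  notes <- character()
  if (!is.null(config$subgroup)) {
    for (v in names(config$subgroup))
      cohort <- cohort[cohort[[v]] == config$subgroup[[v]], , drop = FALSE]
    if (nrow(cohort) == 0L) stop("subgroup filter removed all patients")
    notes <- c(notes, sprintf("subgroup: %s", paste(names(config$subgroup),
               config$subgroup, sep = "=", collapse = ", ")))
  }
  params <- intersect(pet_parameters(), names(cohort))
  if (length(params) == 0L) stop("cohort has no PET parameter columns")

  ## stage 1: ROC per PET parameter
  lab <- favourable_os_label(cohort$os_months, cohort$os_event,
                             config$favourable_os_cutoff_months)
  keep <- lab != "indeterminate"
  n_excl <- sum(!keep)
  roc_list <- list()
  t2 <- NULL
  for (p in params) {
    roc_list[[p]] <- roc_optimal_cutoff(cohort[[p]][keep], lab[keep],
                                        n_excluded = n_excl)
    r <- roc_list[[p]]
    t2 <- rbind(t2, data.frame(
      parameter = p, threshold = r$threshold,
      sensitivity_pct = 100 * r$sensitivity,
      specificity_pct = 100 * r$specificity,
      auc = r$auc, auc_se = r$auc_se, p_value = r$p_value,
      direction = r$direction, n_favourable = r$n_pos,
      n_unfavourable = r$n_neg, n_excluded = r$n_excluded))
  }

  ## stage 2: univariate KM/log-rank for PFS and OS
  thr_used <- vapply(params, function(p) {
    if (!is.null(config$thresholds) && p %in% names(config$thresholds))
      config$thresholds[[p]] else roc_list[[p]]$threshold
  }, numeric(1))
  factors <- list()
  for (p in params) {
    if (is.na(thr_used[[p]])) next
    dir <- roc_list[[p]]$direction
    fav <- if (dir == "higher_favourable") cohort[[p]] > thr_used[[p]]
           else cohort[[p]] < thr_used[[p]]
    factors[[p]] <- list(label = sprintf("%s %s %.4g", p,
                                         if (dir == "higher_favourable")
                                           ">" else "<", thr_used[[p]]),
                         fav = fav, threshold = thr_used[[p]],
                         kind = "pet")
  }
  for (nm in names(clinical_factor_defs())) {
    def <- clinical_factor_defs()[[nm]]
    factors[[nm]] <- list(label = def$label, fav = def$fn(cohort),
                          threshold = NA_real_, kind = "clinical")
  }
  t3 <- NULL
  os_p <- setNames(rep(NA_real_, length(factors)), names(factors))
  for (nm in names(factors)) {
    f <- factors[[nm]]
    grp <- factor(ifelse(f$fav, "favourable", "unfavourable"),
                  levels = c("favourable", "unfavourable"))
    row <- data.frame(factor = nm, criterion = f$label,
                      pfs_p = NA_real_, pfs_median_fav = NA_real_,
                      pfs_median_unfav = NA_real_,
                      os_p = NA_real_, os_median_fav = NA_real_,
                      os_median_unfav = NA_real_)
    if (nlevels(droplevels(grp)) == 2L) {
      km_p <- km_logrank(cohort$pfs_months, cohort$pfs_event, grp)
      km_o <- km_logrank(cohort$os_months, cohort$os_event, grp)
      row$pfs_p <- km_p$p_value
      row$pfs_median_fav <- km_p$median_months[1L]
      row$pfs_median_unfav <- km_p$median_months[2L]
      row$os_p <- km_o$p_value
      row$os_median_fav <- km_o$median_months[1L]
      row$os_median_unfav <- km_o$median_months[2L]
      os_p[nm] <- km_o$p_value
    } else {
      notes <- c(notes, sprintf("factor %s has a single level; skipped", nm))
    }
    t3 <- rbind(t3, row)
  }

  ## stage 3: multivariate Cox on OS-significant factors
  sig <- names(os_p)[!is.na(os_p) & os_p < config$alpha]
  cox <- NULL; t4 <- NULL
  if (length(sig) > 0L) {
    covs <- list()
    for (nm in sig) {
      covs[[nm]] <- if (nm %in% c("ttp_min", "mtv_ml")) {
        list(type = "continuous")
      } else if (factors[[nm]]$kind == "pet") {
        dir <- roc_list[[nm]]$direction
        list(type = "binary", threshold = factors[[nm]]$threshold,
             direction = if (dir == "higher_favourable") ">" else "<")
      } else {
        # clinical factors enter as their favourable indicator
        list(type = "indicator")
      }
    }
    X <- as.data.frame(cohort)
    for (nm in sig)
      if (covs[[nm]]$type == "indicator") {
        X[[nm]] <- as.numeric(factors[[nm]]$fav)
        covs[[nm]] <- list(type = "continuous")
      }
    cox <- tryCatch(
      cox_fit(X, cohort$os_months, cohort$os_event, covs),
      error = function(e) {
        notes <<- c(notes, paste("Cox stage failed:", conditionMessage(e)))
        NULL
      })
    if (!is.null(cox)) t4 <- cox$table
  } else {
    notes <- c(notes, "no univariately significant factor; Cox stage empty")
  }
  structure(list(t2_roc = t2, t3_univariate = t3, t4_cox = t4, cox = cox,
                 n_analysed = nrow(cohort), thresholds_used = thr_used,
                 roc = roc_list, config = config, notes = notes),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Prognostic analysis of %d patients\n", x$n_analysed))
  cat("\n-- ROC / optimal thresholds --\n")
  print(transform(x$t2_roc, auc = round(auc, 3), auc_se = round(auc_se, 3),
                  threshold = signif(threshold, 4),
                  p_value = signif(p_value, 3)),
        row.names = FALSE)
  cat("\n-- Univariate log-rank --\n")
  print(transform(x$t3_univariate, pfs_p = signif(pfs_p, 3),
                  os_p = signif(os_p, 3)), row.names = FALSE)
  cat("\n-- Multivariate Cox (OS) --\n")
  if (is.null(x$t4_cox)) cat("  (empty)\n") else print(x$cox)
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write a survival report to a directory
#'
#' Writes \code{t2_roc.csv}, \code{t3_univariate.csv}, \code{t4_cox.csv}
#' and \code{report.json} (which embeds the resolved configuration).
#'
#' @param report a \code{survival_report}.
#' @param dir output directory (created if needed).
#' @export
write_survival_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$t2_roc, file.path(dir, "t2_roc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$t3_univariate, file.path(dir, "t3_univariate.csv"),
                   row.names = FALSE)
  if (!is.null(report$t4_cox))
    utils::write.csv(report$t4_cox, file.path(dir, "t4_cox.csv"),
                     row.names = FALSE)
  payload <- list(
    n_analysed = report$n_analysed,
    thresholds_used = as.list(report$thresholds_used),
    t2_roc = report$t2_roc, t3_univariate = report$t3_univariate,
    t4_cox = report$t4_cox, notes = report$notes,
    config = unclass(report$config))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
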