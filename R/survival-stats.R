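#' Favourable-survival labelling for ROC analysis
#'
#' Dichotomizes overall survival at a reference cutoff (default 24 months,
#' the conventional favourable-OS landmark in glioblastoma). Patients alive
#' at or beyond the cutoff are favourable regardless of censoring; patients
#' who died before it are unfavourable; patients censored alive before the
#' cutoff carry no information about it and are labelled indeterminate
#' (excluded from ROC, with the exclusion count reported).
#'
#' @param os_months overall survival in months.
#' @param os_event 1 = death observed, 0 = censored.
#' @param cutoff_months favourable-OS landmark (default 24).
#' @return Character vector in \{"favourable", "unfavourable",
#'   "indeterminate"\}.
#' @export
favourable_os_label <- function(os_months, os_event, cutoff_months = 24) {
  ifelse(os_months >= cutoff_months, "favourable",
         ifelse(os_event == 1, "unfavourable", "indeterminate"))
}

# empirical AUC with ties counting 1/2, via the rank-sum identity
auc_rank <- function(values, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(values, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with the sensitivity-specificity-product optimal cutoff
#'
#' Empirical ROC of a continuous marker against a binary favourable /
#' unfavourable outcome. The AUC is the rank (pair-counting) estimate with
#' ties counting 1/2; its standard error is Hanley-McNeil. Orientation is
#' chosen automatically so the reported AUC is at least 0.5 and recorded in
#' \code{direction}. Candidate cutoffs are midpoints between consecutive
#' distinct marker values; the optimal cutoff maximizes sensitivity times
#' specificity, with ties broken toward higher specificity.
#'
#' @param values numeric marker values.
#' @param labels character vector, "favourable" (positive class) or
#'   "unfavourable"; other labels are an error.
#' @param n_excluded number of indeterminate patients excluded upstream
#'   (reported, not used).
#' @return An object of class \code{roc_result}: \code{auc}, \code{auc_se},
#'   \code{p_value} (Wald test of AUC = 0.5), \code{threshold},
#'   \code{sensitivity}, \code{specificity}, \code{direction},
#'   \code{n_pos}, \code{n_neg}, \code{n_excluded}.
#' @export
roc_optimal_cutoff <- function(values, labels, n_excluded = 0L) {
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  ok <- labels %in% c("favourable", "unfavourable")
  if (!all(ok)) stop("labels must be 'favourable' or 'unfavourable'")
  pos <- labels == "favourable"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs both favourable and unfavourable patients (got ",
         n1, " favourable, ", n0, " unfavourable)")
  a <- auc_rank(values, pos)
  direction <- if (a >= 0.5) "higher_favourable" else "lower_favourable"
  if (a < 0.5) a <- 1 - a
  # Hanley-McNeil standard error of the empirical AUC
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  p <- if (se == 0) {
    if (a > 0.5) 0 else 1
  } else 2 * stats::pnorm(-abs(a - 0.5) / se)
  sv <- sort(unique(values))
  if (length(sv) < 2L) {
    warning("all marker values identical: AUC 0.5, no cutoff")
    return(structure(list(auc = 0.5, auc_se = se, p_value = 1,
                          threshold = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, direction = direction,
                          n_pos = n1, n_neg = n0,
                          n_excluded = as.integer(n_excluded)),
                     class = "roc_result"))
  }
  cuts <- (sv[-1L] + sv[-length(sv)]) / 2
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    call_pos <- if (direction == "higher_favourable") values > cuts[i]
                else values < cuts[i]
    sens[i] <- sum(call_pos & pos) / n1
    spec[i] <- sum(!call_pos & !pos) / n0
  }
  prod <- sens * spec
  best <- which(prod == max(prod))
  best <- best[which.max(spec[best])]  # tie -> higher specificity
  structure(list(auc = a, auc_se = se, p_value = p,
                 threshold = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], direction = direction,
                 n_pos = n1, n_neg = n0,
                 n_excluded = as.integer(n_excluded)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f +/- %.3f (p = %.3g), threshold %.4g (%s)\n",
    x$auc, x$auc_se, x$p_value, x$threshold, x$direction))
  cat(sprintf("  sensitivity %.2f, specificity %.2f; n = %d/%d (+%d excluded)\n",
              x$sensitivity, x$specificity, x$n_pos, x$n_neg, x$n_excluded))
  invisible(x)
}

# KM median: earliest event time at which the survival step function is <= 0.5
km_median <- function(fit) {
  s <- summary(fit, censored = FALSE)
  idx <- which(s$surv <= 0.5 + 1e-12)
  if (length(idx) == 0L) NA_real_ else s$time[min(idx)]
}

#' Two-group Kaplan-Meier / log-rank comparison
#'
#' Product-limit survival estimates per group with per-group medians
#' (earliest time the survival curve reaches 0.5 or below; NA when never
#' reached), and the two-group log-rank test with 1 degree of freedom.
#'
#' @param times survival times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @param group two-level grouping vector.
#' @return An object of class \code{km_result}: \code{group_labels},
#'   per-group \code{n}, \code{events}, \code{median_months};
#'   \code{logrank_chi2}, \code{p_value}, and \code{fit} (the
#'   \code{survfit} object, for curve coordinates).
#' @export
km_logrank <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L)
    stop("km_logrank needs exactly two groups, got ", nlevels(group))
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  if (sum(events) < 1L) stop("no events observed")
  dat <- data.frame(t = times, e = events, g = group)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = dat)
  meds <- vapply(levels(group), function(lv) {
    sub <- dat[dat$g == lv, ]
    km_median(survival::survfit(survival::Surv(t, e) ~ 1, data = sub))
  }, numeric(1))
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = dat)
  chi2 <- sd_$chisq
  structure(list(group_labels = levels(group),
                 n = as.integer(table(group)),
                 events = as.integer(tapply(events, group, sum)),
                 median_months = meds,
                 logrank_chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 fit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier / log-rank comparison\n")
  for (i in 1:2)
    cat(sprintf("  %s: n = %d, events = %d, median = %s months\n",
                x$group_labels[i], x$n[i], x$events[i],
                ifelse(is.na(x$median_months[i]), "not reached",
                       format(x$median_months[i]))))
  cat(sprintf("  log-rank chi2 = %.3f, p = %.4g\n", x$logrank_chi2,
              x$p_value))
  invisible(x)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling) of a survival
#' endpoint on a set of coded covariates, via \code{survival::coxph}. Each
#' covariate is either continuous (entered as-is) or dichotomized at a
#' threshold.
#'
#' @param data data frame containing the covariate columns.
#' @param times,events endpoint (months) and event indicators.
#' @param covariates named list of coding specs; each element is
#'   \code{list(type = "continuous")} or \code{list(type = "binary",
#'   threshold = x, direction = ">"| "<" )} (TRUE when value > / < threshold)
#'   or \code{list(type = "level", level = "methylated")} for categoricals.
#' @return An object of class \code{cox_result}: a \code{table} data frame
#'   with per-covariate \code{beta}, \code{hazard_ratio}, \code{ci95_low},
#'   \code{ci95_high}, \code{p_value}; plus \code{n}, \code{n_events},
#'   \code{converged}, and the underlying \code{fit}.
#' @export
cox_fit <- function(data, times, events, covariates) {
  if (length(covariates) == 0L) stop("no covariates specified")
  X <- data.frame(row.names = seq_len(nrow(data)))
  for (nm in names(covariates)) {
    spec <- covariates[[nm]]
    v <- data[[nm]]
    if (is.null(v)) stop("covariate column not found: ", nm)
    X[[nm]] <- switch(spec$type,
      continuous = as.numeric(v),
      binary = {
        dir <- spec$direction %||% ">"
        as.numeric(if (dir == ">") v > spec$threshold else v < spec$threshold)
      },
      level = as.numeric(v == spec$level),
      stop("unknown covariate coding type: ", spec$type))
    if (length(unique(X[[nm]])) < 2L)
      stop("covariate '", nm, "' is constant across patients; ",
           "remove it from the model")
  }
  n_ev <- sum(events)
  if (n_ev < length(covariates))
    stop("fewer events (", n_ev, ") than covariates (",
         length(covariates), ")")
  if (n_ev / length(covariates) < 10)
    warning("events per covariate below 10 (", round(n_ev /
            length(covariates), 1), "); estimates may be unstable")
  dat <- cbind(data.frame(.t = times, .e = events), X)
  fml <- stats::as.formula(paste("survival::Surv(.t, .e) ~",
                                 paste(names(X), collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(iter.max = 100,
                                                      eps = 1e-9)),
    warning = function(w) {
      if (grepl("infinite|singular|did not converge",
                conditionMessage(w))) sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("Cox fit degenerate (singular design); ",
         "consider removing a covariate")
  if (sep_warn && any(abs(beta) > 15))
    stop("complete separation detected for a covariate; ",
         "consider removing it from the model")
  se <- sqrt(diag(fit$var))
  converged <- !sep_warn && fit$iter < 100
  tab <- data.frame(
    covariate = names(beta),
    beta = unname(beta),
    hazard_ratio = exp(unname(beta)),
    ci95_low = exp(unname(beta) - 1.96 * se),
    ci95_high = exp(unname(beta) + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    row.names = NULL)
  structure(list(table = tab, n = nrow(dat), n_events = n_ev,
                 converged = converged, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards model: n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(transform(x$table,
                  hazard_ratio = signif(hazard_ratio, 4),
                  ci95_low = signif(ci95_low, 4),
                  ci95_high = signif(ci95_high, 4),
                  p_value = signif(p_value, 3),
                  beta = signif(beta, 4)), row.names = FALSE)
  invisible(x)
}
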