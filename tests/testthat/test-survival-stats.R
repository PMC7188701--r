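test_that("favourable-OS labelling respects censoring", {
  expect_equal(favourable_os_label(29, 1), "favourable")
  expect_equal(favourable_os_label(29, 0), "favourable")
  expect_equal(favourable_os_label(12, 1), "unfavourable")
  expect_equal(favourable_os_label(10, 0), "indeterminate")
  expect_equal(favourable_os_label(24, 0), "favourable")  # at the landmark
  expect_equal(favourable_os_label(c(30, 5, 5), c(0, 1, 0)),
               c("favourable", "unfavourable", "indeterminate"))
})

test_that("ROC handles perfect separation, chance, and ties", {
  r <- roc_optimal_cutoff(c(1, 2, 3, 4),
                          c("unfavourable", "unfavourable",
                            "favourable", "favourable"))
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 2); expect_lt(r$threshold, 3)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_equal(r$direction, "higher_favourable")

  # alternating labels: the 4 favourable/unfavourable pairs are
  # (1,2)=0, (1,4)=0, (3,2)=1, (3,4)=0 -> 1/4, oriented to 3/4
  r2 <- roc_optimal_cutoff(c(1, 2, 3, 4),
                           c("favourable", "unfavourable",
                             "favourable", "unfavourable"))
  expect_equal(r2$auc,
               max(auc_pairs_oracle(1:4, c(TRUE, FALSE, TRUE, FALSE)),
                   1 - auc_pairs_oracle(1:4, c(TRUE, FALSE, TRUE, FALSE))))
  expect_equal(r2$auc, 0.75)

  # one shared value between classes contributes 1/2 a pair
  vals <- c(1, 2, 2, 3)
  labs <- c("unfavourable", "unfavourable", "favourable", "favourable")
  expect_equal(roc_optimal_cutoff(vals, labs)$auc,
               auc_pairs_oracle(vals, labs == "favourable"))
  expect_equal(roc_optimal_cutoff(vals, labs)$auc, 0.875)

  expect_error(roc_optimal_cutoff(1:3, rep("favourable", 3)),
               "both favourable and unfavourable")
  expect_warning(r3 <- roc_optimal_cutoff(c(2, 2, 2, 2),
                                          labs), "identical")
  expect_equal(r3$auc, 0.5)
})

test_that("empirical AUC equals brute-force pair counting on random data", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    vals <- round(rnorm(n, ifelse(pos, 0.5, 0), 1), sample(0:2, 1))
    labs <- ifelse(pos, "favourable", "unfavourable")
    r <- roc_optimal_cutoff(vals, labs)
    oracle <- auc_pairs_oracle(vals, pos)
    expect_equal(r$auc, max(oracle, 1 - oracle))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(23)
  vals <- rnorm(40); pos <- runif(40) < 0.4
  labs <- ifelse(pos, "favourable", "unfavourable")
  base <- roc_optimal_cutoff(vals, labs)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) rank(x, ties.method = "average"))) {
    got <- roc_optimal_cutoff(f(vals), labs)
    expect_equal(got$auc, base$auc)
    expect_equal(got$direction, base$direction)
  }
})

test_that("Hanley-McNeil SE matches the closed form on a known case", {
  # AUC A, n1 favourable, n0 unfavourable
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c("unfavourable", "unfavourable", "favourable",
            "unfavourable", "favourable", "favourable")
  r <- roc_optimal_cutoff(vals, labs)
  a <- auc_pairs_oracle(vals, labs == "favourable")
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 2 * (q1 - a^2) + 2 * (q2 - a^2)) / 9)
  expect_equal(r$auc, a)
  expect_equal(r$auc_se, se)
})

test_that("sens-spec product cutoff prefers specificity on ties", {
  # oriented higher_favourable; cutoffs between distinct values
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c("unfavourable", "unfavourable", "unfavourable",
            "favourable", "favourable", "favourable")
  r <- roc_optimal_cutoff(vals, labs)
  expect_equal(r$threshold, 3.5)
  # degrade one favourable below all: two cutoffs share the product max;
  # the higher-specificity one must be returned
  vals2 <- c(0, 2, 3, 4, 5, 6)
  labs2 <- c("favourable", "unfavourable", "unfavourable",
             "unfavourable", "favourable", "favourable")
  r2 <- roc_optimal_cutoff(vals2, labs2)
  grid <- sapply(sort(unique(vals2))[-1] - 0.5, function(ct) {
    sens <- mean(vals2[labs2 == "favourable"] > ct)
    spec <- mean(vals2[labs2 == "unfavourable"] <= ct)
    c(ct, sens * spec, spec)
  })
  best_prod <- max(grid[2, ])
  cand <- grid[, grid[2, ] == best_prod, drop = FALSE]
  expect_equal(r2$sensitivity * r2$specificity, best_prod)
  expect_equal(r2$specificity, max(cand[3, ]))
})

test_that("KM medians follow the step-function rule; log-rank is sound", {
  # identical data in both groups: chi2 = 0, p = 1
  km <- km_logrank(c(2, 4, 6, 8, 2, 4, 6, 8), rep(1, 8),
                   rep(c("a", "b"), each = 4))
  expect_equal(km$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1)

  # uncensored {2,4,6,8}: S = .75,.5,.25,0 -> earliest S <= 0.5 is t = 4
  steps <- km_steps_oracle(c(2, 4, 6, 8), rep(1, 4))
  expect_equal(steps$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_months, c(a = 4, b = 4))

  # censoring beyond the last event leaves the median undefined
  km2 <- km_logrank(c(1, 50, 60, 70, 1, 2, 3, 4),
                    c(1, 0, 0, 0, 1, 1, 1, 1),
                    rep(c("g1", "g2"), each = 4))
  expect_true(is.na(km2$median_months[["g1"]]))
  expect_equal(km2$median_months[["g2"]], 2)

  expect_error(km_logrank(1:4, rep(1, 4), rep("a", 4)), "two groups")
  expect_error(km_logrank(1:4, rep(0, 4), rep(c("a", "b"), 2)), "no events")

  # KM median of exponential draws approximates ln 2 / lambda
  set.seed(31)
  t <- rexp(1000, log(2) / 15)
  km3 <- km_logrank(c(t, t + 0.01), rep(1, 2000),
                    rep(c("x", "y"), each = 1000))
  expect_lt(abs(km3$median_months[["x"]] - 15) / 15, 0.1)
})

test_that("Cox fit recovers a known hazard ratio and flags degeneracies", {
  set.seed(41)
  n <- 500
  grp <- rep(0:1, each = n)
  t <- rexp(2 * n, 0.05 * exp(log(2) * grp))
  d <- data.frame(g = grp)
  fit <- cox_fit(d, t, rep(1, 2 * n),
                 list(g = list(type = "continuous")))
  hr <- fit$table$hazard_ratio
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
  expect_true(fit$converged)
  expect_equal(fit$table$hazard_ratio, exp(fit$table$beta))
  expect_lte(fit$table$ci95_low, fit$table$hazard_ratio)
  expect_gte(fit$table$ci95_high, fit$table$hazard_ratio)

  # constant covariate
  d2 <- data.frame(g = rep(1, 20))
  expect_error(cox_fit(d2, rexp(20), rep(1, 20),
                       list(g = list(type = "continuous"))), "constant")

  # binary-at-threshold coding
  d3 <- data.frame(x = c(rep(1, 50), rep(10, 50)))
  t3 <- rexp(100, 0.05 * exp(0.7 * (d3$x > 5)))
  fit3 <- suppressWarnings(
    cox_fit(d3, t3, rep(1, 100),
            list(x = list(type = "binary", threshold = 5))))
  expect_equal(nrow(fit3$table), 1)
})

test_that("log-rank p-values are near-uniform under the null", {
  set.seed(51)
  p <- replicate(400, {
    t <- rexp(40, 0.08)
    g <- rep(c("a", "b"), 20)
    km_logrank(t, rep(1, 40), g)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("run_survival_analysis reproduces the three-stage flow", {
  res <- generate_cohort(cohort_config(n_patients = 60, seed = 97))
  rep_ <- run_survival_analysis(res$cohort,
                                pipeline_config(thresholds = c(ttp_min = 25)))
  expect_equal(nrow(rep_$t2_roc), 5)
  expect_equal(rep_$t3_univariate$factor[1:5],
               c("tbr_max", "tbr_mean", "mtv_ml", "ttp_min",
                 "slope_suv_per_h"))
  expect_equal(nrow(rep_$t3_univariate), 10)
  expect_equal(rep_$n_analysed, 60)
  # the user-fixed TTP threshold overrides the ROC-derived one
  expect_equal(unname(rep_$thresholds_used[["ttp_min"]]), 25)

  # subgroup filtering
  rep_wt <- run_survival_analysis(res$cohort,
    pipeline_config(subgroup = c(idh = "wildtype")))
  expect_equal(rep_wt$n_analysed, sum(res$cohort$idh == "wildtype"))

  # subgroup reducing a class to zero errors in the ROC stage
  one <- res$cohort[res$cohort$os_months < 24 & res$cohort$os_event == 1, ]
  expect_error(run_survival_analysis(one), "favourable")

  # a cohort with no prognostic signal leaves the Cox stage empty
  set.seed(61)
  null_co <- res$cohort
  null_co$os_months <- round(rexp(60, log(2) / 15), 2)
  null_co$pfs_months <- pmin(null_co$pfs_months, null_co$os_months)
  for (col in c("tbr_max", "tbr_mean", "mtv_ml", "ttp_min",
                "slope_suv_per_h"))
    null_co[[col]] <- sample(null_co[[col]])
  rep_null <- suppressWarnings(run_survival_analysis(null_co))
  if (is.null(rep_null$t4_cox))
    expect_match(paste(rep_null$notes, collapse = " "),
                 "Cox stage empty|failed")
  else succeed()

  # the dichotomized marker's AUC collapses to (sens + spec) / 2 at the
  # chosen cutoff (the two-segment ROC), so thresholding cannot create
  # discrimination beyond that operating point
  lab <- favourable_os_label(res$cohort$os_months, res$cohort$os_event)
  keep <- lab != "indeterminate"
  for (p in c("ttp_min", "tbr_max")) {
    r <- rep_$roc[[p]]
    dirfun <- if (r$direction == "higher_favourable") `>` else `<`
    bin <- as.numeric(dirfun(res$cohort[[p]][keep], r$threshold))
    rb <- suppressWarnings(roc_optimal_cutoff(bin, lab[keep]))
    expect_equal(rb$auc, (r$sensitivity + r$specificity) / 2)
    expect_lte(rb$auc, 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    vals <- rnorm(n, 0.6 * pos, 1)
    r <- roc_optimal_cutoff(vals, ifelse(pos, "favourable", "unfavourable"))
    ext <- suppressMessages(pROC::auc(pROC::roc(pos, vals,
                                                direction = "auto",
                                                quiet = TRUE)))
    expect_equal(r$auc, as.numeric(ext), tolerance = 1e-12)
  }
})
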