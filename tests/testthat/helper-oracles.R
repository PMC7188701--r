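# Independent oracles and tiny fixture builders used across the suite.

# brute-force AUC by explicit pair counting (ties count 1/2)
auc_pairs_oracle <- function(values, positive) {
  pos <- values[positive]; neg <- values[!positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# brute-force seeded connected component by queue flood fill
flood_fill_oracle <- function(above, seed, three_d = TRUE) {
  d <- dim(above)
  comp <- array(FALSE, dim = d)
  queue <- list(seed)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  steps <- list(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0))
  if (three_d) steps <- c(steps, list(c(1, 0, 0), c(-1, 0, 0)))
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (s in steps) {
      w <- v + s
      if (all(w >= 1) && all(w <= d) && above[w[1], w[2], w[3]] &&
          !comp[w[1], w[2], w[3]]) {
        comp[w[1], w[2], w[3]] <- TRUE
        queue <- c(queue, list(w))
      }
    }
  }
  comp
}

# hand-rolled product-limit estimate at event times (no censoring support
# needed beyond risk-set bookkeeping)
km_steps_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# uniform image with an axis-aligned box of higher uptake
box_image <- function(n = c(8, 12, 12), spacing = c(2, 2, 2),
                      bg = 1, fg = 3.2,
                      z = 3:5, y = 4:7, x = 4:7) {
  vox <- array(bg, dim = n)
  vox[z, y, x] <- fg
  volume_image(vox, spacing)
}

# dynamic series that is spatially uniform with given frame values
uniform_series <- function(frame_values, n = c(6, 6, 6),
                           spacing = c(4, 4, 4),
                           schema = default_frame_schema()) {
  stopifnot(length(frame_values) == nrow(schema))
  vox <- array(rep(frame_values, prod(n)), dim = c(length(frame_values), n))
  dynamic_pet_series(vox, spacing, schema)
}

ref_stats <- function(mean_suv) {
  structure(list(mean_suv = mean_suv, voxel_count = 10L),
            class = "reference_stats")
}

# minimal valid cohort row(s)
make_cohort <- function(n = 4, os = c(29, 12, 30, 10),
                        os_ev = c(1, 1, 0, 0)) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    os_months = os[seq_len(n)], os_event = os_ev[seq_len(n)],
    pfs_months = pmin(os[seq_len(n)], 8), pfs_event = 1,
    idh = "wildtype", mgmt = "methylated", kps = 90,
    resection = "complete", age_years = 55, who_grade = "IV",
    tbr_max = 2.5, tbr_mean = 2.0, mtv_ml = 10,
    ttp_min = 25, slope_suv_per_h = -0.1)
}
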