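# Independent oracles used to cross-check package computations.

# ICC(A,1) from mean squares obtained via stats::aov on the long-format
# two-way layout (independent of the package's sums-of-squares path).
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  long <- data.frame(
    value = c(x, y),
    subject = factor(rep(seq_len(n), 2)),
    method = factor(rep(c("a", "b"), each = n))
  )
  ms <- summary(stats::aov(value ~ subject + method, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Consistency-form single-measure ICC (two-way mixed), for contrast with the
# absolute-agreement form.
oracle_icc_consistency <- function(x, y) {
  n <- length(x)
  long <- data.frame(
    value = c(x, y),
    subject = factor(rep(seq_len(n), 2)),
    method = factor(rep(c("a", "b"), each = n))
  )
  ms <- summary(stats::aov(value ~ subject + method, data = long))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + ms[3])
}

# Brute-force per-minute re-summation of an SVM series (mean * 60).
oracle_epoch_values <- function(time_s, svm) {
  vapply(0:1439, function(m) {
    sel <- time_s >= m * 60 & time_s < (m + 1) * 60
    if (!any(sel)) return(NA_real_)
    mean(svm[sel]) * 60
  }, numeric(1))
}

# Minute-expansion oracle for diary compilation: assign every single minute
# to a band, then count.
oracle_diary_minutes <- function(diary) {
  lab <- character(1440)
  for (i in seq_len(nrow(diary))) {
    mins <- (diary$start_min[i] + 1):diary$end_min[i]
    band <- if (tolower(diary$activity[i]) == "sleep") "sleep"
      else if (diary$met[i] >= 3) "mvpa"
      else if (diary$met[i] >= 1.5) "lpa"
      else "sed"
    lab[mins] <- band
  }
  c(sleep = sum(lab == "sleep"), sed = sum(lab == "sed"),
    lpa = sum(lab == "lpa"), mvpa = sum(lab == "mvpa"))
}

# Shared small fixtures ------------------------------------------------------

# A hand-built schedule whose composition is on the 5-min grid.
fixture_schedule <- function(sleep = 590, sed = 485, lpa = 280, mvpa = 85,
                             seed = 99, awakening_min = 0) {
  withr::with_seed(seed, make_day_schedule(
    c(sleep = sleep, sed = sed, lpa = lpa, mvpa = mvpa),
    awakening_min = awakening_min
  ))
}

zero_bias <- function(day_sd = 0, mvpa_shift_min = 0, lpa_to_sed_min = 0,
                      sleep_extend_min = 0, ...) {
  bias_params(mvpa_shift_min = mvpa_shift_min, lpa_to_sed_min = lpa_to_sed_min,
              sleep_extend_min = sleep_extend_min, day_sd = day_sd, ...)
}

comp_cols <- paste0(c("sleep", "sed", "lpa", "mvpa"), "_min")
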