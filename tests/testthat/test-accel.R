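test_that("signal vector magnitude handles the canonical cases", {
  rec <- tibble::tibble(
    time_s = 0:2,
    ax_g = c(0, 0.6, 3), ay_g = c(0, 0.8, 4), az_g = c(1, 0, 0)
  )
  expect_equal(compute_svm(rec)$svm, c(0, 0, 4))
})

test_that("svm is non-negative and invariant to axis permutation and sign", {
  withr::with_seed(4, {
    a <- matrix(rnorm(60), ncol = 3)
    rec <- tibble::tibble(time_s = 1:20, ax_g = a[, 1], ay_g = a[, 2], az_g = a[, 3])
    base <- compute_svm(rec)$svm
    expect_true(all(base >= 0))
    perm <- tibble::tibble(time_s = 1:20, ax_g = a[, 3], ay_g = -a[, 1], az_g = a[, 2])
    expect_equal(compute_svm(perm)$svm, base)
  })
})

test_that("non-finite samples are reported with their timestamp", {
  rec <- tibble::tibble(time_s = c(1, 2), ax_g = c(0, NA), ay_g = 0, az_g = 1)
  expect_error(compute_svm(rec), "time_s = 2")
})

test_that("epoch aggregation is mean-SVM times 60 and rate-invariant", {
  mk <- function(hz, svm_g, minutes = 2) {
    n <- hz * 60 * minutes
    t <- seq(0, by = 1 / hz, length.out = n)
    tibble::tibble(time_s = t, svm = rep(svm_g, n))
  }
  e50 <- aggregate_epochs(mk(50, 0.1), 50)
  expect_equal(e50$value[1:2], c(6, 6))
  e5 <- aggregate_epochs(mk(5, 0.1), 5)
  expect_equal(e5$value[1:2], c(6, 6))
  zero <- aggregate_epochs(mk(5, 0), 5)
  expect_equal(zero$value[1:2], c(0, 0))
})

test_that("epoch values match brute-force re-summation on an irregular fixture", {
  withr::with_seed(8, {
    t <- sort(runif(4000, 0, 600))
    svm <- rexp(4000, 10)
  })
  got <- aggregate_epochs(tibble::tibble(time_s = t, svm = svm), 10)
  want <- oracle_epoch_values(t, svm)
  # the trailing minute is partially covered at 10 Hz and gets dropped
  last <- max(floor(t / 60))
  keep <- setdiff(which(!is.na(want)), last + 1)
  expect_equal(got$value[keep], want[keep], tolerance = 1e-12)
  expect_true(is.na(got$value[last + 1]))
})

test_that("minutes without samples inside the span become missing epochs", {
  t <- c(seq(0, 59.9, by = 0.2), seq(120, 179.9, by = 0.2))
  df <- tibble::tibble(time_s = t, svm = 0.05)
  e <- aggregate_epochs(df, 5)
  expect_false(is.na(e$value[1]))
  expect_true(is.na(e$value[2]))
  expect_false(is.na(e$value[3]))
})

make_epochs <- function(value = 1) {
  tibble::tibble(minute = 0:1439, value = value)
}

test_that("minute labelling follows sleep, non-wear, then inclusive cut-points", {
  cuts <- cut_points(3.4, 15.1)
  log <- list(bed_time = 1320, getup_time = 420,
              removals = tibble::tibble(start = 600, end = 660, reason = "other"))
  e <- make_epochs(15.1)  # exactly at the MVPA threshold
  lab <- label_day(e, log, cuts)
  expect_equal(nrow(lab), 1440)
  expect_equal(sum(lab$label == "sleep"), 420 + 120)
  expect_equal(sum(lab$label == "nonwear"), 60)
  expect_true(all(lab$label[lab$minute >= 660 & lab$minute < 1320] == "mvpa"))
  # boundary below the threshold is LPA; below sed/lpa cut is sedentary
  lab2 <- label_day(make_epochs(15.0999), log, cuts)
  expect_true(all(lab2$label[lab2$minute == 700] == "lpa"))
  lab3 <- label_day(make_epochs(3.39), log, cuts)
  expect_true(all(lab3$label[lab3$minute == 700] == "sed"))
})

test_that("a whole-day sleep window yields 1440 sleep minutes", {
  log <- list(bed_time = 720, getup_time = 720,
              removals = tibble::tibble(start = numeric(0), end = numeric(0),
                                        reason = character(0)))
  lab <- label_day(make_epochs(5), log)
  expect_equal(sum(lab$label == "sleep"), 1440)
})

test_that("sleep wins over logged removals inside the window", {
  log <- list(bed_time = 1320, getup_time = 420,
              removals = tibble::tibble(start = 100, end = 500, reason = "other"))
  lab <- label_day(make_epochs(5), log)
  expect_true(all(lab$label[lab$minute < 420] == "sleep"))
  expect_true(all(lab$label[lab$minute >= 420 & lab$minute < 500] == "nonwear"))
})

test_that("missing-sample minutes are non-wear by default, an error in strict mode", {
  e <- make_epochs(5)
  e$value[700:720 + 1] <- NA
  log <- list(bed_time = 1320, getup_time = 420,
              removals = tibble::tibble(start = numeric(0), end = numeric(0),
                                        reason = character(0)))
  lab <- label_day(e, log)
  expect_equal(sum(lab$label == "nonwear"), 21)
  expect_error(label_day(e, log, strict_log_only = TRUE), "strict mode")
  expect_error(label_day(e, NULL), "wear log missing")
})

test_that("labelling conserves all 1440 minutes", {
  log <- list(bed_time = 1300, getup_time = 400,
              removals = tibble::tibble(start = 500, end = 540, reason = "sports"))
  e <- make_epochs(5)
  e$value[800:850] <- NA
  lab <- label_day(e, log)
  comp <- day_composition(lab)
  expect_equal(comp$sleep_min + comp$sed_min + comp$lpa_min + comp$mvpa_min +
                 comp$nonwear_min, 1440)
})

test_that("sports non-wear is replaced 40/40/20 with exact fractions", {
  base <- tibble::tibble(participant = "P", date = NA, weekend = FALSE,
                         sleep_min = 540, sed_min = 500, lpa_min = 250,
                         mvpa_min = 90, nonwear_min = 60)
  log60 <- list(bed_time = 1380, getup_time = 420,
                removals = tibble::tibble(start = 600, end = 660, reason = "sports"))
  out <- replace_sport_nonwear(base, log60)
  expect_equal(out$mvpa_min, 90 + 24)
  expect_equal(out$lpa_min, 250 + 24)
  expect_equal(out$sed_min, 500 + 12)
  expect_equal(out$nonwear_min, 0)
  # 25-minute removal gives exact fractional minutes
  base25 <- dplyr::mutate(base, nonwear_min = 25, sed_min = 535)
  log25 <- list(bed_time = 1380, getup_time = 420,
                removals = tibble::tibble(start = 600, end = 625, reason = "sports"))
  out25 <- replace_sport_nonwear(base25, log25)
  expect_equal(out25$mvpa_min, 100)
  expect_equal(out25$lpa_min, 260)
  expect_equal(out25$sed_min, 540)
  # non-sports reasons and zero-length removals are untouched
  logo <- list(bed_time = 1380, getup_time = 420,
               removals = tibble::tibble(start = 600, end = 660, reason = "forgot"))
  expect_equal(replace_sport_nonwear(base, logo), base)
  # total is conserved in every case
  for (o in list(out, out25)) {
    expect_equal(o$sleep_min + o$sed_min + o$lpa_min + o$mvpa_min + o$nonwear_min, 1440)
  }
})

test_that("day validity bounds are inclusive and monotone in non-wear", {
  mk <- function(nonwear, waking) {
    tibble::tibble(sleep_min = 1440 - nonwear - waking, sed_min = waking,
                   lpa_min = 0, mvpa_min = 0, nonwear_min = nonwear)
  }
  expect_true(day_is_valid(mk(360, 600)))
  expect_false(day_is_valid(mk(361, 600)))
  expect_false(day_is_valid(mk(360, 599)))
  # moving a wear minute into non-wear can never rescue an invalid day
  withr::with_seed(2, {
    for (i in 1:20) {
      nw <- sample(0:500, 1); wk <- sample(400:900, 1)
      if (nw + wk > 1440) next
      d <- mk(nw, wk)
      worse <- mk(nw + 1, wk - 1)
      if (!day_is_valid(d)) expect_false(day_is_valid(worse))
    }
  })
})

test_that("participant validity needs four valid days including a weekend day", {
  mk_days <- function(valid, weekend) tibble::tibble(valid = valid, weekend = weekend)
  expect_false(participant_is_valid(mk_days(rep(TRUE, 4), rep(FALSE, 4))))
  expect_true(participant_is_valid(mk_days(rep(TRUE, 4), c(FALSE, FALSE, FALSE, TRUE))))
  expect_false(participant_is_valid(mk_days(c(TRUE, TRUE, TRUE, FALSE), c(F, F, F, T))))
  # an invalid weekend day does not count towards the weekend requirement
  expect_false(participant_is_valid(mk_days(c(T, T, T, T, FALSE), c(F, F, F, F, TRUE))))
  expect_false(participant_is_valid(tibble::tibble(valid = logical(0), weekend = logical(0))))
})

test_that("closure rescales to 1440 and rejects zero wear", {
  got <- normalize_to_1440(tibble::tibble(
    sleep_min = 580, sed_min = 480, lpa_min = 270, mvpa_min = 86
  ))
  expect_equal(round(unlist(got), 2),
               c(sleep_min = 589.83, sed_min = 488.14, lpa_min = 274.58,
                 mvpa_min = 87.46))
  expect_equal(sum(unlist(got)), 1440, tolerance = 1e-9)
  already <- tibble::tibble(sleep_min = 600, sed_min = 500, lpa_min = 250, mvpa_min = 90)
  expect_equal(normalize_to_1440(already), already)
  expect_error(normalize_to_1440(tibble::tibble(
    sleep_min = 0, sed_min = 0, lpa_min = 0, mvpa_min = 0
  )), "zero total wear")
})

test_that("noise-controlled synthetic days round-trip within one minute per behaviour", {
  dev <- device_params(sampling_rate_hz = 0.2)
  for (seed in c(3, 17)) {
    sched <- fixture_schedule(seed = seed)
    truth <- schedule_truth(sched$segments)
    raw <- generate_raw_day(sched, dev, seed = seed)
    comp <- process_accel_day(raw$recording, raw$wear_log, 0.2, cuts = dev$cuts)
    got <- c(comp$sleep_min, comp$sed_min, comp$lpa_min, comp$mvpa_min)
    expect_true(all(abs(got - unname(truth)) <= 1))
  }
})
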