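# Cohort, raw-signal and diary generators: invariants and determinism.

test_that("schedules tile the day exactly with grid-aligned segments", {
  withr::with_seed(5, {
    for (i in 1:10) {
      comp <- as.numeric(timeusecoda:::rdirichlet_around(c(0.4, 0.33, 0.2, 0.07), 0.01)) * 1440
      names(comp) <- c("sleep", "sed", "lpa", "mvpa")
      s <- make_day_schedule(comp)
      segs <- s$segments
      expect_equal(sum(segs$duration), 1440)
      expect_true(all(segs$duration >= 5 & segs$duration %% 5 == 0))
      expect_equal(segs$start, cumsum(c(0, utils::head(segs$duration, -1))))
      # window consistent with the sleep placed at the day edges
      expect_equal(s$getup_time + (1440 - s$bed_time),
                   schedule_truth(segs)[["sleep"]])
    }
  })
})

test_that("a stationary night-only device reads exactly 1 g", {
  sched <- list(
    segments = tibble::tibble(behaviour = "sleep", start = 0, duration = 1440,
                              wear = TRUE, reason = NA_character_),
    bed_time = 720, getup_time = 720
  )
  dev <- device_params(sampling_rate_hz = 0.5,
                       svm_bands = list(sleep = c(0, 0), sed = c(0.5, 3),
                                        lpa = c(4.5, 13.5), mvpa = c(16, 40)))
  raw <- generate_raw_day(sched, dev, seed = 2)
  norms <- sqrt(raw$recording$ax_g^2 + raw$recording$ay_g^2 + raw$recording$az_g^2)
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-12)
})

test_that("a full MVPA hour is classified MVPA epoch by epoch downstream", {
  sched <- list(
    segments = tibble::tibble(
      behaviour = c("sleep", "sed", "mvpa", "sed", "sleep"),
      start = c(0, 420, 600, 660, 1320),
      duration = c(420, 180, 60, 660, 120),
      wear = TRUE, reason = NA_character_
    ),
    bed_time = 1320, getup_time = 420
  )
  dev <- device_params(sampling_rate_hz = 0.2)
  raw <- generate_raw_day(sched, dev, seed = 31)
  epochs <- aggregate_epochs(compute_svm(raw$recording), 0.2)
  lab <- label_day(epochs, raw$wear_log, dev$cuts)
  expect_true(all(lab$label[lab$minute >= 600 & lab$minute < 660] == "mvpa"))
})

test_that("removal intervals and reasons copy through to the wear log", {
  sched <- fixture_schedule()
  sched$segments <- timeusecoda:::mark_nonwear(sched$segments, 620, 680, "sports")
  raw <- generate_raw_day(sched, device_params(sampling_rate_hz = 0.2), seed = 4)
  rem <- raw$wear_log$removals
  expect_equal(nrow(rem), 1)
  expect_equal(rem$start, 620)
  expect_equal(rem$end, 680)
  expect_equal(rem$reason, "sports")
  # no samples emitted while the device is off
  expect_false(any(raw$recording$time_s >= 620 * 60 & raw$recording$time_s < 680 * 60))
  # gravity mode instead emits a flat 1-g signal there
  rawg <- generate_raw_day(sched, device_params(sampling_rate_hz = 0.2,
                                                nonwear_mode = "gravity"), seed = 4)
  off <- rawg$recording$time_s >= 620 * 60 & rawg$recording$time_s < 680 * 60
  expect_true(any(off))
  norms <- with(rawg$recording[off, ], sqrt(ax_g^2 + ay_g^2 + az_g^2))
  expect_equal(norms, rep(1, sum(off)), tolerance = 1e-12)
})

test_that("intensity bands touching a cut-point are rejected", {
  expect_error(
    device_params(svm_bands = list(sleep = c(0, 0.3), sed = c(0.5, 3.5),
                                   lpa = c(4.5, 13.5), mvpa = c(16, 40))),
    "overlaps a cut-point"
  )
  expect_error(
    device_params(svm_bands = list(sleep = c(0, 0.3), sed = c(0.5, 3),
                                   lpa = c(4.5, 15.1), mvpa = c(16, 40))),
    "overlaps a cut-point"
  )
})

test_that("raw-day generation is deterministic given a seed", {
  sched <- fixture_schedule()
  a <- generate_raw_day(sched, device_params(sampling_rate_hz = 0.5), seed = 77)
  b <- generate_raw_day(sched, device_params(sampling_rate_hz = 0.5), seed = 77)
  expect_identical(a, b)
})

test_that("cohort generation is deterministic and tiles every day", {
  cfg <- cohort_config(n_participants = 8, days_per_participant = 4, seed = 13)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1$days), 32)
  expect_true(all(rowSums(co1$days[, comp_cols]) == 1440))
  by_day <- dplyr::summarise(
    dplyr::group_by(co1$segments, .data$participant, .data$date),
    tot = sum(.data$duration), .groups = "drop"
  )
  expect_true(all(by_day$tot == 1440))
})

test_that("zero dispersion reproduces the level mean composition exactly", {
  mean_comp <- c(sleep = 590, sed = 485, lpa = 280, mvpa = 85)
  cfg <- cohort_config(
    n_participants = 4, days_per_participant = 2,
    true_composition = mean_comp,
    composition_by = list(),  # no level overrides
    participant_dispersion = 0, day_dispersion = 0, removal_prob = 0, seed = 3
  )
  co <- generate_cohort(cfg)
  for (i in seq_len(nrow(co$days))) {
    expect_equal(unlist(co$days[i, comp_cols]), unname(mean_comp),
                 ignore_attr = TRUE)
  }
})

test_that("cohort characteristic means converge to the configured targets", {
  cfg <- cohort_config(n_participants = 2000, days_per_participant = 1,
                       recall_days_per_participant = 1, seed = 42)
  co <- generate_cohort(cfg)
  p <- co$participants
  se <- function(sd) 3 * sd / sqrt(nrow(p))
  expect_lt(abs(mean(p$sex == "female") - 0.67), 3 * sqrt(0.67 * 0.33 / nrow(p)))
  expect_lt(abs(mean(p$age) - 10.0), se(0.3) + 0.05)       # rounded to 0.1 y
  expect_lt(abs(mean(p$zbmi) - 0.17), se(1.20) + 0.005)    # rounded to 0.01
  expect_lt(abs(mean(p$vo2max) - 40.1), se(6.6) + 0.05)
  expect_lt(abs(mean(p$pat, na.rm = TRUE) - 126), se(9) + 0.5)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(true_composition = c(sleep = -10, sed = 700,
                                                  lpa = 600, mvpa = 150)),
               "strictly positive")
  expect_error(cohort_config(sex_prob = c(female = 0.5, male = 0.3)),
               "sum to 1")
})

test_that("zero-bias diaries on the grid reproduce the true composition", {
  sched <- fixture_schedule()
  truth <- schedule_truth(sched$segments)
  diary <- generate_recall_day(sched, zero_bias(), seed = 5)
  comp <- compile_recall_day(diary)
  expect_equal(unlist(comp), unname(truth), ignore_attr = TRUE)
})

test_that("a forced MVPA shift moves exactly that time from LPA", {
  sched <- fixture_schedule()
  truth <- schedule_truth(sched$segments)
  diary <- generate_recall_day(sched, zero_bias(mvpa_shift_min = 30), seed = 5)
  comp <- compile_recall_day(diary)
  expect_equal(comp$mvpa_min, truth[["mvpa"]] + 30)
  expect_equal(comp$lpa_min, truth[["lpa"]] - 30)
  expect_equal(comp$sleep_min, truth[["sleep"]])
  expect_equal(comp$sed_min, truth[["sed"]])
})

test_that("awakenings inside the sleep window are absorbed into reported sleep", {
  sched <- fixture_schedule(seed = 12, awakening_min = 20)
  truth <- schedule_truth(sched$segments)
  diary <- generate_recall_day(sched, zero_bias(absorb_awakenings = TRUE), seed = 9)
  comp <- compile_recall_day(diary)
  expect_equal(comp$sleep_min, truth[["sleep"]] + 20)
  expect_equal(comp$lpa_min, truth[["lpa"]] - 20)
  # with absorption off the truth is reported
  diary2 <- generate_recall_day(sched, zero_bias(absorb_awakenings = FALSE), seed = 9)
  expect_equal(compile_recall_day(diary2)$sleep_min, truth[["sleep"]])
})

test_that("over-large biases clamp at the 5-minute floor with a warning", {
  sched <- fixture_schedule()
  expect_warning(
    diary <- generate_recall_day(sched, zero_bias(mvpa_shift_min = 1000), seed = 1),
    "clamped"
  )
  comp <- compile_recall_day(diary)
  expect_equal(comp$lpa_min, 5)
  expect_equal(sum(unlist(comp)), 1440)
})

test_that("generated diaries always tile 1440 minutes at 5-minute resolution", {
  withr::with_seed(30, {
    for (i in 1:8) {
      comp <- as.numeric(timeusecoda:::rdirichlet_around(c(0.4, 0.33, 0.2, 0.07), 0.005)) * 1440
      names(comp) <- c("sleep", "sed", "lpa", "mvpa")
      sched <- make_day_schedule(comp)
      diary <- generate_recall_day(sched, bias_params(), seed = i)
      expect_silent(timeusecoda:::validate_diary_tiling(diary))
      expect_equal(sum(unlist(compile_recall_day(diary))), 1440)
    }
  })
})
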