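#' Cut-points for classifying 1-minute epochs
#'
#' Waking wear epochs are classified from their summed signal vector
#' magnitude (SVM, g.min per 60-s epoch) into sedentary (< 1.5 METs), light
#' (1.5-2.99 METs) and moderate-to-vigorous (>= 3 METs) intensity. The MET
#' bands are fixed by convention; the SVM thresholds realising them depend
#' on device, wear site and population. Defaults follow the Phillips et al.
#' wrist-worn GENEActiv children's cut-points, rescaled to this package's
#' rate-invariant epoch convention (mean per-sample SVM times 60).
#'
#' The upper band is inclusive at the threshold (>= 3 METs is MVPA); the
#' sedentary/light boundary is inclusive on the light side.
#'
#' @param sed_lpa Threshold between sedentary and LPA (g.min/epoch).
#' @param lpa_mvpa Threshold between LPA and MVPA (g.min/epoch).
#' @return A `cut_points` list.
#' @export
cut_points <- function(sed_lpa = 3.4, lpa_mvpa = 15.1) {
  if (!(is.numeric(sed_lpa) && is.numeric(lpa_mvpa) &&
        0 < sed_lpa && sed_lpa < lpa_mvpa)) {
    abort("cut-points must satisfy 0 < sed_lpa < lpa_mvpa")
  }
  structure(list(sed_lpa = sed_lpa, lpa_mvpa = lpa_mvpa), class = "cut_points")
}

#' Per-sample signal vector magnitude
#'
#' SVM is the absolute deviation of the Euclidean norm of the triaxial
#' acceleration from 1 g: `|sqrt(ax^2 + ay^2 + az^2) - 1|`. A stationary
#' device reads 0 whatever its orientation.
#'
#' @param recording A data frame with columns `time_s`, `ax_g`, `ay_g`,
#'   `az_g` (a raw triaxial recording in g, times strictly increasing).
#' @return The recording with an added `svm` column (g).
#' @export
compute_svm <- function(recording) {
  req <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(req %in% names(recording))) {
    abort("`recording` needs columns time_s, ax_g, ay_g, az_g")
  }
  a <- as.matrix(recording[, c("ax_g", "ay_g", "az_g")])
  bad <- !is.finite(rowSums(a))
  if (any(bad)) {
    abort(sprintf(
      "non-finite acceleration sample(s), first at time_s = %s",
      format(recording$time_s[which(bad)[1]])
    ))
  }
  dplyr::mutate(as_tibble(recording), svm = abs(sqrt(rowSums(a^2)) - 1))
}

#' Aggregate per-sample SVM into 1-minute epochs
#'
#' Each epoch value is the mean per-sample SVM over the minute times 60
#' (g.min), which makes epoch values invariant to the sampling rate: a
#' constant per-sample SVM of `s` g always yields `60 s` g.min. Minutes with
#' no samples inside the recording span are returned as `NA` (candidate
#' non-wear). A trailing minute covered by fewer samples than a full minute
#' at the nominal rate is dropped.
#'
#' @param svm_data Output of [compute_svm()] (needs `time_s` and `svm`).
#' @param sampling_rate_hz Nominal sampling rate (> 0).
#' @return A tibble `minute` (0-1439), `value` (g.min, `NA` where missing).
#' @export
aggregate_epochs <- function(svm_data, sampling_rate_hz) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive")
  }
  if (nrow(svm_data) == 0 || diff(range(svm_data$time_s)) < 60) {
    abort("recording must span at least one minute")
  }
  minute <- floor(svm_data$time_s / 60)
  counts <- tapply(svm_data$svm, minute, length)
  sums <- tapply(svm_data$svm, minute, sum)
  got <- as.integer(names(sums))
  epochs <- tibble(minute = 0:(MINUTES_PER_DAY - 1L), value = NA_real_)
  idx <- match(got, epochs$minute)
  keep <- !is.na(idx)
  epochs$value[idx[keep]] <- (sums / counts)[keep] * 60
  # drop a partial trailing minute (fewer samples than a full minute holds)
  last <- max(got)
  expected <- sampling_rate_hz * 60
  if (counts[as.character(last)] < expected && last <= MINUTES_PER_DAY - 1L) {
    epochs$value[epochs$minute == last] <- NA_real_
  }
  epochs
}

#' Label every minute of a day
#'
#' Applies the processing order used for wrist accelerometry with paper
#' wear logs: (1) minutes inside the logged sleep window (from bed time to
#' get-up time) are sleep; (2) logged removal intervals in waking time are
#' non-wear, as are waking minutes with no recorded samples (unless
#' `strict_log_only`); (3) remaining waking wear minutes are classified by
#' cut-points: sedentary below `sed_lpa`, LPA in `[sed_lpa, lpa_mvpa)`,
#' MVPA at or above `lpa_mvpa`.
#'
#' The sleep window is expressed within the midnight-to-midnight day: minutes
#' before `getup_time` and from `bed_time` onwards are sleep. Logged removals
#' overlapping the sleep window are ignored there (sleep is applied first).
#'
#' @param epochs Epoch series from [aggregate_epochs()].
#' @param wear_log A one-day wear log: list or one-row data frame with
#'   `bed_time`, `getup_time` (minutes of day) and a `removals` tibble
#'   (`start`, `end`, `reason`), as produced by [generate_raw_day()] or
#'   [read_wear_log()].
#' @param cuts A [cut_points()] object.
#' @param strict_log_only If `TRUE`, missing-sample minutes outside logged
#'   removals raise an error instead of being auto-labelled non-wear.
#' @return A tibble `minute`, `value`, `label` with 1440 rows; `label` in
#'   `sleep`, `nonwear`, `sed`, `lpa`, `mvpa`.
#' @export
label_day <- function(epochs, wear_log, cuts = cut_points(),
                      strict_log_only = FALSE) {
  if (is.null(wear_log) || is.null(wear_log$bed_time)) {
    abort("wear log missing for this day")
  }
  stopifnot(nrow(epochs) == MINUTES_PER_DAY)
  m <- epochs$minute
  label <- rep(NA_character_, MINUTES_PER_DAY)
  sleep <- m < wear_log$getup_time | m >= wear_log$bed_time
  label[sleep] <- "sleep"
  removals <- wear_log$removals
  if (!is.null(removals) && nrow(removals) > 0) {
    for (i in seq_len(nrow(removals))) {
      inr <- m >= removals$start[i] & m < removals$end[i] & !sleep
      label[inr] <- "nonwear"
    }
  }
  open <- is.na(label)
  missing <- open & is.na(epochs$value)
  if (any(missing)) {
    if (strict_log_only) {
      abort(sprintf(
        "%d waking minute(s) without samples and no logged removal (strict mode)",
        sum(missing)
      ))
    }
    label[missing] <- "nonwear"
  }
  open <- is.na(label)
  v <- epochs$value[open]
  label[open] <- dplyr::case_when(
    v >= cuts$lpa_mvpa ~ "mvpa",
    v >= cuts$sed_lpa ~ "lpa",
    TRUE ~ "sed"
  )
  tibble(minute = m, value = epochs$value, label = label)
}

#' Summarise a labelled day into minutes per behaviour
#'
#' @param labelled Output of [label_day()].
#' @param date,weekend,participant Metadata carried into the row.
#' @return A one-row tibble: `participant`, `date`, `weekend`, `sleep_min`,
#'   `sed_min`, `lpa_min`, `mvpa_min`, `nonwear_min` (summing to 1440).
#' @export
day_composition <- function(labelled, date = NA, weekend = NA,
                            participant = NA_character_) {
  counts <- table(factor(labelled$label, levels = c(BEHAVIOURS, "nonwear")))
  tibble(
    participant = participant, date = date, weekend = weekend,
    sleep_min = as.numeric(counts[["sleep"]]),
    sed_min = as.numeric(counts[["sed"]]),
    lpa_min = as.numeric(counts[["lpa"]]),
    mvpa_min = as.numeric(counts[["mvpa"]]),
    nonwear_min = as.numeric(counts[["nonwear"]])
  )
}

#' Replace sports non-wear with a representative activity mix
#'
#' Children commonly remove wrist devices for organised sport. Removal
#' intervals logged with reason `"sports"` are re-attributed as 40% MVPA,
#' 40% LPA and 20% sedentary time; fractional minutes are carried in the
#' daily totals rather than re-labelled per minute. Other non-wear is left
#' untouched. The 1440-minute day total is conserved.
#'
#' @param comp A day-composition row from [day_composition()].
#' @param wear_log The day's wear log (for removal reasons).
#' @return The composition row with sports non-wear redistributed.
#' @export
replace_sport_nonwear <- function(comp, wear_log) {
  removals <- wear_log$removals
  if (is.null(removals) || nrow(removals) == 0) return(comp)
  sports <- removals[!is.na(removals$reason) & removals$reason == "sports", , drop = FALSE]
  if (nrow(sports) == 0) return(comp)
  # only the portion actually labelled nonwear (outside the sleep window)
  waking <- function(s, e, log) {
    mins <- s:(e - 1)
    sum(mins >= log$getup_time & mins < log$bed_time)
  }
  d <- sum(mapply(waking, sports$start, sports$end, MoreArgs = list(log = wear_log)))
  d <- min(d, comp$nonwear_min)
  dplyr::mutate(comp,
    mvpa_min = .data$mvpa_min + 0.4 * d,
    lpa_min = .data$lpa_min + 0.4 * d,
    sed_min = .data$sed_min + 0.2 * d,
    nonwear_min = .data$nonwear_min - d
  )
}

#' Day-level validity rule
#'
#' A day is valid if it has at most 6 h (360 min) of non-wear and at least
#' 10 h (600 min) of waking wear time (sedentary + LPA + MVPA). Both bounds
#' are inclusive.
#'
#' @param comp Day-composition row(s).
#' @return Logical vector, one flag per row.
#' @export
day_is_valid <- function(comp) {
  comp$nonwear_min <= 360 &
    (comp$sed_min + comp$lpa_min + comp$mvpa_min) >= 600
}

#' Participant-level validity rule
#'
#' Valid if at least 4 valid days, including at least one valid weekend day.
#'
#' @param days Day-composition rows for one participant, with logical
#'   columns `valid` and `weekend`.
#' @return A single logical flag.
#' @export
participant_is_valid <- function(days) {
  if (is.null(days) || nrow(days) == 0) return(FALSE)
  ok <- days$valid
  sum(ok) >= 4 && any(days$weekend[ok])
}

#' Close a day composition to 1440 minutes
#'
#' Accelerometer non-wear is accounted for by linearly rescaling the four
#' behaviour durations so they collectively sum to 1440 min (24 h).
#'
#' @param data Data frame with columns `sleep_min`, `sed_min`, `lpa_min`,
#'   `mvpa_min`; other columns pass through.
#' @return `data` with the four columns rescaled to sum to 1440 per row.
#' @export
normalize_to_1440 <- function(data) {
  cols <- paste0(BEHAVIOURS, "_min")
  x <- as.matrix(data[, cols])
  assert_minutes(x, "behaviour durations")
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    abort("cannot close a day with zero total wear time")
  }
  data[cols] <- x * (MINUTES_PER_DAY / tot)
  as_tibble(data)
}

#' Process one raw participant-day end to end
#'
#' Convenience wrapper: SVM, epochs, labelling, sports replacement,
#' validity. Does not close to 1440; see [normalize_to_1440()].
#'
#' @inheritParams compute_svm
#' @inheritParams label_day
#' @param sampling_rate_hz Nominal sampling rate of `recording`.
#' @param date,weekend,participant Metadata for the output row.
#' @return A one-row day composition with a `valid` flag.
#' @export
process_accel_day <- function(recording, wear_log, sampling_rate_hz,
                              cuts = cut_points(), date = NA, weekend = NA,
                              participant = NA_character_,
                              strict_log_only = FALSE) {
  svm <- compute_svm(recording)
  epochs <- aggregate_epochs(svm, sampling_rate_hz)
  labelled <- label_day(epochs, wear_log, cuts, strict_log_only)
  comp <- day_composition(labelled, date, weekend, participant)
  comp <- replace_sport_nonwear(comp, wear_log)
  dplyr::mutate(comp, valid = day_is_valid(comp))
}
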