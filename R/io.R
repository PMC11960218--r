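# CSV dialects shared by the pipeline stages. All readers return tibbles;
# all writers are plain readr CSV so runs are reproducible byte for byte.

#' Read and write the raw-signal CSV dialect
#'
#' Columns `time_s, ax_g, ay_g, az_g`: seconds since midnight and triaxial
#' acceleration in g.
#'
#' @param recording Recording tibble.
#' @param path File path.
#' @return `read_raw_recording()` returns the recording tibble.
#' @export
write_raw_recording <- function(recording, path) {
  readr::write_csv(recording, path)
  invisible(path)
}

#' @rdname write_raw_recording
#' @export
read_raw_recording <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), ax_g = readr::col_double(),
    ay_g = readr::col_double(), az_g = readr::col_double()
  ))
}

#' Read and write the wear-log CSV dialect
#'
#' One row per removal interval with bed/get-up times repeated:
#' `date,bed_time,getup_time,removal_start,removal_end,reason` (HH:MM). A
#' day without removals is a single row with empty removal fields.
#'
#' @param wear_log Wear-log list (as produced by [generate_raw_day()]).
#' @param path File path.
#' @return `read_wear_log()` returns the wear-log list.
#' @export
write_wear_log <- function(wear_log, path) {
  rem <- wear_log$removals
  if (is.null(rem) || nrow(rem) == 0) {
    rem <- tibble(start = NA_real_, end = NA_real_, reason = NA_character_)
  }
  readr::write_csv(tibble(
    date = as.character(wear_log$date),
    bed_time = minute_to_hhmm(wear_log$bed_time),
    getup_time = minute_to_hhmm(wear_log$getup_time),
    removal_start = ifelse(is.na(rem$start), "", minute_to_hhmm(rem$start)),
    removal_end = ifelse(is.na(rem$end), "", minute_to_hhmm(rem$end)),
    reason = ifelse(is.na(rem$reason), "", rem$reason)
  ), path)
  invisible(path)
}

#' @rdname write_wear_log
#' @export
read_wear_log <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  has_rem <- !is.na(df$removal_start) & df$removal_start != ""
  list(
    date = as.Date(df$date[1]),
    bed_time = hhmm_to_minute(df$bed_time[1]),
    getup_time = hhmm_to_minute(df$getup_time[1]),
    removals = tibble(
      start = hhmm_to_minute(df$removal_start[has_rem]),
      end = hhmm_to_minute(df$removal_end[has_rem]),
      reason = df$reason[has_rem]
    )
  )
}

#' Read and write the recall-diary CSV dialect
#'
#' Columns `date,start_min,end_min,activity,met`; half-open minute
#' intervals `[start, end)`.
#'
#' @param diary Diary tibble (see [generate_recall_day()]).
#' @param path File path.
#' @param date Date recorded with each segment.
#' @return `read_diary()` returns the diary tibble.
#' @export
write_diary <- function(diary, path, date = NA) {
  out <- dplyr::mutate(diary, date = as.character(date), .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_diary
#' @export
read_diary <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), start_min = readr::col_double(),
    end_min = readr::col_double(), activity = readr::col_character(),
    met = readr::col_double()
  ))
}

#' Write the per-day composition CSV dialect
#'
#' `participant,date,weekend,sleep_min,sed_min,lpa_min,mvpa_min,nonwear_min,valid`.
#'
#' @param days Day-composition tibble.
#' @param path File path.
#' @return `read_day_compositions()` returns the tibble.
#' @export
write_day_compositions <- function(days, path) {
  readr::write_csv(days, path)
  invisible(path)
}

#' @rdname write_day_compositions
#' @export
read_day_compositions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(), date = readr::col_date()
  ))
}

#' Write and read the ground-truth CSV dialect
#'
#' `participant,date,sleep_min,sed_min,lpa_min,mvpa_min` — the true daily
#' behaviour minutes behind a synthetic cohort.
#'
#' @param cohort A [generate_cohort()] result (or any table with those
#'   columns).
#' @param path File path.
#' @return `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(cohort, path) {
  days <- if (inherits(cohort, "cohort")) cohort$days else cohort
  cols <- c("participant", "date", paste0(BEHAVIOURS, "_min"))
  readr::write_csv(days[, cols], path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(), date = readr::col_date()
  ))
}
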