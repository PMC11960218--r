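#' Compile a recall diary day into a 24-hour composition
#'
#' A 24-hour recall diary lists every activity as a half-open minute
#' interval `[start_min, end_min)` with an associated MET (metabolic
#' equivalent) value, at a 5-minute minimum resolution. Minutes of segments
#' whose activity is flagged as sleep count as sleep; remaining minutes are
#' binned by energy expenditure: below 1.5 METs sedentary, 1.5 up to (but
#' excluding) 3 METs light activity, 3 METs and above moderate-to-vigorous
#' activity. Sleep is identified by the activity flag, not its MET, so quiet
#' wakeful rest stays sedentary.
#'
#' @param diary A data frame for one participant-day with columns
#'   `start_min`, `end_min`, `activity`, `met`; segments must tile
#'   `[0, 1440)` exactly, each at least 5 minutes and a multiple of 5.
#' @param sleep_activities Activity labels treated as sleep.
#' @return A one-row tibble `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`
#'   summing to exactly 1440 (no closure step is needed).
#' @export
compile_recall_day <- function(diary, sleep_activities = "sleep") {
  validate_diary_tiling(diary)
  if (any(!is.finite(diary$met)) || any(diary$met <= 0)) {
    abort("diary MET values must be positive")
  }
  dur <- diary$end_min - diary$start_min
  is_sleep <- tolower(diary$activity) %in% tolower(sleep_activities)
  band <- dplyr::case_when(
    is_sleep ~ "sleep",
    diary$met >= 3 ~ "mvpa",
    diary$met >= 1.5 ~ "lpa",
    TRUE ~ "sed"
  )
  mins <- tapply(dur, factor(band, levels = BEHAVIOURS), sum, default = 0)
  tibble(
    sleep_min = as.numeric(mins[["sleep"]]), sed_min = as.numeric(mins[["sed"]]),
    lpa_min = as.numeric(mins[["lpa"]]), mvpa_min = as.numeric(mins[["mvpa"]])
  )
}

# Diary segments must tile [0, 1440) exactly: ordered, gapless, no overlap,
# durations >= 5 min and on the 5-min grid.
validate_diary_tiling <- function(diary) {
  req <- c("start_min", "end_min", "activity", "met")
  if (!all(req %in% names(diary))) {
    abort("diary needs columns start_min, end_min, activity, met")
  }
  d <- diary[order(diary$start_min), ]
  dur <- d$end_min - d$start_min
  if (any(dur < 5) || any(dur %% 5 != 0)) {
    abort("diary segments must be >= 5 min and multiples of 5")
  }
  edges_ok <- d$start_min[1] == 0 && d$end_min[nrow(d)] == MINUTES_PER_DAY
  joins <- if (nrow(d) > 1) d$start_min[-1] - d$end_min[-nrow(d)] else 0
  if (!edges_ok || any(joins != 0)) {
    bad <- which(joins != 0)
    detail <- if (length(bad)) {
      paste(sprintf(
        "[%d,%d) -> [%d,%d)", d$start_min[bad], d$end_min[bad],
        d$start_min[bad + 1], d$end_min[bad + 1]
      ), collapse = ", ")
    } else {
      sprintf("covers [%d,%d)", d$start_min[1], d$end_min[nrow(d)])
    }
    abort(paste0("diary does not tile [0,1440): ", detail))
  }
  invisible(diary)
}

#' Exclude implausibly short self-reported sleep
#'
#' Recall days reporting less than 300 minutes of sleep are removed as
#' implausible for children (the threshold is strict: exactly 300 is kept).
#'
#' @param days Data frame of compiled recall-day compositions with a
#'   `sleep_min` column.
#' @param threshold Minimum plausible sleep, minutes/day.
#' @return The retained rows, with attribute `"exclusions"` (a one-row
#'   tibble: `n_excluded`, `n_retained`, `threshold`).
#' @export
exclude_low_sleep <- function(days, threshold = 300) {
  keep <- days$sleep_min >= threshold
  out <- as_tibble(days[keep, , drop = FALSE])
  attr(out, "exclusions") <- tibble(
    n_excluded = sum(!keep), n_retained = sum(keep), threshold = threshold
  )
  out
}
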