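#' Match recall days with valid accelerometer days by calendar date
#'
#' A participant-day contributes to the comparison only if a recall diary
#' and a *valid* accelerometer day exist for the same participant and date.
#'
#' @param accel_days Data frame of device day compositions with columns
#'   `participant`, `date`, `valid` and the behaviour-minute columns.
#' @param recall_days Data frame of recall day compositions with columns
#'   `participant`, `date` and the behaviour-minute columns.
#' @return A tibble of matched pairs: `participant`, `date`, device
#'   behaviour columns suffixed `_device`, recall columns suffixed `_self`,
#'   plus the device `weekend` flag when present.
#' @export
match_days <- function(accel_days, recall_days) {
  for (side in list(accel = accel_days, recall = recall_days)) {
    key <- paste(side$participant, side$date)
    if (anyDuplicated(key)) {
      abort(sprintf(
        "duplicate (participant, date) rows: %s",
        paste(unique(key[duplicated(key)]), collapse = ", ")
      ))
    }
  }
  comp_cols <- paste0(BEHAVIOURS, "_min")
  keep <- c("participant", "date", intersect("weekend", names(accel_days)), comp_cols)
  a <- dplyr::filter(as_tibble(accel_days), .data$valid)[, keep]
  r <- as_tibble(recall_days)[, c("participant", "date", comp_cols)]
  dplyr::inner_join(a, r, by = c("participant", "date"),
                    suffix = c("_device", "_self"))
}

#' Average matched days into one record per participant
#'
#' Each retained participant gets one "average" device day and one "average"
#' recall day: the arithmetic mean of each behaviour across their matched
#' days, per method (averaging preserves closure). Participants missing any
#' requested characteristic are dropped and reported.
#'
#' @param matched Output of [match_days()].
#' @param participants Participant characteristics table (one row per
#'   participant).
#' @param characteristics Characteristic columns that must be complete;
#'   defaults to all columns of `participants` other than the id and the
#'   academic score (`pat`), whose missingness is handled per model (the
#'   academic-performance model simply uses the reduced n).
#' @return A tibble with one row per participant: characteristics, the 8
#'   averaged composition columns and `n_matched_days`; attribute
#'   `"dropped"` lists participants removed for incomplete characteristics.
#' @export
average_per_participant <- function(matched, participants,
                                    characteristics = NULL) {
  comp_cols <- c(paste0(BEHAVIOURS, "_min_device"), paste0(BEHAVIOURS, "_min_self"))
  averaged <- dplyr::summarise(
    dplyr::group_by(matched, .data$participant),
    dplyr::across(dplyr::all_of(comp_cols), mean),
    n_matched_days = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::inner_join(averaged, as_tibble(participants), by = "participant")
  characteristics <- characteristics %||% setdiff(names(participants),
                                                  c("participant", "pat"))
  complete <- stats::complete.cases(out[, characteristics, drop = FALSE])
  dropped <- out$participant[!complete]
  if (length(dropped)) {
    inform(sprintf("%d participant(s) dropped for incomplete characteristics",
                   length(dropped)))
  }
  res <- out[complete, , drop = FALSE]
  attr(res, "dropped") <- dropped
  res
}
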