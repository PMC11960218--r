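#' Recall reporting-bias parameters
#'
#' Operationalises the mechanisms by which children's 24-hour recalls drift
#' from their true day: durations are remembered in whole blocks of time
#' (epoch effect), physically active play is over-reported at the expense of
#' light activity (desirability effect), light-activity interruptions inside
#' long sedentary blocks are forgotten (homogenisation), reported bed/wake
#' times drift outward into adjacent waking time, and awakenings inside the
#' sleep window are remembered as sleep.
#'
#' Defaults emulate the method differences typical of primary-school
#' cohorts: self-report sleep +37, sedentary +12, LPA -83, MVPA +34 min/day
#' relative to the device (37 from sleep extension against sedentary, 34
#' shifted LPA to MVPA, 49 shifted LPA to sedentary). `day_sd` adds
#' day-to-day noise to each shift so reporting error is not perfectly
#' systematic.
#'
#' @param block_min Recall resolution in minutes (multiple of 5).
#' @param mvpa_shift_min Minutes moved from LPA to MVPA.
#' @param lpa_to_sed_min Minutes moved from LPA to sedentary.
#' @param sleep_extend_min Minutes moved from the donor behaviour to sleep.
#' @param sleep_extend_donor Behaviour donating to sleep extension.
#' @param absorb_awakenings Report awake time inside the sleep window as
#'   sleep.
#' @param day_sd SD of per-day normal jitter applied to each shift.
#' @param met_values Named METs assigned to reported behaviours (sedentary
#'   below 1.5, light below 3, moderate-to-vigorous at or above 3).
#' @return A `bias_params` list.
#' @export
bias_params <- function(block_min = 5,
                        mvpa_shift_min = 34,
                        lpa_to_sed_min = 49,
                        sleep_extend_min = 37,
                        sleep_extend_donor = "sed",
                        absorb_awakenings = TRUE,
                        day_sd = 15,
                        met_values = c(sleep = 0.9, sed = 1.3, lpa = 2.2, mvpa = 4.5)) {
  stopifnot(
    block_min %% 5 == 0, block_min >= 5,
    is.finite(mvpa_shift_min), is.finite(lpa_to_sed_min),
    is.finite(sleep_extend_min), day_sd >= 0,
    sleep_extend_donor %in% BEHAVIOURS,
    setequal(names(met_values), BEHAVIOURS), all(met_values > 0)
  )
  structure(list(
    block_min = block_min, mvpa_shift_min = mvpa_shift_min,
    lpa_to_sed_min = lpa_to_sed_min, sleep_extend_min = sleep_extend_min,
    sleep_extend_donor = sleep_extend_donor,
    absorb_awakenings = absorb_awakenings, day_sd = day_sd,
    met_values = met_values
  ), class = "bias_params")
}

#' Generate a biased recall diary for one day
#'
#' Starts from the true behaviour schedule (what the child actually did,
#' ignoring the device-removal overlay), applies the configured reporting
#' biases, and re-tiles the result into a diary of >= 5-minute segments on
#' the recall block grid summing to exactly 1440 min. Per-behaviour reported
#' totals are preserved exactly through the re-tiling (largest-remainder
#' rounding within each behaviour), so with all biases zero and a true
#' schedule already on the block grid the diary composition equals the true
#' composition.
#'
#' If a shift would push a behaviour below 5 minutes it is clamped there and
#' a warning is issued.
#'
#' @param schedule A schedule list (see [make_day_schedule()],
#'   [cohort_schedule()]).
#' @param bias A [bias_params()] object.
#' @param seed Integer seed for the day's reporting noise.
#' @return A diary tibble `start_min`, `end_min`, `activity`, `met` tiling
#'   `[0, 1440)`.
#' @export
generate_recall_day <- function(schedule, bias = bias_params(), seed = 1L) {
  segs <- dplyr::select(schedule$segments, "behaviour", "start", "duration")
  bed <- schedule$bed_time
  getup <- schedule$getup_time

  # (1) absorb awake time inside the sleep window into reported sleep
  if (bias$absorb_awakenings) {
    inside <- segs$start >= bed | (segs$start + segs$duration) <= getup
    segs$behaviour[inside] <- "sleep"
  }
  true_tot <- schedule_truth(segs)

  # (2) composition-level shifts with per-day jitter
  withr::with_seed(seed, {
    jitter3 <- if (bias$day_sd > 0) stats::rnorm(3, 0, bias$day_sd) else c(0, 0, 0)
    target <- true_tot
    # jittered shifts may go slightly negative (reporting error is not
    # perfectly one-sided); both donor and recipient are kept >= 5 min
    apply_shift <- function(target, amount, from, to) {
      lo <- -(target[[to]] - 5)
      hi <- target[[from]] - 5
      if (amount < lo || amount > hi) {
        warn(sprintf(
          "recall bias clamped: shift %s -> %s of %.0f min exceeds available time",
          from, to, amount
        ))
        amount <- min(max(amount, lo), hi)
      }
      target[[from]] <- target[[from]] - amount
      target[[to]] <- target[[to]] + amount
      target
    }
    target <- apply_shift(target, bias$mvpa_shift_min + jitter3[1], "lpa", "mvpa")
    target <- apply_shift(target, bias$lpa_to_sed_min + jitter3[2], "lpa", "sed")
    target <- apply_shift(target, bias$sleep_extend_min + jitter3[3],
                          bias$sleep_extend_donor, "sleep")
    # snap reported totals to the block grid, preserving the 1440 total
    target <- round_preserving_total(target, bias$block_min, MINUTES_PER_DAY)
    diary <- retile_segments(segs, target, bias$block_min)
  })
  diary$activity <- c(sleep = "sleep", sed = "sedentary", lpa = "light",
                      mvpa = "moderate-vigorous")[diary$behaviour]
  diary$met <- unname(bias$met_values[diary$behaviour])
  tibble(
    start_min = diary$start, end_min = diary$start + diary$duration,
    activity = diary$activity, met = diary$met
  )
}

# Rescale segment durations so each behaviour hits its target total, round
# to the block grid within behaviour (preserving the behaviour total), drop
# empties and re-tile from midnight. Behaviours with a positive target but
# no segments get one new segment appended before the final sleep block.
retile_segments <- function(segs, target, block) {
  segs <- segs[order(segs$start), ]
  for (b in BEHAVIOURS) {
    rows <- which(segs$behaviour == b)
    tot <- sum(segs$duration[rows])
    if (target[[b]] > 0 && length(rows) == 0) {
      at <- if (nrow(segs) > 1) nrow(segs) - 1 else 1
      segs <- dplyr::bind_rows(
        segs[seq_len(at), ],
        tibble(behaviour = b, start = NA_real_, duration = 0),
        segs[-seq_len(at), ]
      )
      rows <- at + 1
      tot <- 0
    }
    if (length(rows) == 0) next
    scaled <- if (tot > 0) segs$duration[rows] * target[[b]] / tot else {
      rep(target[[b]] / length(rows), length(rows))
    }
    segs$duration[rows] <- round_preserving_total(scaled, block, target[[b]])
  }
  segs <- segs[segs$duration > 0, ]
  segs$start <- cumsum(c(0, utils::head(segs$duration, -1)))
  segs
}
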