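#' Device simulation parameters
#'
#' Controls how a ground-truth schedule is rendered as a raw triaxial
#' recording. Each minute of a behaviour draws a target epoch SVM uniformly
#' from that behaviour's band (g.min per 1-min epoch); samples within the
#' minute are white-direction acceleration with Euclidean norm `1 + s/60` g,
#' so the epoch SVM hits the target exactly at any sampling rate. Bands for
#' waking behaviours must lie strictly inside the classifier's cut-point
#' bands, otherwise the ground-truth label of an epoch would be ambiguous.
#'
#' @param sampling_rate_hz Samples per second (>= 1/60 so every minute holds
#'   a sample). 50 Hz matches the wrist device emulated; lower rates give
#'   identical epoch values by construction.
#' @param svm_bands Named list of `c(lo, hi)` target bands in g.min/epoch
#'   for `sleep`, `sed`, `lpa`, `mvpa`. A degenerate band like `c(0, 0)`
#'   produces a noise-free signal.
#' @param nonwear_mode `"absent"` (no samples while removed) or `"gravity"`
#'   (flat 1-g signal, exercising missing-data-free non-wear handling).
#' @param cuts The [cut_points()] the downstream classifier will use; bands
#'   are validated against it.
#' @return A `device_params` list.
#' @export
device_params <- function(sampling_rate_hz = 50,
                          svm_bands = list(
                            sleep = c(0, 0.3),
                            sed = c(0.5, 3.0),
                            lpa = c(4.5, 13.5),
                            mvpa = c(16, 40)
                          ),
                          nonwear_mode = c("absent", "gravity"),
                          cuts = cut_points()) {
  nonwear_mode <- match.arg(nonwear_mode)
  if (sampling_rate_hz < 1 / 60) abort("sampling rate must be at least one sample per minute")
  stopifnot(setequal(names(svm_bands), BEHAVIOURS))
  for (b in BEHAVIOURS) {
    band <- svm_bands[[b]]
    if (length(band) != 2 || band[1] > band[2] || band[1] < 0) {
      abort(sprintf("invalid SVM band for %s", b))
    }
  }
  lim <- list(
    sleep = c(0, cuts$sed_lpa), sed = c(0, cuts$sed_lpa),
    lpa = c(cuts$sed_lpa, cuts$lpa_mvpa), mvpa = c(cuts$lpa_mvpa, Inf)
  )
  for (b in c("sed", "lpa", "mvpa")) {
    band <- svm_bands[[b]]
    if (band[1] < lim[[b]][1] || band[2] >= lim[[b]][2]) {
      abort(sprintf(
        "SVM band for %s [%g, %g] overlaps a cut-point boundary (%g, %g)",
        b, band[1], band[2], lim[[b]][1], lim[[b]][2]
      ))
    }
  }
  structure(list(
    sampling_rate_hz = sampling_rate_hz, svm_bands = svm_bands,
    nonwear_mode = nonwear_mode, cuts = cuts
  ), class = "device_params")
}

#' Build a minute-tiled behaviour schedule for one day
#'
#' Converts a 4-part target composition into an ordered segment tiling of
#' the 1440-minute day: sleep at both ends of the day (morning until get-up,
#' evening from bed time), alternating waking-behaviour blocks in between,
#' optionally with restless awake (light-activity) minutes inside the sleep
#' window. Durations are snapped to the schedule grid by largest-remainder
#' rounding, preserving the 1440 total.
#'
#' Uses the current RNG stream; seed externally (the cohort generator seeds
#' a substream per participant-day).
#'
#' @param composition Named minutes for `sleep`, `sed`, `lpa`, `mvpa`
#'   (closed to 1440 internally; must be strictly positive).
#' @param grid Segment resolution in minutes.
#' @param awakening_min Awake (LPA) minutes placed inside the sleep window;
#'   drawn from the sleep part of the window, not from `composition`'s
#'   waking parts.
#' @param getup_frac Fraction of the sleep window placed before get-up.
#' @return A schedule list: `segments` (tibble `behaviour`, `start`,
#'   `duration`, `wear`, `reason`), `bed_time`, `getup_time`.
#' @export
make_day_schedule <- function(composition, grid = 5, awakening_min = 0,
                              getup_frac = 0.45) {
  comp <- composition[BEHAVIOURS]
  if (any(!is.finite(comp)) || any(comp <= 0)) {
    abort("schedule composition must be strictly positive")
  }
  comp <- comp / sum(comp) * MINUTES_PER_DAY
  comp <- round_preserving_total(comp, grid, MINUTES_PER_DAY)
  awak <- round(awakening_min / grid) * grid
  window <- comp[["sleep"]]           # logged window = sleep + awake-in-bed
  if (awak > window - 2 * grid) abort("awakening_min too large for the sleep window")
  morning <- max(grid, round(window * getup_frac / grid) * grid)
  evening <- window - morning
  if (evening < grid) {
    evening <- grid
    morning <- window - evening
  }
  getup <- morning
  bed <- MINUTES_PER_DAY - evening

  behaviour <- character(0)
  duration <- numeric(0)
  push <- function(b, d) {
    if (d > 0) {
      behaviour <<- c(behaviour, b)
      duration <<- c(duration, d)
    }
  }
  # morning sleep, with any awakening carved from its middle
  if (awak > 0 && morning >= awak + 2 * grid) {
    a <- round((morning - awak) / 2 / grid) * grid
    push("sleep", a)
    push("lpa", awak)
    push("sleep", morning - awak - a)
  } else if (awak > 0) {
    push("lpa", awak)
    push("sleep", morning - awak)
  } else {
    push("sleep", morning)
  }
  # waking blocks: alternate behaviours in 10-45 min chunks, weighted by
  # remaining budget so the tiling hits the target composition exactly
  budget <- comp[c("sed", "lpa", "mvpa")]
  last <- ""
  while (sum(budget) > 0) {
    open <- names(budget)[budget > 0]
    pick <- if (length(open) == 1) open else {
      w <- budget[open]
      if (last %in% open && length(open) > 1) w[last] <- w[last] * 0.25
      sample(open, 1, prob = w)
    }
    len <- min(budget[[pick]], sample(2:9, 1) * grid)
    push(pick, len)
    budget[[pick]] <- budget[[pick]] - len
    last <- pick
  }
  push("sleep", evening)

  list(
    segments = tibble(
      behaviour = behaviour,
      start = cumsum(c(0, utils::head(duration, -1))),
      duration = duration,
      wear = TRUE,
      reason = NA_character_
    ),
    bed_time = bed, getup_time = getup
  )
}

# With configured probability, mark one waking interval as device-off
# (wear = FALSE), splitting segments at its boundaries. Uses current RNG.
overlay_removal <- function(sched, config) {
  if (stats::runif(1) >= config$removal_prob) return(sched)
  dur <- max(config$grid, round(
    stats::rnorm(1, config$removal_mean_min, config$removal_sd_min) / config$grid
  ) * config$grid)
  wak_lo <- sched$getup_time
  wak_hi <- sched$bed_time
  dur <- min(dur, wak_hi - wak_lo - config$grid)
  start <- wak_lo + round(
    stats::runif(1, 0, wak_hi - wak_lo - dur) / config$grid
  ) * config$grid
  reason <- if (stats::runif(1) < config$sports_reason_prob) "sports" else "other"
  sched$segments <- mark_nonwear(sched$segments, start, start + dur, reason)
  sched
}

# Split schedule segments at [start, end) and flag the inside as non-wear.
mark_nonwear <- function(segments, start, end, why) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    s <- seg$start
    e <- seg$start + seg$duration
    cutpts <- sort(unique(c(s, e, pmin(pmax(c(start, end), s), e))))
    for (j in seq_len(length(cutpts) - 1)) {
      a <- cutpts[j]; b <- cutpts[j + 1]
      if (b <= a) next
      inside <- a >= start && b <= end
      out[[length(out) + 1]] <- dplyr::mutate(
        seg, start = a, duration = b - a,
        wear = .data$wear & !inside,
        reason = ifelse(inside, why, .data$reason)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Ground-truth minutes per behaviour from a segment tiling
#'
#' @param segments A schedule segment tibble (`behaviour`, `duration`, ...).
#' @return Named numeric vector of minutes for sleep, sed, lpa, mvpa.
#' @export
schedule_truth <- function(segments) {
  mins <- tapply(segments$duration, factor(segments$behaviour, levels = BEHAVIOURS),
                 sum, default = 0)
  stats::setNames(as.numeric(mins), BEHAVIOURS)
}

#' Render a schedule as a raw triaxial recording plus wear log
#'
#' Emits acceleration samples for every worn minute: the minute's behaviour
#' sets a target epoch SVM drawn uniformly from the device band, realised as
#' samples of norm `1 + target/60` g in a random (white) direction, so the
#' downstream epoch value equals the target exactly. Non-worn minutes emit
#' no samples (or a flat 1-g gravity signal, per [device_params()]). The
#' wear log carries the logged bed/get-up times and removal intervals with
#' their reasons copied from the schedule.
#'
#' @param schedule A schedule list from [make_day_schedule()] or
#'   [cohort_schedule()].
#' @param device A [device_params()] object.
#' @param seed Integer seed for this day's signal.
#' @return A list: `recording` (tibble `time_s`, `ax_g`, `ay_g`, `az_g`) and
#'   `wear_log` (list `date`, `bed_time`, `getup_time`, `removals`).
#' @export
generate_raw_day <- function(schedule, device = device_params(), seed = 1L) {
  segs <- schedule$segments
  rate <- device$sampling_rate_hz
  n_per_min <- max(1L, round(rate * 60))
  minutes <- rep(segs$behaviour, segs$duration)
  worn <- rep(segs$wear, segs$duration)
  stopifnot(length(minutes) == MINUTES_PER_DAY)

  withr::with_seed(seed, {
    target <- vapply(minutes, function(b) {
      band <- device$svm_bands[[b]]
      stats::runif(1, band[1], band[2])
    }, numeric(1))
    emit <- worn | device$nonwear_mode == "gravity"
    norm <- ifelse(worn, 1 + target / 60, 1)
    idx <- which(emit)
    n_samples <- length(idx) * n_per_min
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
  })
  scale <- rep(norm[idx], each = n_per_min)
  a <- u * scale
  time_s <- rep((idx - 1) * 60, each = n_per_min) +
    rep(seq(0, by = 60 / n_per_min, length.out = n_per_min), times = length(idx))

  removals <- wear_removals(segs)
  list(
    recording = tibble(
      time_s = time_s, ax_g = a[, 1], ay_g = a[, 2], az_g = a[, 3]
    ),
    wear_log = list(
      date = schedule$date %||% NA,
      bed_time = schedule$bed_time,
      getup_time = schedule$getup_time,
      removals = removals
    )
  )
}

# Collapse consecutive non-worn segments into removal intervals.
wear_removals <- function(segments) {
  off <- segments[!segments$wear, , drop = FALSE]
  if (nrow(off) == 0) {
    return(tibble(start = numeric(0), end = numeric(0), reason = character(0)))
  }
  off <- off[order(off$start), ]
  runs <- cumsum(c(1, (off$start[-1] != off$start[-nrow(off)] + off$duration[-nrow(off)]) |
                     (off$reason[-1] != off$reason[-nrow(off)])))
  out <- dplyr::group_by(dplyr::mutate(off, .run = runs), .data$.run)
  out <- dplyr::summarise(out,
    end = max(.data$start + .data$duration),
    start = min(.data$start),
    reason = .data$reason[1], .groups = "drop"
  )
  dplyr::select(out, "start", "end", "reason")
}
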