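#' Configuration for a synthetic cohort
#'
#' Defines the study conditions under which ground-truth behaviour schedules,
#' raw wrist-acceleration signals, wear logs and recall diaries are
#' generated. Defaults describe a primary-school cohort: 120 children
#' (two-thirds female, age 10.0 +/- 0.3 y), clustered in schools over two
#' study waves, wearing the device for 7 consecutive days with 2 recall
#' days, with a mean device composition of 588/488/279/85 min of
#' sleep/sedentary/LPA/MVPA and roughly 24 min/day of non-wear.
#'
#' Day-to-day and between-child variation is generated by symmetric
#' Dirichlet perturbation around the relevant mean composition, which
#' respects positivity and closure; `*_dispersion` is the inverse Dirichlet
#' concentration, so 0 means no variation at that level.
#'
#' @param n_participants,n_schools,n_waves Cohort structure; schools are
#'   split evenly across waves.
#' @param days_per_participant Consecutive device-wear days per child.
#' @param recall_days_per_participant Days per child that also get a diary.
#' @param start_date First wear day (a Monday keeps two weekend days in a
#'   7-day window).
#' @param sex_prob Named probabilities for `female`/`male`.
#' @param age_mean,age_sd,zbmi_mean,zbmi_sd,vo2max_mean,vo2max_sd,academic_mean,academic_sd
#'   Continuous characteristic distributions (normal).
#' @param academic_missing_prob Probability a child has no academic score.
#' @param puberty_prob,parent_ed_prob Named category probabilities.
#' @param true_composition Overall mean 4-part composition (minutes; closed
#'   to 1440 internally).
#' @param composition_by Optional named list: characteristic -> level ->
#'   composition, overriding `true_composition` for that level (default: a
#'   small sex difference mirroring the configured overall means).
#' @param participant_dispersion,day_dispersion Inverse Dirichlet
#'   concentrations for between-child and within-child day variation.
#' @param awakening_min True awake minutes (restless light activity) inside
#'   the sleep window per night.
#' @param removal_prob,removal_mean_min,removal_sd_min,sports_reason_prob
#'   Device-removal overlay: per-day probability of one removal, its
#'   duration distribution, and the chance its logged reason is `"sports"`.
#' @param bias Recall reporting bias, a [bias_params()] object.
#' @param bias_by Optional function `(participant_row) -> bias_params`
#'   giving characteristic-dependent reporting bias.
#' @param grid Schedule resolution in minutes (diary block size must be a
#'   multiple of this).
#' @param seed Integer seed; all randomness flows from it via per
#'   participant-day substreams.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 120,
                          n_schools = 9,
                          n_waves = 2,
                          days_per_participant = 7,
                          recall_days_per_participant = 2,
                          start_date = as.Date("2019-02-04"),
                          sex_prob = c(female = 0.67, male = 0.33),
                          age_mean = 10.0, age_sd = 0.3,
                          puberty_prob = c(pre = 0.65, early = 0.20, mid = 0.15,
                                           late = 0, post = 0),
                          parent_ed_prob = c(low = 0.07, mid = 0.36, high = 0.57),
                          zbmi_mean = 0.17, zbmi_sd = 1.20,
                          vo2max_mean = 40.1, vo2max_sd = 6.6,
                          academic_mean = 126, academic_sd = 9,
                          academic_missing_prob = 0.14,
                          true_composition = c(sleep = 588, sed = 488,
                                               lpa = 279, mvpa = 85),
                          composition_by = NULL,
                          participant_dispersion = 1 / 150,
                          day_dispersion = 1 / 300,
                          awakening_min = 0,
                          removal_prob = 0.3,
                          removal_mean_min = 80,
                          removal_sd_min = 30,
                          sports_reason_prob = 0.3,
                          bias = bias_params(),
                          bias_by = NULL,
                          grid = 5,
                          seed = 1L) {
  close1440 <- function(x) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      abort("composition targets must be strictly positive")
    }
    x / sum(x) * MINUTES_PER_DAY
  }
  true_composition <- close1440(true_composition[BEHAVIOURS])
  if (is.null(composition_by)) {
    # mild default sex contrast around the overall mean
    composition_by <- list(sex = list(
      female = close1440(true_composition + c(-3, 14, -1, -10)),
      male = close1440(true_composition + c(7, -30, 1, 22))
    ))
  } else {
    composition_by <- lapply(composition_by, function(levels) lapply(levels, close1440))
  }
  for (p in list(sex_prob, puberty_prob, parent_ed_prob)) {
    if (abs(sum(p) - 1) > 1e-8) abort("category probabilities must sum to 1")
  }
  stopifnot(
    n_participants >= 1, n_schools >= 1, n_waves >= 1,
    days_per_participant >= 1,
    recall_days_per_participant <= days_per_participant,
    participant_dispersion >= 0, day_dispersion >= 0,
    grid >= 1, removal_prob >= 0, removal_prob <= 1
  )
  structure(
    list(
      n_participants = n_participants, n_schools = n_schools,
      n_waves = n_waves, days_per_participant = days_per_participant,
      recall_days_per_participant = recall_days_per_participant,
      start_date = as.Date(start_date),
      sex_prob = sex_prob, age_mean = age_mean, age_sd = age_sd,
      puberty_prob = puberty_prob, parent_ed_prob = parent_ed_prob,
      zbmi_mean = zbmi_mean, zbmi_sd = zbmi_sd,
      vo2max_mean = vo2max_mean, vo2max_sd = vo2max_sd,
      academic_mean = academic_mean, academic_sd = academic_sd,
      academic_missing_prob = academic_missing_prob,
      true_composition = true_composition, composition_by = composition_by,
      participant_dispersion = participant_dispersion,
      day_dispersion = day_dispersion,
      awakening_min = awakening_min,
      removal_prob = removal_prob, removal_mean_min = removal_mean_min,
      removal_sd_min = removal_sd_min,
      sports_reason_prob = sports_reason_prob,
      bias = bias, bias_by = bias_by, grid = grid, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Dirichlet draw around mean proportions p with dispersion = 1/concentration;
# dispersion 0 returns p exactly.
rdirichlet_around <- function(p, dispersion) {
  p <- p / sum(p)
  if (dispersion == 0) return(p)
  g <- stats::rgamma(length(p), shape = p / dispersion, rate = 1)
  if (sum(g) == 0) return(p)
  stats::setNames(g / sum(g), names(p))
}

#' Generate a synthetic cohort with ground-truth schedules
#'
#' Draws participant characteristics, assigns schools and waves, draws each
#' child's mean composition around their characteristic-level mean, then
#' each day's true composition around the child mean, and converts each day
#' into a minute-tiled behaviour schedule with a device-removal overlay.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort`:
#' \describe{
#'   \item{participants}{tibble of characteristics (one row per child).}
#'   \item{days}{tibble with one row per participant-day: date, weekend and
#'     recall flags, logged bed/get-up times, and the ground-truth minutes
#'     per behaviour (the four columns tile 1440).}
#'   \item{segments}{long tibble of schedule segments (`behaviour`, `start`,
#'     `duration`, `wear`, `reason`) keyed by participant and date.}
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  withr::with_seed(config$seed, {
    schools <- sample(seq_len(config$n_schools), n, replace = TRUE)
    wave_of_school <- rep(seq_len(config$n_waves), length.out = config$n_schools)
    participants <- tibble(
      participant = sprintf("P%04d", seq_len(n)),
      school = sprintf("S%02d", schools),
      wave = wave_of_school[schools],
      sex = sample(names(config$sex_prob), n, TRUE, prob = config$sex_prob),
      age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
      puberty = sample(names(config$puberty_prob), n, TRUE, prob = config$puberty_prob),
      parental_education = sample(names(config$parent_ed_prob), n, TRUE,
                                  prob = config$parent_ed_prob),
      zbmi = round(stats::rnorm(n, config$zbmi_mean, config$zbmi_sd), 2),
      vo2max = round(stats::rnorm(n, config$vo2max_mean, config$vo2max_sd), 1),
      pat = ifelse(stats::runif(n) < config$academic_missing_prob, NA_real_,
                   round(stats::rnorm(n, config$academic_mean, config$academic_sd)))
    )
  })

  days_list <- vector("list", n)
  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    prow <- participants[i, ]
    mean_comp <- level_mean_composition(config, prow)
    withr::with_seed(substream_seed(config$seed, i, 0L), {
      pcomp <- rdirichlet_around(mean_comp / MINUTES_PER_DAY,
                                 config$participant_dispersion) * MINUTES_PER_DAY
      recall_days <- sort(sample(seq_len(config$days_per_participant),
                                 config$recall_days_per_participant))
    })
    pd <- vector("list", config$days_per_participant)
    ps <- vector("list", config$days_per_participant)
    for (d in seq_len(config$days_per_participant)) {
      date <- config$start_date + (d - 1)
      withr::with_seed(substream_seed(config$seed, i, d), {
        dcomp <- rdirichlet_around(pcomp / MINUTES_PER_DAY,
                                   config$day_dispersion) * MINUTES_PER_DAY
        sched <- make_day_schedule(dcomp, grid = config$grid,
                                   awakening_min = config$awakening_min)
        sched <- overlay_removal(sched, config)
      })
      truth <- schedule_truth(sched$segments)
      pd[[d]] <- tibble(
        participant = prow$participant, date = date,
        weekend = format(date, "%u") %in% c("6", "7"),
        recall = d %in% recall_days,
        bed_time = sched$bed_time, getup_time = sched$getup_time,
        sleep_min = truth[["sleep"]], sed_min = truth[["sed"]],
        lpa_min = truth[["lpa"]], mvpa_min = truth[["mvpa"]]
      )
      ps[[d]] <- dplyr::mutate(sched$segments,
        participant = prow$participant, date = date, .before = 1
      )
    }
    days_list[[i]] <- dplyr::bind_rows(pd)
    seg_list[[i]] <- dplyr::bind_rows(ps)
  }
  structure(
    list(
      participants = participants,
      days = dplyr::bind_rows(days_list),
      segments = dplyr::bind_rows(seg_list),
      config = config
    ),
    class = "cohort"
  )
}

# Mean composition for a participant, honouring per-level overrides.
level_mean_composition <- function(config, prow) {
  comp <- config$true_composition
  for (chr in names(config$composition_by)) {
    lev <- as.character(prow[[chr]])
    override <- config$composition_by[[chr]][[lev]]
    if (!is.null(override)) comp <- override
  }
  comp
}

#' Extract one day's schedule from a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param participant,date Day key.
#' @return A schedule list (`segments`, `bed_time`, `getup_time`, `date`,
#'   `weekend`, `participant`) usable with [generate_raw_day()] and
#'   [generate_recall_day()].
#' @export
cohort_schedule <- function(cohort, participant, date) {
  day <- dplyr::filter(cohort$days, .data$participant == !!participant,
                       .data$date == !!date)
  if (nrow(day) != 1) abort("no such participant-day in the cohort")
  segs <- dplyr::filter(cohort$segments, .data$participant == !!participant,
                        .data$date == !!date)
  list(
    segments = dplyr::select(segs, -"participant", -"date"),
    bed_time = day$bed_time, getup_time = day$getup_time,
    date = day$date, weekend = day$weekend, participant = participant
  )
}
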