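#' Simulate participant records directly at the composition level
#'
#' A lightweight generator for validating the modelling stage without the
#' raw-signal and diary machinery: participant mean compositions are drawn
#' in ILR space around a base composition with nested wave, school and
#' participant random effects, and each method's observed composition adds
#' independent coordinate noise. Method effects (overall, or differing by
#' sex to plant a method-by-characteristic interaction) are specified as
#' min/day shifts of the self-reported mean composition.
#'
#' @param n Number of participants.
#' @param n_schools,n_waves Nesting structure.
#' @param base Mean 4-part composition (min/day, closed to 1440).
#' @param sd_wave,sd_school,sd_participant,sd_noise SDs of the normal
#'   random effects / residual noise on each ILR coordinate.
#' @param self_shift Optional 4-part min/day shift of the self-reported
#'   mean composition (applied to everyone; parts must stay positive).
#' @param self_shift_by_sex Optional named list (`female`, `male`) of
#'   4-part shifts, planting a sex-by-method interaction.
#' @param base_by_sex Optional named list (`female`, `male`) of base
#'   compositions, planting a device-side sex difference.
#' @param seed Integer seed.
#' @return A records tibble compatible with [build_stacked()]: participant,
#'   school, wave, `sex`, a standard-normal continuous `score`, and the 8
#'   composition columns.
#' @export
simulate_participant_records <- function(n = 120,
                                         n_schools = 9,
                                         n_waves = 2,
                                         base = c(sleep = 588, sed = 488,
                                                  lpa = 279, mvpa = 85),
                                         sd_wave = 0.02,
                                         sd_school = 0.04,
                                         sd_participant = 0.12,
                                         sd_noise = 0.08,
                                         self_shift = NULL,
                                         self_shift_by_sex = NULL,
                                         base_by_sex = NULL,
                                         seed = 1L) {
  base <- base[BEHAVIOURS] / sum(base) * MINUTES_PER_DAY
  shift_comp <- function(comp, delta) {
    out <- comp + delta[BEHAVIOURS]
    if (any(out <= 0)) abort("self shift makes a composition part non-positive")
    out / sum(out) * MINUTES_PER_DAY
  }
  withr::with_seed(seed, {
    school <- sample(seq_len(n_schools), n, replace = TRUE)
    wave <- rep(seq_len(n_waves), length.out = n_schools)[school]
    sex <- sample(c("female", "male"), n, replace = TRUE)
    score <- stats::rnorm(n)
    wave_re <- matrix(stats::rnorm(n_waves * 3, 0, sd_wave), n_waves, 3)
    school_re <- matrix(stats::rnorm(n_schools * 3, 0, sd_school), n_schools, 3)
    p_re <- matrix(stats::rnorm(n * 3, 0, sd_participant), n, 3)
    noise_d <- matrix(stats::rnorm(n * 3, 0, sd_noise), n, 3)
    noise_s <- matrix(stats::rnorm(n * 3, 0, sd_noise), n, 3)
  })
  z_for <- function(comp) {
    comp <- comp[BEHAVIOURS] / sum(comp) * MINUTES_PER_DAY
    as.matrix(ilr_transform(as_tibble(as.list(comp))))[1, ]
  }
  z_base <- if (is.null(base_by_sex)) {
    matrix(z_for(base), n, 3, byrow = TRUE)
  } else {
    t(vapply(sex, function(s) z_for(base_by_sex[[s]]), numeric(3)))
  }
  z_mean <- z_base +
    wave_re[wave, , drop = FALSE] + school_re[school, , drop = FALSE] + p_re

  z_self_target <- z_mean
  if (!is.null(self_shift) || !is.null(self_shift_by_sex)) {
    comp_mean <- as.matrix(
      ilr_inverse(mat_tibble(z_mean, c("z1", "z2", "z3")))
    )
    comp_self <- comp_mean
    for (i in seq_len(n)) {
      delta <- self_shift %||% c(sleep = 0, sed = 0, lpa = 0, mvpa = 0)
      if (!is.null(self_shift_by_sex)) {
        delta <- delta + self_shift_by_sex[[sex[i]]][BEHAVIOURS]
      }
      comp_self[i, ] <- shift_comp(comp_mean[i, ], delta)
    }
    z_self_target <- as.matrix(
      ilr_transform(mat_tibble(comp_self, BEHAVIOURS))
    )
  }
  z_device <- z_mean + noise_d
  z_self <- z_self_target + noise_s

  to_comp <- function(z, suffix) {
    comp <- ilr_inverse(mat_tibble(z, c("z1", "z2", "z3")))
    stats::setNames(comp, paste0(BEHAVIOURS, "_min", suffix))
  }
  dplyr::bind_cols(
    tibble(
      participant = sprintf("P%04d", seq_len(n)),
      school = sprintf("S%02d", school),
      wave = wave, sex = sex, score = score
    ),
    to_comp(z_device, "_device"),
    to_comp(z_self, "_self")
  )
}
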