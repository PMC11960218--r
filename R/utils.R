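# Internal helpers shared across modules.

# Canonical behaviour order used everywhere a 4-part composition appears.
BEHAVIOURS <- c("sleep", "sed", "lpa", "mvpa")

MINUTES_PER_DAY <- 1440L

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible substream seed for one participant-day from a base
# seed. Kept below 2^31 so it is always a valid R integer.
substream_seed <- function(base_seed, participant_index, day_index = 0L) {
  ((as.numeric(base_seed) %% 2147483647) * 48271 +
     participant_index * 69621 + day_index * 16807) %% 2147483399 + 1
}

# Check that a vector of minutes is a set of non-negative finite numbers.
assert_minutes <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("%s must be finite and non-negative", what))
  }
  invisible(x)
}

# Round a vector of durations to multiples of `block` while preserving the
# (block-divisible) total, by the largest-remainder method.
round_preserving_total <- function(x, block, total = sum(x)) {
  stopifnot(total %% block == 0)
  units <- x / block
  base <- floor(units)
  shortfall <- round(total / block) - sum(base)
  if (shortfall > 0) {
    frac <- units - base
    add <- order(frac, decreasing = TRUE)[seq_len(shortfall)]
    base[add] <- base[add] + 1
  } else if (shortfall < 0) {
    # over-allocated (can happen when x was already integral); trim largest
    take <- order(base, decreasing = TRUE)[seq_len(-shortfall)]
    base[take] <- base[take] - 1
  }
  base * block
}

# Minutes-of-day formatting helpers for the wear-log CSV dialect (HH:MM).
minute_to_hhmm <- function(m) {
  sprintf("%02d:%02d", (m %/% 60) %% 24, m %% 60)
}

hhmm_to_minute <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
}

# Matrix -> tibble with explicit column names (avoids name-repair noise).
mat_tibble <- function(m, nms) {
  colnames(m) <- nms
  as_tibble(m)
}
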