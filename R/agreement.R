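#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' Quantifies agreement between two measurement methods across subjects
#' from the two-way ANOVA mean squares (rows = subjects, columns = methods,
#' k = 2):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Absolute agreement penalises a systematic offset between methods, unlike
#' the consistency form. The 95% confidence interval and the F test of
#' ICC = 0 follow the McGraw-Wong formulation. Estimates are labelled poor
#' (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (> 0.9).
#'
#' @param data Data frame of paired measurements.
#' @param device,self Columns holding the two methods' values (tidy-eval).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc` with fields `icc`, `ci_low`, `ci_high`,
#'   `f`, `df1`, `df2`, `p`, `label`, `n`, and the mean squares. `tidy()`
#'   returns it as a one-row tibble.
#' @export
icc_2_1 <- function(data, device, self, conf_level = 0.95) {
  x <- rlang::eval_tidy(rlang::enquo(device), data)
  y <- rlang::eval_tidy(rlang::enquo(self), data)
  if (length(x) < 3) abort("ICC needs at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("ICC inputs must be finite")
  n <- length(x)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- sum((m - outer(row_means, rep(1, k)) -
                   outer(rep(1, n), col_means) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (ss_rows + ss_cols + ss_err) == 0) {
    abort("ICC undefined: zero total variance")
  }
  icc <- (msr - mse) / denom

  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  fj <- msc / mse
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v)) v <- 1e12  # degenerate mse = 0 (perfect agreement)
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  f0 <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f0, df1, df2, lower.tail = FALSE)
  label <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
    else if (icc <= 0.9) "good" else "excellent"
  structure(list(
    icc = icc, ci_low = ci_low, ci_high = ci_high,
    f = f0, df1 = df1, df2 = df2, p = p, label = label, n = n,
    msr = msr, msc = msc, mse = mse, conf_level = conf_level
  ), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) absolute agreement: %.3f [%.2f, %.2f] (%s)\nF(%d, %d) = %.2f, p = %.3g, n = %d\n",
    x$icc, x$ci_low, x$ci_high, x$label, x$df1, x$df2, x$f, x$p, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icc <- function(x, ...) {
  tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    f = x$f, df1 = x$df1, df2 = x$df2, p = x$p, label = x$label, n = x$n
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences are self minus device; the bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 times the sample SD of the
#' differences. Per-pair `(mean, diff)` points are kept for plotting.
#'
#' @inheritParams icc_2_1
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n` and a `points` tibble. `tidy()` gives the one-row
#'   summary; `autoplot()` draws the standard plot.
#' @export
bland_altman <- function(data, device, self) {
  x <- rlang::eval_tidy(rlang::enquo(device), data)
  y <- rlang::eval_tidy(rlang::enquo(self), data)
  if (length(x) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    n = length(d),
    points = tibble(mean = (x + y) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (self - device): bias %.1f, 95%% limits [%.1f, %.1f], n = %d\n",
    x$bias, x$loa_low, x$loa_high, x$n
  ))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Mean absolute percentage error of self-report against the device
#'
#' Treats the self-reported value as the forecast and the device-measured
#' value as the actual: `mean(|self - device| / device) * 100`. Pairs with a
#' zero device value are excluded with a warning (their count is returned as
#' an attribute).
#'
#' @inheritParams icc_2_1
#' @return The MAPE as a percentage, with attribute `n_excluded`.
#' @export
mape <- function(data, device, self) {
  x <- rlang::eval_tidy(rlang::enquo(device), data)
  y <- rlang::eval_tidy(rlang::enquo(self), data)
  zero <- x == 0
  if (any(zero)) {
    warn(sprintf("%d pair(s) with device value 0 excluded from MAPE", sum(zero)))
  }
  out <- mean(abs(y[!zero] - x[!zero]) / x[!zero]) * 100
  attr(out, "n_excluded") <- sum(zero)
  out
}

#' Agreement summary for all four behaviours
#'
#' Runs [icc_2_1()], [bland_altman()] and [mape()] per behaviour on a
#' participant-record table.
#'
#' @param records Output of [average_per_participant()] (or any table with
#'   `<behaviour>_min_device` / `<behaviour>_min_self` columns).
#' @return A tibble with one row per behaviour: ICC with CI and F test,
#'   bias, limits of agreement, and MAPE.
#' @export
agreement_summary <- function(records) {
  purrr::map_dfr(BEHAVIOURS, function(b) {
    dev <- records[[paste0(b, "_min_device")]]
    slf <- records[[paste0(b, "_min_self")]]
    df <- tibble(device = dev, self = slf)
    ic <- icc_2_1(df, device, self)
    ba <- bland_altman(df, device, self)
    mp <- suppressWarnings(mape(df, device, self))
    tibble(
      behaviour = b, icc = ic$icc, icc_ci_low = ic$ci_low,
      icc_ci_high = ic$ci_high, icc_f = ic$f, icc_p = ic$p,
      icc_label = ic$label, bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high, mape_pct = as.numeric(mp)
    )
  })
}
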