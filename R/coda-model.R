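#' Stack participant records for the compositional interaction model
#'
#' Each participant contributes two dependent compositions (average
#' device-measured and self-reported days), expressed as isometric
#' log-ratios and stacked long: 2 methods x 3 ILR coordinates = 6 rows per
#' participant. Continuous characteristics are standardised (mean 0, SD 1)
#' with the transform recorded for back-conversion; age stays on its raw
#' scale (its display levels are 9.5, 10 and 10.5 years). Participants
#' missing the characteristic are dropped (so e.g. an academic-score model
#' runs on the reduced n).
#'
#' @param records Output of [average_per_participant()].
#' @param characteristic Name of the characteristic column to model.
#' @param sbp Sequential binary partition for the ILR transform.
#' @param zero_replace Passed to [ilr_transform()] (averaged, closed days
#'   rarely contain zeros; 1-minute multiplicative replacement if they do).
#' @return A tibble with columns `participant`, `school`, `wave`, `method`,
#'   `ilr_index`, `value`, `x` (the modelling-scale characteristic) plus
#'   metadata attributes (`char_name`, `char_type`, `center`, `scale`,
#'   `levels`, `range`).
#' @export
build_stacked <- function(records, characteristic, sbp = sbp_default(),
                          zero_replace = 1) {
  if (!characteristic %in% names(records)) {
    abort(sprintf("characteristic `%s` not found in records", characteristic))
  }
  rec <- records[!is.na(records[[characteristic]]), , drop = FALSE]
  xraw <- rec[[characteristic]]
  if (is.numeric(xraw)) {
    type <- "continuous"
    if (characteristic == "age") {
      center <- 0; scale <- 1
    } else {
      center <- mean(xraw); scale <- stats::sd(xraw)
      if (scale == 0) abort("characteristic has zero variance")
    }
    x <- (xraw - center) / scale
    levels <- NULL
  } else {
    type <- "categorical"
    x <- factor(xraw)
    x <- droplevels(x)
    if (nlevels(x) < 2) {
      abort(sprintf("characteristic `%s` has fewer than 2 observed levels",
                    characteristic))
    }
    center <- NA_real_; scale <- NA_real_
    levels <- levels(x)
  }

  n_days <- if ("n_matched_days" %in% names(rec)) rec$n_matched_days else 1L
  one_method <- function(suffix, method) {
    comp <- tibble(
      sleep = rec[[paste0("sleep_min", suffix)]],
      sed = rec[[paste0("sed_min", suffix)]],
      lpa = rec[[paste0("lpa_min", suffix)]],
      mvpa = rec[[paste0("mvpa_min", suffix)]]
    )
    z <- ilr_transform(comp, sbp, zero_replace = zero_replace)
    dplyr::mutate(z,
      participant = rec$participant, school = rec$school,
      wave = factor(rec$wave), method = method, x = x,
      n_matched_days = n_days
    )
  }
  wide <- dplyr::bind_rows(one_method("_device", "device"),
                           one_method("_self", "self"))
  stacked <- tidyr::pivot_longer(wide, dplyr::all_of(c("z1", "z2", "z3")),
                                 names_to = "ilr_index", values_to = "value")
  stacked <- dplyr::mutate(stacked,
    method = factor(.data$method, levels = c("device", "self")),
    ilr_index = factor(.data$ilr_index)
  )
  structure(
    as_tibble(stacked),
    char_name = characteristic, char_type = type,
    center = center, scale = scale, levels = levels,
    range = if (type == "continuous") range(xraw) else NULL,
    sbp = sbp
  )
}

#' Fit the stacked compositional interaction model
#'
#' A linear mixed model on the stacked ILR values with fixed effects for
#' ILR coordinate, measurement method, the characteristic, and all their
#' interactions up to the three-way term, so each ILR coordinate gets its
#' own intercept, method shift, characteristic slope and
#' method-by-characteristic term. Random effects: intercepts for wave,
#' school and participant-level random effects indexed by ILR coordinate
#' (random slopes at the log-ratio level, which subsume a participant
#' intercept). Fitted by maximum likelihood so Wald blocks are comparable
#' across characteristics.
#'
#' If the fitted random structure is singular, the structure is simplified
#' stepwise by removing whichever component is actually degenerate: a wave
#' or school intercept whose variance collapsed to zero, then an
#' unstructured slope covariance on a correlation boundary (replaced by
#' independent per-coordinate slopes), then slopes whose variances
#' collapsed (replaced by a participant intercept). Pruning only the
#' degenerate component keeps the residual variance honest; dropping the
#' ILR slopes while participant-by-coordinate variance is real would
#' inflate the Wald covariance of the method contrasts and make the
#' omnibus test conservative. Each step is recorded in the returned object.
#'
#' @param stacked A table from [build_stacked()].
#' @param weight_by_days Sensitivity option: weight each child by their
#'   number of matched days instead of equally. The default (equal weight)
#'   mirrors the average-first-model-second design.
#' @return An object of class `coda_fit`: the `lme4` fit, the formula used,
#'   the simplification log and the characteristic metadata.
#' @export
fit_interaction_model <- function(stacked, weight_by_days = FALSE) {
  meta <- attributes(stacked)
  data <- dplyr::mutate(stacked,
    i1 = as.numeric(.data$ilr_index == "z1"),
    i2 = as.numeric(.data$ilr_index == "z2"),
    i3 = as.numeric(.data$ilr_index == "z3")
  )
  has_wave <- length(unique(data$wave)) > 1
  has_school <- length(unique(data$school)) > 1
  slope_mode <- "unstructured"
  steps <- character(0)
  fit <- NULL
  tol <- 1e-8
  for (iter in 1:6) {
    parts <- c(
      "value ~ ilr_index * method * x",
      if (has_wave) "(1 | wave)",
      if (has_school) "(1 | school)",
      switch(slope_mode,
        unstructured = "(0 + ilr_index | participant)",
        independent = "(0 + i1 | participant) + (0 + i2 | participant) + (0 + i3 | participant)",
        intercept = "(1 | participant)"
      )
    )
    form <- paste(parts, collapse = " + ")
    w <- if (weight_by_days && "n_matched_days" %in% names(data)) {
      data$n_matched_days
    } else {
      NULL
    }
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(stats::as.formula(form), data = data, REML = FALSE,
                   weights = w,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
      )),
      error = identity
    )
    if (inherits(fit, "error")) {
      # a numerically infeasible structure (e.g. zero residual variance
      # under the full slope covariance): force the next simplification
      if (slope_mode == "unstructured") {
        slope_mode <- "independent"
      } else if (slope_mode == "independent") {
        slope_mode <- "intercept"
      } else if (has_wave) {
        has_wave <- FALSE
      } else if (has_school) {
        has_school <- FALSE
      } else {
        abort(sprintf("mixed model failed to fit: %s", conditionMessage(fit)))
      }
      steps <- c(steps, sprintf("fit error (%s), simplifying", conditionMessage(fit)))
      fit <- NULL
      next
    }
    if (!lme4::isSingular(fit, tol = 1e-4)) break
    vc <- lme4::VarCorr(fit)
    get_var <- function(group) {
      v <- vc[names(vc) == group]
      if (length(v) == 0) return(NA_real_)
      sum(vapply(v, function(m) sum(diag(m)), numeric(1)))
    }
    if (has_wave && isTRUE(get_var("wave") < tol)) {
      has_wave <- FALSE
      steps <- c(steps, "wave intercept variance ~0: dropped")
    } else if (has_school && isTRUE(get_var("school") < tol)) {
      has_school <- FALSE
      steps <- c(steps, "school intercept variance ~0: dropped")
    } else if (slope_mode == "unstructured") {
      slope_mode <- "independent"
      steps <- c(steps, "slope covariance on boundary: independent ILR slopes")
    } else if (slope_mode == "independent") {
      slope_mode <- "intercept"
      steps <- c(steps, "slope variance ~0: participant intercept only")
    } else {
      steps <- c(steps, "residual singularity accepted")
      break
    }
  }
  if (is.null(fit)) abort("mixed model failed to fit under every random structure")
  structure(list(
    fit = fit, formula = form, simplification_log = steps,
    char_name = meta$char_name, char_type = meta$char_type,
    center = meta$center, scale = meta$scale, levels = meta$levels,
    range = meta$range, sbp = meta$sbp
  ), class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, ...) {
  cat(sprintf("Compositional interaction model for `%s` (%s)\n",
              x$char_name, x$char_type))
  cat("formula:", x$formula, "\n")
  if (length(x$simplification_log)) {
    cat("random structure simplified", length(x$simplification_log), "step(s)\n")
  }
  om <- omnibus_interaction_test(x)
  cat(sprintf("omnibus method-by-characteristic: chi2 = %.1f, df = %d, p = %.3g\n",
              om$chi2, om$df, om$p))
  invisible(x)
}

#' Omnibus Wald test of the method-by-characteristic interaction
#'
#' Tests the full block of `ilr_index:method:x` coefficients jointly: a
#' Wald chi-squared statistic `b' V^{-1} b` on the three-way interaction
#' block, with 3(L-1) degrees of freedom for a categorical characteristic
#' with L levels and 3 for a continuous one. A significant result means the
#' difference between device-measured and self-reported compositions varies
#' with the characteristic.
#'
#' @param object A `coda_fit` (or the statistic can be assembled manually
#'   with [wald_p()]).
#' @return A one-row tibble: `characteristic`, `chi2`, `df`, `p`,
#'   `n_participants`.
#' @export
omnibus_interaction_test <- function(object) {
  fit <- object$fit
  beta <- lme4::fixef(fit)
  assign <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  # the method difference in coordinate i as a function of x is
  # (method:x) + (ilr_index_i:method:x); the omnibus null sets both blocks
  # to zero, giving 3(L-1) df for L levels (3 for continuous x)
  block <- which(assign %in% which(labels %in% c("method:x", "ilr_index:method:x")))
  if (length(block) == 0) abort("no method:x interaction block in the fit")
  b <- beta[block]
  V <- as.matrix(stats::vcov(fit))[block, block, drop = FALSE]
  qrV <- qr(V)
  if (qrV$rank < length(b)) {
    abort(paste0(
      "rank-deficient interaction block; deficient terms: ",
      paste(names(b)[-seq_len(qrV$rank)], collapse = ", ")
    ))
  }
  chi2 <- as.numeric(t(b) %*% solve(V, b))
  df <- length(b)
  tibble(
    characteristic = object$char_name,
    chi2 = chi2, df = df, p = wald_p(chi2, df),
    n_participants = length(unique(stats::model.frame(fit)$participant))
  )
}

#' Upper-tail p-value of a Wald chi-squared statistic
#'
#' @param chi2 Test statistic.
#' @param df Degrees of freedom (3 per level contrast: `3(L-1)` for a
#'   categorical characteristic with `L` levels, 3 for a continuous one).
#' @return The p-value.
#' @export
wald_p <- function(chi2, df) {
  stats::pchisq(chi2, df, lower.tail = FALSE)
}

#' Model-based composition estimates per method and characteristic level
#'
#' Predicts the fixed-effect ILR means (random effects at zero) for each
#' method at each display level of the characteristic and back-transforms
#' them to min/day compositions summing to 1440. Display levels: observed
#' levels for categorical characteristics; mean and +/- 1 SD (on the raw
#' scale) for continuous ones; 9.5 / 10 / 10.5 years for age.
#'
#' @param object A `coda_fit`.
#' @param levels Optional explicit display levels (raw scale for
#'   continuous characteristics).
#' @return A tibble: `characteristic`, `level`, `method`, and the four
#'   behaviour columns (min/day, closing to 1440).
#' @export
estimate_compositions <- function(object, levels = NULL) {
  fit <- object$fit
  if (object$char_type == "categorical") {
    lv <- levels %||% object$levels
    grid <- expand.grid(x = factor(lv, levels = object$levels),
                        method = c("device", "self"),
                        stringsAsFactors = FALSE)
    display <- as.character(grid$x)
  } else {
    raw <- levels %||% (
      if (object$char_name == "age") c(9.5, 10, 10.5)
      else object$center + c(-1, 0, 1) * object$scale
    )
    if (!is.null(object$range) &&
        (min(raw) < object$range[1] || max(raw) > object$range[2])) {
      warn(sprintf("display level(s) outside the observed `%s` range [%g, %g]",
                   object$char_name, object$range[1], object$range[2]))
    }
    xs <- if (object$char_name == "age") raw else (raw - object$center) / object$scale
    grid <- expand.grid(x = xs, method = c("device", "self"),
                        stringsAsFactors = FALSE)
    grid$.display <- rep(raw, times = 2)
    display <- format(grid$.display, trim = TRUE)
  }
  newdata <- dplyr::bind_rows(lapply(c("z1", "z2", "z3"), function(zi) {
    g <- grid
    g$ilr_index <- zi
    g
  }))
  newdata$method <- factor(newdata$method, levels = c("device", "self"))
  newdata$ilr_index <- factor(newdata$ilr_index, levels = c("z1", "z2", "z3"))
  pred <- stats::predict(fit, newdata = newdata, re.form = NA)
  z <- matrix(pred, ncol = 3)
  colnames(z) <- c("z1", "z2", "z3")
  est <- ilr_inverse(as_tibble(z), sbp = object$sbp, total = MINUTES_PER_DAY)
  dplyr::bind_cols(
    tibble(
      characteristic = object$char_name,
      level = rep(display, 1),
      method = as.character(grid$method)
    ),
    est
  )
}

#' Classify how a between-level difference changes across methods
#'
#' For one behaviour and one characteristic, let `delta_device` and
#' `delta_self` be the high-minus-low level difference (min/day) estimated
#' under each method. The pattern is:
#' * `inverting` - the differences have opposite signs and both exceed the
#'   tolerance (the lines cross);
#' * `isomorphic` - the differences agree within the tolerance (parallel
#'   lines);
#' * `converging` - the self-reported difference is smaller in magnitude;
#' * `diverging` - the self-reported difference is larger in magnitude.
#'
#' @param delta_device,delta_self Numeric vectors of level differences.
#' @param tolerance Min/day below which differences are treated as equal
#'   (default 5, the scale of display rounding).
#' @return A character vector of pattern labels.
#' @export
classify_pattern <- function(delta_device, delta_self, tolerance = 5) {
  stopifnot(length(delta_device) == length(delta_self))
  mapply(function(dd, ds) {
    if (sign(dd) != sign(ds) && abs(dd) > tolerance && abs(ds) > tolerance) {
      "inverting"
    } else if (abs(ds - dd) <= tolerance) {
      "isomorphic"
    } else if (abs(ds) < abs(dd) - tolerance) {
      "converging"
    } else if (abs(ds) > abs(dd) + tolerance) {
      "diverging"
    } else {
      "isomorphic"
    }
  }, delta_device, delta_self)
}

#' Pattern labels for a fitted model's extreme levels
#'
#' Convenience wrapper: takes the first and last display level of
#' [estimate_compositions()] output and labels each behaviour's pattern.
#'
#' @param estimates Output of [estimate_compositions()] for one
#'   characteristic.
#' @inheritParams classify_pattern
#' @return A tibble `behaviour`, `delta_device`, `delta_self`, `pattern`.
#' @export
pattern_from_estimates <- function(estimates, tolerance = 5) {
  lv <- unique(estimates$level)
  lo <- lv[1]; hi <- lv[length(lv)]
  purrr::map_dfr(BEHAVIOURS, function(b) {
    g <- function(level, method) {
      estimates[[b]][estimates$level == level & estimates$method == method]
    }
    dd <- g(hi, "device") - g(lo, "device")
    ds <- g(hi, "self") - g(lo, "self")
    tibble(behaviour = b, delta_device = dd, delta_self = ds,
           pattern = classify_pattern(dd, ds, tolerance))
  })
}

#' Run the interaction model for every characteristic
#'
#' Fits one model per characteristic and assembles an omnibus-test table
#' with per-level, per-method composition estimates and pattern labels.
#'
#' @param records Output of [average_per_participant()].
#' @param characteristics Characteristic columns to model.
#' @param sbp Sequential binary partition.
#' @param tolerance Pattern tolerance in min/day.
#' @return A list: `tests` (one row per characteristic: chi2, df, p, n),
#'   `estimates` (stacked composition estimates), `patterns` (per
#'   behaviour x characteristic labels), `fits` (the `coda_fit` objects).
#' @export
run_interaction_models <- function(records,
                                   characteristics = c(
                                     "sex", "age", "puberty",
                                     "parental_education", "zbmi",
                                     "vo2max", "pat"
                                   ),
                                   sbp = sbp_default(), tolerance = 5) {
  fits <- list()
  tests <- list()
  estimates <- list()
  patterns <- list()
  for (chr in characteristics) {
    stacked <- build_stacked(records, chr, sbp = sbp)
    fit <- fit_interaction_model(stacked)
    fits[[chr]] <- fit
    tests[[chr]] <- omnibus_interaction_test(fit)
    est <- estimate_compositions(fit)
    estimates[[chr]] <- est
    patterns[[chr]] <- dplyr::mutate(pattern_from_estimates(est, tolerance),
                                     characteristic = chr, .before = 1)
  }
  list(
    tests = dplyr::bind_rows(tests),
    estimates = dplyr::bind_rows(estimates),
    patterns = dplyr::bind_rows(patterns),
    fits = fits
  )
}

#' @export
glance.coda_fit <- function(x, ...) {
  om <- omnibus_interaction_test(x)
  dplyr::mutate(om,
    formula = x$formula,
    n_simplifications = length(x$simplification_log)
  )
}

#' @export
tidy.coda_fit <- function(x, ...) {
  beta <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    statistic = unname(beta / se)
  )
}
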