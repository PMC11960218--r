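records_fixture <- function(n = 120, seed = 2, ...) {
  simulate_participant_records(n = n, seed = seed, ...)
}

test_that("stacking yields six rows per participant with recorded scaling", {
  rec <- records_fixture(n = 120)
  st <- build_stacked(rec, "sex")
  expect_equal(nrow(st), 720)
  expect_equal(attr(st, "char_type"), "categorical")
  st2 <- build_stacked(rec, "score")
  expect_equal(mean(st2$x[st2$ilr_index == "z1" & st2$method == "device"]), 0,
               tolerance = 1e-12)
  expect_equal(sd(st2$x[st2$ilr_index == "z1" & st2$method == "device"]), 1,
               tolerance = 1e-12)
  # participants missing the characteristic fall out of that model only
  rec$score[1:17] <- NA
  expect_equal(nrow(build_stacked(rec, "score")), (120 - 17) * 6)
  rec$sex <- "female"
  expect_error(build_stacked(rec, "sex"), "fewer than 2")
})

test_that("identical compositions per method yield near-zero method terms", {
  rec <- records_fixture(n = 80, sd_noise = 0.05)
  for (b in c("sleep", "sed", "lpa", "mvpa")) {
    rec[[paste0(b, "_min_self")]] <- rec[[paste0(b, "_min_device")]]
  }
  fit <- fit_interaction_model(build_stacked(rec, "sex"))
  co <- tidy(fit)
  method_terms <- co$estimate[grepl("method", co$term)]
  expect_true(all(abs(method_terms) < 1e-8))
})

test_that("symmetric data give near-equal estimates across sexes", {
  rec <- records_fixture(n = 400, seed = 10)
  fit <- fit_interaction_model(build_stacked(rec, "sex"))
  est <- estimate_compositions(fit)
  expect_true(all(abs(rowSums(est[, c("sleep", "sed", "lpa", "mvpa")]) - 1440) < 1e-6))
  for (m in c("device", "self")) {
    f <- est[est$method == m & est$level == "female", c("sleep", "sed", "lpa", "mvpa")]
    g <- est[est$method == m & est$level == "male", c("sleep", "sed", "lpa", "mvpa")]
    expect_true(all(abs(unlist(f) - unlist(g)) < 15))  # Monte-Carlo error only
  }
})

test_that("degrees of freedom follow the three-per-contrast rule", {
  rec <- records_fixture(n = 150, seed = 8)
  rec$edu <- sample(c("low", "mid", "high"), 150, replace = TRUE)
  expect_equal(omnibus_interaction_test(
    fit_interaction_model(build_stacked(rec, "sex")))$df, 3)
  expect_equal(omnibus_interaction_test(
    fit_interaction_model(build_stacked(rec, "score")))$df, 3)
  expect_equal(omnibus_interaction_test(
    fit_interaction_model(build_stacked(rec, "edu")))$df, 6)
})

test_that("the omnibus statistic is invariant to the choice of partition", {
  rec <- records_fixture(n = 200, seed = 15, sd_wave = 0.05, sd_school = 0.08)
  alt <- rbind(c(1, 1, -1, -1), c(1, -1, 0, 0), c(0, 0, 1, -1))
  colnames(alt) <- c("sleep", "sed", "lpa", "mvpa")
  f1 <- fit_interaction_model(build_stacked(rec, "score"))
  f2 <- fit_interaction_model(build_stacked(rec, "score", sbp = alt))
  om1 <- omnibus_interaction_test(f1)
  om2 <- omnibus_interaction_test(f2)
  expect_equal(om1$df, om2$df)
  expect_equal(om1$chi2, om2$chi2, tolerance = 1e-2)
})

test_that("continuous characteristics are displayed at mean and +/- 1 SD", {
  rec <- records_fixture(n = 120, seed = 3)
  fit <- fit_interaction_model(build_stacked(rec, "score"))
  est <- estimate_compositions(fit)
  lv <- unique(as.numeric(est$level))
  expect_equal(lv[2], mean(rec$score), tolerance = 1e-6)
  expect_equal(lv[3] - lv[1], 2 * sd(rec$score), tolerance = 1e-6)
  expect_warning(estimate_compositions(fit, levels = c(-50, 0, 50)),
                 "outside the observed")
})

test_that("pattern classification implements the four-way taxonomy", {
  expect_equal(classify_pattern(20, -15, 5), "inverting")
  expect_equal(classify_pattern(20, 20, 5), "isomorphic")
  expect_equal(classify_pattern(40, 10, 5), "converging")
  expect_equal(classify_pattern(10, 40, 5), "diverging")
  expect_equal(classify_pattern(-40, -10, 5), "converging")
  # tiny opposite-sign deltas are parallel-ish, not inverting
  expect_equal(classify_pattern(3, -3, 5), "isomorphic")
  expect_equal(classify_pattern(c(20, 40), c(-15, 10), 5),
               c("inverting", "converging"))
})

test_that("a planted sex-by-method shift is recovered and labelled", {
  shift <- list(female = c(sleep = 0, sed = 0, lpa = -30, mvpa = 30),
                male = c(sleep = 0, sed = 0, lpa = 0, mvpa = 0))
  rec <- records_fixture(n = 500, seed = 77, self_shift_by_sex = shift)
  fit <- fit_interaction_model(build_stacked(rec, "sex"))
  om <- omnibus_interaction_test(fit)
  expect_lt(om$p, 1e-6)
  pat <- pattern_from_estimates(estimate_compositions(fit))
  # male minus female difference flips for mvpa between methods
  expect_equal(pat$pattern[pat$behaviour == "mvpa"], "diverging")
})

test_that("wald_p maps chi-squared statistics to upper-tail p-values", {
  expect_equal(wald_p(0, 3), 1)
  expect_equal(wald_p(23, 6), pchisq(23, 6, lower.tail = FALSE))
  expect_lt(wald_p(23, 6), wald_p(23, 7))
})
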