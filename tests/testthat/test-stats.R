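test_that("bilateral difference is absolute and symmetric", {
  expect_equal(bilateral_difference(62, 62), 0)
  expect_equal(bilateral_difference(62.0, 55.64), 6.36)
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(bilateral_difference(a, b), bilateral_difference(b, a))
  expect_true(all(bilateral_difference(a, b) >= 0))
})

test_that("left-right correlation behaves like Pearson r", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_lr(x, x), 1)
  expect_equal(pearson_lr(x, -x + 10), -1)
  sim <- withr::with_seed(2, {
    z <- rnorm(1e4); e <- rnorm(1e4)
    list(l = z, r = 0.7 * z + sqrt(1 - 0.49) * e)
  })
  expect_equal(pearson_lr(sim$l, sim$r), 0.7, tolerance = 0.02)
  expect_error(pearson_lr(rep(1, 5), rnorm(5)),
               class = "auriclesym_degenerate_error")
})

test_that("reliability threshold closed forms and monotonicity", {
  expect_equal(reliability_threshold(1, 1), 0)
  expect_equal(reliability_threshold(1, 0), 1.96 * sqrt(2))
  expect_equal(reliability_threshold(0.5, 0.5), 0.98)
  expect_equal(reliability_threshold(2, positional = TRUE), 3.92)
  # literal (no-radical) variant for sensitivity analysis
  expect_equal(reliability_threshold(1, 0.5, variant = "literal"), 1.96)
  # monotone non-increasing in r, linear in SD
  rs <- seq(-1, 1, 0.1)
  tr <- reliability_threshold(1, rs)
  expect_true(all(diff(tr) <= 1e-12))
  expect_equal(reliability_threshold(3, 0.4), 3 * reliability_threshold(1, 0.4))
  expect_error(reliability_threshold(1, 1.5), class = "auriclesym_input_error")
})

test_that("asymmetry classification flags exceedances", {
  expect_equal(classify_asymmetry(c(0, 0, 0), 1)$fraction, 0)
  cl <- classify_asymmetry(c(1, 3), 2)
  expect_identical(cl$flags, c(FALSE, TRUE))
  expect_equal(cl$fraction, 0.5)
})

test_that("group tests: identity, strong shift, and null calibration", {
  x <- c(60, 62, 65, 58, 61)
  g <- group_tests(x, x)
  expect_equal(g$t_p, 1)
  shift <- withr::with_seed(3, x2 <- rnorm(30, 60, 3))
  g2 <- group_tests(x2, x2 + 5 + rnorm(30, 0, 0.01))
  expect_lt(g2$t_p, 1e-6)
  # ~95% of null cohorts give p > 0.05
  ps <- withr::with_seed(4, vapply(1:400, function(k) {
    l <- rnorm(25, 60, 4); r <- l + rnorm(25, 0, 0.5)
    group_tests(l, r)$t_p
  }, 0))
  expect_equal(mean(ps > 0.05), 0.95, tolerance = 0.035)
})

test_that("precision from repeats is the sample SD", {
  expect_equal(precision_from_repeats(data.frame(length = c(2, 2, 2)))$sd, 0)
  expect_equal(precision_from_repeats(data.frame(length = c(1, 2, 3)))$sd, 1)
  expect_error(precision_from_repeats(data.frame(length = 1)),
               class = "auriclesym_input_error")
  # chi-square spread: 50 repeats with injected noise
  reps <- withr::with_seed(5, data.frame(p = 60 + rnorm(50, 0, 0.3)))
  expect_equal(precision_from_repeats(reps)$sd, 0.3, tolerance = 0.2)
})

test_that("null flag rate is calibrated at 5% for any truth spread", {
  for (tsd in c(0.5, 5, 20)) {
    r <- simulate_null_flag_rate(n = 4000, noise_sd = 0.3, truth_sd = tsd,
                                 seed = 42)
    expect_lt(abs(r$fraction - 0.05), 0.013)
    expect_lt(abs(r$threshold - 1.96 * sqrt(2) * 0.3), 0.03)
  }
})

cohort_table <- function(n = 12, seed = 9, asym = 0) {
  withr::with_seed(seed, {
    base <- list(length = rnorm(n, 62, 4), width = rnorm(n, 32, 3),
                 protrusion = rnorm(n, 20, 2.5), acangle = rnorm(n, 30, 4),
                 inclination = rnorm(n, 25, 4))
    mk <- function(side_sign) {
      data.frame(subject = seq_len(n), side = if (side_sign > 0) "left" else "right",
                 length = base$length + side_sign * asym / 2 + rnorm(n, 0, 0.1),
                 width = base$width + rnorm(n, 0, 0.1),
                 protrusion = base$protrusion + rnorm(n, 0, 0.1),
                 acangle = base$acangle + rnorm(n, 0, 0.1),
                 inclination = base$inclination + rnorm(n, 0, 0.1),
                 centroid_x = 80 * side_sign, centroid_y = rnorm(n, -15, 0.1),
                 centroid_z = rnorm(n, -12, 0.1))
    }
    rbind(mk(1), mk(-1))
  })
}

ref_precision <- function(sds, method) precision_table(sds, method)

seven_sds <- function(x) {
  stats::setNames(rep(x, 7),
                  c("length", "width", "protrusion", "acangle",
                    "inclination", "si_position", "pa_position"))
}

test_that("cohort summary assembles thresholds, flags and tests", {
  tab <- cohort_table(asym = 4)
  rep <- summarize_cohort(tab, ref_precision(seven_sds(0.1), "automatic"))
  pp <- rep$per_parameter
  expect_setequal(pp$parameter,
                  c("length", "width", "protrusion", "acangle", "inclination",
                    "si_position", "pa_position"))
  expect_true(all(pp$threshold >= 0))
  expect_true(all(pp$detection_fraction >= 0 & pp$detection_fraction <= 1))
  # injected 4 mm length asymmetry must be detected in every subject
  expect_equal(pp$detection_fraction[pp$parameter == "length"], 1)
  # per-subject flags are consistent with the threshold
  ps <- rep$per_subject
  expect_identical(ps$flagged, ps$abs_diff > ps$threshold)
  # missing precision entry is a configuration error
  bad <- precision_table(c(length = 0.1), "automatic")
  expect_error(summarize_cohort(tab, bad), class = "auriclesym_config_error")
})

test_that("lower precision SDs never detect less asymmetry", {
  tab <- cohort_table(asym = 3)
  rep_auto <- summarize_cohort(tab, ref_precision(seven_sds(0.15), "automatic"))
  rep_man <- summarize_cohort(tab, ref_precision(seven_sds(2.0), "manual"))
  merged <- merge(rep_auto$per_parameter[, c("parameter", "detection_fraction")],
                  rep_man$per_parameter[, c("parameter", "detection_fraction")],
                  by = "parameter", suffixes = c("_auto", "_man"))
  expect_true(all(merged$detection_fraction_auto >=
                    merged$detection_fraction_man))
})

test_that("cohort summary is invariant to subject order", {
  tab <- cohort_table(asym = 2)
  rep1 <- summarize_cohort(tab, ref_precision(seven_sds(0.5), "automatic"))
  perm <- withr::with_seed(10, tab[sample.int(nrow(tab)), ])
  rep2 <- summarize_cohort(perm, ref_precision(seven_sds(0.5), "automatic"))
  expect_equal(rep1$per_parameter, rep2$per_parameter)
})
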