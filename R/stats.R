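# Bilateral-symmetry statistics: reliable-change reliability thresholds,
# per-individual asymmetry classification, and group-level tests.

#' Absolute bilateral difference
#'
#' @param left,right Parameter values in the same units.
#' @return `|left - right|` (vectorized).
#' @export
bilateral_difference <- function(left, right) abs(left - right)

#' Pearson correlation between left and right values
#'
#' The correlation coefficient of the linear trend line between the left and
#' right values of a parameter across a cohort.
#'
#' @param lefts,rights Numeric vectors, `n >= 3`.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_lr <- function(lefts, rights) {
  if (length(lefts) < 3L || length(lefts) != length(rights))
    stop_input("need matched vectors of at least 3 left/right values")
  if (sd(lefts) == 0 || sd(rights) == 0)
    stop_degenerate("correlation undefined: zero variance on one side")
  cor(lefts, rights)
}

#' Reliability threshold for a bilateral difference
#'
#' Smallest bilateral difference distinguishable from measurement noise at
#' the two-sided 5% level. Non-positional parameters use the
#' reliable-change-index form `T_rel = 1.96 * SD * sqrt(2 * (1 - r))`
#' (`variant = "radical"`, the default); `variant = "literal"` uses
#' `1.96 * SD * 2 * (1 - r)` for sensitivity analysis. Positional parameters
#' are already bilateral differences, so their threshold is `1.96 * SD`,
#' ignoring `r`.
#'
#' @param sd Measurement-precision SD, same units as the parameter.
#' @param r Left-right Pearson correlation (ignored when `positional`).
#' @param positional Is the parameter itself a bilateral position
#'   difference?
#' @param variant `"radical"` (default) or `"literal"`.
#' @return Threshold, same units as `sd`.
#' @export
reliability_threshold <- function(sd, r = NULL, positional = FALSE,
                                  variant = c("radical", "literal")) {
  variant <- match.arg(variant)
  if (any(sd < 0)) stop_input("sd must be non-negative")
  if (positional) return(1.96 * sd)
  if (is.null(r) || any(!is.finite(r)) || any(r < -1) || any(r > 1))
    stop_input("r must be in [-1, 1]")
  if (variant == "radical") 1.96 * sd * sqrt(2 * (1 - r))
  else 1.96 * sd * 2 * (1 - r)
}

#' Classify per-individual asymmetry against a threshold
#'
#' @param differences Absolute bilateral differences.
#' @param threshold Reliability threshold (same units).
#' @return List with logical `flags` (`difference > threshold`) and
#'   `fraction` (mean flag rate).
#' @export
classify_asymmetry <- function(differences, threshold) {
  if (threshold < 0) stop_input("threshold must be non-negative")
  flags <- differences > threshold
  list(flags = flags, fraction = mean(flags))
}

#' Group-level tests of left vs right
#'
#' Paired t-test on the left-minus-right differences and Shapiro-Wilk
#' normality per side, as routinely reported alongside individual-level
#' classification. Non-normality does not alter the main pipeline; it is the
#' caller's job to note it.
#'
#' @param lefts,rights Matched vectors, `n >= 3`.
#' @return List with `t_p` (two-sided paired-t p-value), `normality_p_left`,
#'   `normality_p_right`, `mean_left`, `sd_left`, `mean_right`, `sd_right`.
#' @export
group_tests <- function(lefts, rights) {
  if (length(lefts) < 3L || length(lefts) != length(rights))
    stop_input("need matched vectors of at least 3 left/right values")
  d <- lefts - rights
  if (sd(d) == 0) {
    if (all(d == 0)) {
      tp <- 1
    } else {
      stop_degenerate("constant nonzero differences: paired t undefined")
    }
  } else {
    tp <- t.test(lefts, rights, paired = TRUE)$p.value
  }
  shap <- function(x) {
    if (sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  list(t_p = tp,
       normality_p_left = shap(lefts), normality_p_right = shap(rights),
       mean_left = mean(lefts), sd_left = sd(lefts),
       mean_right = mean(rights), sd_right = sd(rights))
}

#' Measurement-precision SDs from repeated measurements
#'
#' Sample SD (n-1 denominator) per parameter across repeated measurements of
#' the same specimen — the test-retest precision that the reliability
#' thresholds are built from.
#'
#' @param repeats data.frame/matrix with one row per repeat and one column
#'   per parameter, or a named list of repeat vectors.
#' @param method Tag recorded in the table (`"automatic"` or `"manual"`).
#' @return data.frame of class `precision_table` with columns `parameter`,
#'   `sd`, `method`.
#' @export
precision_from_repeats <- function(repeats, method = "automatic") {
  if (is.list(repeats) && !is.data.frame(repeats))
    repeats <- as.data.frame(repeats)
  repeats <- as.data.frame(repeats)
  if (nrow(repeats) < 2L)
    stop_input("precision needs at least 2 repeated measurements")
  out <- data.frame(parameter = names(repeats),
                    sd = vapply(repeats, function(x) sd(x), 0),
                    method = method, row.names = NULL)
  class(out) <- c("precision_table", "data.frame")
  out
}

#' Construct a precision table directly from SD values
#'
#' @param sds Named numeric vector of per-parameter SDs.
#' @param method Method tag.
#' @return A `precision_table` data.frame.
#' @export
precision_table <- function(sds, method = "manual") {
  if (is.null(names(sds))) stop_input("sds must be a named vector")
  if (any(sds < 0)) stop_input("SDs must be non-negative")
  out <- data.frame(parameter = names(sds), sd = as.numeric(sds),
                    method = method, row.names = NULL)
  class(out) <- c("precision_table", "data.frame")
  out
}

#' Monte-Carlo null flag rate of the reliability threshold
#'
#' Simulates a cohort with zero true bilateral difference: per subject a true
#' value is drawn from a normal distribution, both sides measure that same
#' truth plus independent Gaussian measurement noise. The threshold is
#' computed from the simulated cohort itself — the reliable-change-index
#' convention, with SD the cohort sample SD of the measurements and r the
#' left-right correlation — which makes the threshold equal
#' `1.96 * sqrt(2) * noise_sd` up to sampling error for any truth
#' distribution, so the expected flag rate is the nominal 5%.
#'
#' @param n Number of simulated subjects.
#' @param noise_sd Per-side measurement noise SD.
#' @param truth_mean,truth_sd Between-subject distribution of the true value.
#' @param seed RNG seed.
#' @param variant Threshold variant, see [reliability_threshold()].
#' @return List with `fraction` (flag rate), `threshold`, `r`, `n`.
#' @export
simulate_null_flag_rate <- function(n = 2000L, noise_sd = 0.25,
                                    truth_mean = 60, truth_sd = 5,
                                    seed = 1L,
                                    variant = c("radical", "literal")) {
  variant <- match.arg(variant)
  sim <- with_seed(seed, {
    truth <- rnorm(n, truth_mean, truth_sd)
    list(left = truth + rnorm(n, 0, noise_sd),
         right = truth + rnorm(n, 0, noise_sd))
  })
  r <- pearson_lr(sim$left, sim$right)
  sd_cohort <- sqrt((var(sim$left) + var(sim$right)) / 2)
  thr <- reliability_threshold(sd_cohort, r, variant = variant)
  cls <- classify_asymmetry(bilateral_difference(sim$left, sim$right), thr)
  list(fraction = cls$fraction, threshold = thr, r = r, n = n)
}
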