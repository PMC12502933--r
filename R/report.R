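# Cohort-level symmetry report: per-parameter left/right values, absolute
# differences, reliability thresholds, asymmetry flags and detection
# fractions, plus group-level tests.

.paired_params <- c("length", "width", "protrusion", "acangle", "inclination")
.positional_params <- c("si_position", "pa_position")

#' Summarize bilateral symmetry of a measured cohort
#'
#' Assembles, for each of the seven parameters: the left-right correlation r,
#' the reliability threshold from the supplied precision SD, per-subject
#' asymmetry flags and the detection fraction, and group-level tests. The
#' paired parameters (length, width, protrusion, auriculocephalic angle,
#' inclination) use the reliable-change threshold `1.96*SD*sqrt(2(1-r))`
#' with r computed from the cohort being analyzed; the positional parameters
#' are already bilateral differences and use `1.96*SD` with a one-sample
#' t-test against zero.
#'
#' @param measurements data.frame with one row per subject and side:
#'   columns `subject`, `side` (`"left"`/`"right"`), `length`, `width`,
#'   `protrusion`, `acangle`, `inclination`, `centroid_y`, `centroid_z`
#'   (see [measurement_row()]).
#' @param precision A `precision_table` covering all seven parameters
#'   (`length`, `width`, `protrusion`, `acangle`, `inclination`,
#'   `si_position`, `pa_position`).
#' @param variant Threshold variant, see [reliability_threshold()].
#' @return List of class `symmetry_report`: `per_parameter` (one row per
#'   parameter: `r`, `sd`, `threshold`, `detection_fraction`, `t_p`,
#'   normality p-values, per-side mean/SD), `per_subject` (one row per
#'   subject and parameter: left, right, `abs_diff`, `threshold`, `flagged`),
#'   `method`, `variant`.
#' @export
summarize_cohort <- function(measurements, precision,
                             variant = c("radical", "literal")) {
  variant <- match.arg(variant)
  measurements <- as.data.frame(measurements)
  need <- c("subject", "side", .paired_params, "centroid_y", "centroid_z")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0L)
    stop_config(paste0("measurement table lacks column(s): ",
                       paste(miss, collapse = ", ")))
  sds <- precision$sd
  names(sds) <- precision$parameter
  allp <- c(.paired_params, .positional_params)
  miss <- setdiff(allp, names(sds))
  if (length(miss) > 0L)
    stop_config(paste0("precision table lacks parameter(s): ",
                       paste(miss, collapse = ", ")))

  L <- measurements[measurements$side == "left", , drop = FALSE]
  R <- measurements[measurements$side == "right", , drop = FALSE]
  L <- L[order(L$subject), , drop = FALSE]
  R <- R[order(R$subject), , drop = FALSE]
  if (nrow(L) != nrow(R) || any(L$subject != R$subject))
    stop_config("every subject needs exactly one left and one right row")

  per_param <- list()
  per_subject <- list()
  for (p in .paired_params) {
    lv <- L[[p]]
    rv <- R[[p]]
    r <- pearson_lr(lv, rv)
    thr <- reliability_threshold(sds[[p]], r, variant = variant)
    diffs <- bilateral_difference(lv, rv)
    cls <- classify_asymmetry(diffs, thr)
    gt <- group_tests(lv, rv)
    per_param[[p]] <- data.frame(
      parameter = p, r = r, sd = sds[[p]], threshold = thr,
      detection_fraction = cls$fraction, t_p = gt$t_p,
      normality_p_left = gt$normality_p_left,
      normality_p_right = gt$normality_p_right,
      mean_left = gt$mean_left, sd_left = gt$sd_left,
      mean_right = gt$mean_right, sd_right = gt$sd_right)
    per_subject[[p]] <- data.frame(
      subject = L$subject, parameter = p, left = lv, right = rv,
      abs_diff = diffs, threshold = thr, flagged = cls$flags)
  }
  pos <- list(si_position = L$centroid_y - R$centroid_y,
              pa_position = L$centroid_z - R$centroid_z)
  for (p in .positional_params) {
    dv <- pos[[p]]
    thr <- reliability_threshold(sds[[p]], positional = TRUE)
    diffs <- abs(dv)
    cls <- classify_asymmetry(diffs, thr)
    tp <- if (sd(dv) == 0) {
      if (all(dv == 0)) 1 else NA_real_
    } else {
      t.test(dv)$p.value
    }
    per_param[[p]] <- data.frame(
      parameter = p, r = NA_real_, sd = sds[[p]], threshold = thr,
      detection_fraction = cls$fraction, t_p = tp,
      normality_p_left = if (sd(dv) > 0) shapiro.test(dv)$p.value else NA_real_,
      normality_p_right = NA_real_,
      mean_left = mean(dv), sd_left = sd(dv),
      mean_right = NA_real_, sd_right = NA_real_)
    per_subject[[p]] <- data.frame(
      subject = L$subject, parameter = p, left = NA_real_, right = NA_real_,
      abs_diff = diffs, threshold = thr, flagged = cls$flags)
  }
  structure(list(per_parameter = do.call(rbind, c(per_param,
                                                  make.row.names = FALSE)),
                 per_subject = do.call(rbind, c(per_subject,
                                                make.row.names = FALSE)),
                 method = precision$method[1], variant = variant),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report: method '%s', %d subjects>\n", x$method,
              length(unique(x$per_subject$subject))))
  df <- x$per_parameter
  cat(sprintf("  %-12s r %6s  thr %7s  detected %5s  t_p %6s\n",
              "parameter", "", "", "", ""))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %6s  %7.3f  %4.0f%%     %6.3f\n",
                df$parameter[i],
                ifelse(is.na(df$r[i]), "  -  ", sprintf("%6.3f", df$r[i])),
                df$threshold[i], 100 * df$detection_fraction[i], df$t_p[i]))
  }
  invisible(x)
}

#' Per-subject asymmetry plot with method thresholds
#'
#' Reproduces the standard presentation of individual bilateral differences:
#' one panel per parameter, points are per-subject absolute differences, and
#' horizontal lines mark the reliability thresholds of each supplied method.
#'
#' @param reports Named list of `symmetry_report` objects (e.g.
#'   `list(automatic = ..., manual = ...)`).
#' @return A ggplot object.
#' @export
plot_symmetry_report <- function(reports) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("ggplot2 is required for plotting")
  if (inherits(reports, "symmetry_report")) reports <- list(report = reports)
  pts <- reports[[1]]$per_subject
  thr <- do.call(rbind, lapply(names(reports), function(nm) {
    d <- reports[[nm]]$per_parameter
    data.frame(parameter = d$parameter, threshold = d$threshold, method = nm)
  }))
  pts$parameter <- factor(pts$parameter, levels = unique(pts$parameter))
  thr$parameter <- factor(thr$parameter, levels = levels(pts$parameter))
  pts$subject_index <- ave(seq_len(nrow(pts)), pts$parameter,
                           FUN = seq_along)
  ggplot2::ggplot(pts, ggplot2::aes(x = subject_index, y = abs_diff)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = threshold,
                                     color = method)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "subject", y = "absolute bilateral difference",
                  color = "threshold") +
    ggplot2::theme_minimal()
}
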