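#' Cross-tabulate paired binary calls into a contingency table
#'
#' The index channel (e.g. synthetic enhancement) is compared against the
#' reference channel (conventional LGE): TP = both positive, FP = index
#' only, FN = reference only, TN = both negative.
#'
#' @param index,reference equal-length logical vectors.
#' @param level `"subsegment"` or `"patient"` (a label carried in the result).
#' @return an object of class `contingency`: fields `tp`, `fp`, `fn`, `tn`,
#'   `total`, `level`.
#' @export
build_contingency <- function(index, reference,
                              level = c("subsegment", "patient")) {
  level <- match.arg(level)
  index <- as.logical(index)
  reference <- as.logical(reference)
  if (length(index) != length(reference)) {
    abort("`index` and `reference` must have equal length.")
  }
  if (anyNA(index) || anyNA(reference)) abort("calls must not contain NA.")
  structure(
    list(tp = sum(index & reference), fp = sum(index & !reference),
         fn = sum(!index & reference), tn = sum(!index & !reference),
         total = length(index), level = level),
    class = "contingency"
  )
}

#' Build a contingency table directly from counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @inheritParams build_contingency
#' @return a `contingency` object.
#' @export
contingency_from_counts <- function(tp, fp, fn, tn,
                                    level = c("subsegment", "patient")) {
  level <- match.arg(level)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn, level = level),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %s level: TP %d, FP %d, FN %d, TN %d (n = %d)\n",
              x$level, x$tp, x$fp, x$fn, x$tn, x$total))
  invisible(x)
}

#' @export
tidy.contingency <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn), level = x$level)
}

clopper_pearson <- function(k, n, conf_level) {
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  c(ci[1], ci[2])
}

#' Diagnostic-accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV as percentages with Clopper-Pearson
#' exact binomial confidence intervals. A metric whose denominator is zero
#' is reported as `NA` (undefined), never as 0.
#'
#' @param table a [build_contingency()] result.
#' @param conf_level confidence level for the intervals.
#' @param digits optional rounding (applied to estimate and CI bounds); the
#'   study convention is integer percent for sensitivity/specificity and one
#'   decimal for PPV/NPV, available as `digits = "display"`.
#' @return a tibble with columns `metric`, `estimate`, `ci_low`, `ci_high`
#'   (percent), `numerator`, `denominator`, `ci_method`, `level`.
#' @examples
#' accuracy(contingency_from_counts(tp = 22, fp = 1, fn = 1, tn = 190,
#'                                  level = "patient"))
#' @export
accuracy <- function(table, conf_level = 0.95, digits = NULL) {
  stopifnot(inherits(table, "contingency"))
  defs <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn)
  )
  rows <- purrr::imap(defs, function(kn, nm) {
    if (kn[2] == 0) {
      return(tibble(metric = nm, estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, numerator = kn[1], denominator = kn[2]))
    }
    ci <- clopper_pearson(kn[1], kn[2], conf_level)
    tibble(metric = nm, estimate = 100 * kn[1] / kn[2],
           ci_low = 100 * ci[1], ci_high = 100 * ci[2],
           numerator = kn[1], denominator = kn[2])
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(digits)) {
    dg <- if (identical(digits, "display")) {
      c(sensitivity = 0, specificity = 0, ppv = 1, npv = 1)[out$metric]
    } else {
      rep(digits, nrow(out))
    }
    out$estimate <- round(out$estimate, dg)
    out$ci_low <- round(out$ci_low, 1)
    out$ci_high <- round(out$ci_high, 1)
  }
  out$ci_method <- "clopper-pearson"
  out$level <- table$level
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b summarized as the mean difference, SD of the
#' differences (n - 1 denominator), and 95% limits of agreement
#' mean +/- 1.96 SD.
#'
#' @param a,b equal-length numeric vectors (e.g. masses in grams from two
#'   methods or readers); length >= 2.
#' @param loa_z multiplier for the limits of agreement (1.96 for 95%).
#' @return an object of class `bland_altman`; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
bland_altman <- function(a, b, loa_z = 1.96) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("at least 2 pairs are required.")
  d <- a - b
  m <- (a + b) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(mean_difference = mean_diff, sd_difference = sd_diff,
         loa_low = mean_diff - loa_z * sd_diff,
         loa_high = mean_diff + loa_z * sd_diff,
         loa_z = loa_z, n = length(a), differences = d, means = m),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean difference %.4g +/- %.4g (n = %d), LoA [%.4g, %.4g]\n",
              x$mean_difference, x$sd_difference, x$n, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean = x$means, difference = x$differences)
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_difference = x$mean_difference, sd_difference = x$sd_difference,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of methods", y = "Difference",
                  title = sprintf("Bland-Altman: %.3g +/- %.3g",
                                  object$mean_difference, object$sd_difference)) +
    ggplot2::theme_minimal()
}

#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(2,1) from the standard mean-squares decomposition of the
#' subjects-by-raters table, with the F-based confidence interval of McGraw
#' and Wong. Absolute agreement penalizes systematic offsets between the
#' raters, unlike Pearson correlation.
#'
#' @param a,b equal-length numeric vectors (two raters/methods); length >= 3.
#' @param conf_level confidence level.
#' @return an object of class `icc_fit` with fields `icc`, `ci_low`,
#'   `ci_high`, `model`, and the mean squares.
#' @export
icc_absolute <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 3) abort("at least 3 paired observations are required.")
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom

  ci <- c(NA_real_, NA_real_)
  if (!is.na(icc) && mse > 0) {
    alpha <- 1 - conf_level
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         model = "two-way random, absolute agreement, single measures (ICC(2,1))",
         msr = msr, msc = msc, mse = mse, n = n, k = k,
         conf_level = conf_level, a = a, b = b),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("<icc_fit> ICC = %.4f (%.0f%% CI %.4f-%.4f)\n  %s\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$model))
  invisible(x)
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
         model = x$model, n = x$n)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble(term = c("subjects", "raters", "error"),
         mean_square = c(x$msr, x$msc, x$mse))
}

#' @export
autoplot.icc_fit <- function(object, ...) {
  df <- tibble(a = object$a, b = object$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Method / rater A", y = "Method / rater B",
                  title = sprintf("ICC = %.4f (%s)", object$icc, "absolute agreement")) +
    ggplot2::theme_minimal()
}

#' Paired comparison tests between two quantification channels
#'
#' Wilcoxon signed-rank test (zero differences dropped, Wilcoxon's original
#' rule, as in [stats::wilcox.test()]), paired t test, Pearson correlation,
#' and medians with interquartile ranges. Degenerate inputs (all differences
#' zero, or constant vectors) yield `NA` statistics rather than errors.
#'
#' @param a,b equal-length numeric vectors, length >= 2.
#' @return a one-row tibble: `n`, `median_a`, `iqr_low_a`, `iqr_high_a`,
#'   `median_b`, `iqr_low_b`, `iqr_high_b`, `wilcoxon_p`, `paired_t`,
#'   `paired_t_p`, `pearson_r`.
#' @export
paired_tests <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("at least 2 pairs are required.")
  d <- a - b
  qa <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
  wilcoxon_p <- if (all(d == 0)) NA_real_ else {
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  }
  if (sd(d) == 0) {
    t_stat <- NA_real_
    t_p <- NA_real_
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  tibble(n = length(a),
         median_a = qa[2], iqr_low_a = qa[1], iqr_high_a = qa[3],
         median_b = qb[2], iqr_low_b = qb[1], iqr_high_b = qb[3],
         wilcoxon_p = wilcoxon_p, paired_t = t_stat, paired_t_p = t_p,
         pearson_r = r)
}

#' Run the full agreement study on a synthetic cohort
#'
#' Reproduces the study's analysis plan on a cohort generated by
#' [make_cohort()]: subsegment- and patient-level contingency tables of the
#' synthetic (index) channel against conventional LGE (reference), accuracy
#' metrics with exact CIs, prevalence, and — on the patients concordantly
#' positive in both channels (patients discordant at the patient level are
#' excluded from quantitative agreement) — Pearson correlation, paired
#' tests, Bland-Altman, and ICC of the per-patient masses.
#'
#' @param cohort an `lv_cohort` from [make_cohort()].
#' @param digits passed to [accuracy()] (`"display"` for study-style
#'   rounding).
#' @return an object of class `agreement_report`: `patient_table`,
#'   `subsegment_table` (contingency objects), `patient_accuracy`,
#'   `subsegment_accuracy` (tibbles), `prevalence_pct`, `n_quantitative`,
#'   `excluded_patients`, `paired` (tibble), `bland_altman`, `icc`.
#' @export
run_study <- function(cohort, digits = NULL) {
  stopifnot(inherits(cohort, "lv_cohort"))
  subs <- cohort$subsegments
  pats <- cohort$patients

  sub_table <- build_contingency(subs$esge_call, subs$lge_call,
                                 level = "subsegment")
  pat_calls <- dplyr::summarise(
    dplyr::group_by(subs, .data$patient_id),
    esge = any(.data$esge_call), lge = any(.data$lge_call), .groups = "drop"
  )
  pat_table <- build_contingency(pat_calls$esge, pat_calls$lge,
                                 level = "patient")

  concordant <- pat_calls$patient_id[pat_calls$esge & pat_calls$lge]
  excluded <- pat_calls$patient_id[xor(pat_calls$esge, pat_calls$lge)]
  qp <- pats[pats$patient_id %in% concordant, ]

  paired <- NULL
  ba <- NULL
  icc <- NULL
  if (nrow(qp) >= 3) {
    paired <- paired_tests(qp$esge_mass_g, qp$lge_mass_g)
    ba <- bland_altman(qp$esge_mass_g, qp$lge_mass_g)
    icc <- icc_absolute(qp$esge_mass_g, qp$lge_mass_g)
  }

  structure(
    list(patient_table = pat_table, subsegment_table = sub_table,
         patient_accuracy = accuracy(pat_table, digits = digits),
         subsegment_accuracy = accuracy(sub_table, digits = digits),
         prevalence_pct = 100 * sum(pat_calls$lge) / nrow(pat_calls),
         n_quantitative = nrow(qp), excluded_patients = excluded,
         paired = paired, bland_altman = ba, icc = icc),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  patients: TP %d FP %d FN %d TN %d; prevalence %.1f%%\n",
              x$patient_table$tp, x$patient_table$fp, x$patient_table$fn,
              x$patient_table$tn, x$prevalence_pct))
  cat(sprintf("  subsegments: TP %d FP %d FN %d TN %d (n = %d)\n",
              x$subsegment_table$tp, x$subsegment_table$fp,
              x$subsegment_table$fn, x$subsegment_table$tn,
              x$subsegment_table$total))
  cat(sprintf("  quantitative agreement in %d concordant-positive patients",
              x$n_quantitative))
  if (length(x$excluded_patients) > 0) {
    cat(sprintf(" (%d discordant excluded)", length(x$excluded_patients)))
  }
  cat("\n")
  if (!is.null(x$paired)) {
    cat(sprintf("  r = %.4f, mean difference %.4g +/- %.4g g, ICC %.4f\n",
                x$paired$pearson_r, x$bland_altman$mean_difference,
                x$bland_altman$sd_difference, x$icc$icc))
  }
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::bind_rows(x$patient_accuracy, x$subsegment_accuracy)
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n_patients = x$patient_table$total,
    n_subsegments = x$subsegment_table$total,
    prevalence_pct = x$prevalence_pct,
    n_quantitative = x$n_quantitative,
    pearson_r = if (is.null(x$paired)) NA_real_ else x$paired$pearson_r,
    mean_difference_g = if (is.null(x$bland_altman)) NA_real_ else x$bland_altman$mean_difference,
    sd_difference_g = if (is.null(x$bland_altman)) NA_real_ else x$bland_altman$sd_difference,
    icc = if (is.null(x$icc)) NA_real_ else x$icc$icc
  )
}
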