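#' Construct a paired measurement series
#'
#' Per-subject pairs of one measurement under two methods: a reference
#' (conventional caliper, CM) and an automated value (AM). Pairs are
#' aligned by subject id; differences are oriented reference minus
#' automated.
#'
#' @param measurement Measurement id (e.g. "M3").
#' @param subject_id Subject identifiers.
#' @param reference Reference (caliper) values, mm.
#' @param automated Automated values, mm, same subjects in the same order.
#' @return A `paired_series` list.
#' @export
paired_series <- function(measurement, subject_id, reference, automated) {
  n <- length(subject_id)
  if (n < 2L) fm_stop("fm_data_error", "a paired series needs n >= 2")
  if (length(reference) != n || length(automated) != n) {
    fm_stop("fm_pairing_error", "reference and automated must match subjects")
  }
  if (anyDuplicated(subject_id)) {
    fm_stop("fm_pairing_error", "duplicated subject id in paired series")
  }
  structure(list(measurement = measurement, subject_id = subject_id,
                 reference = as.numeric(reference),
                 automated = as.numeric(automated), n = n),
            class = "paired_series")
}

#' Mean and SD of paired differences
#'
#' @param series A [paired_series()].
#' @return List with `mean` and `sd` (sample SD, n-1 denominator) of
#'   reference - automated, and `n`.
#' @export
paired_differences <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$reference - series$automated
  list(mean = mean(d), sd = sd(d), n = series$n)
}

#' Paired t-test from summary statistics
#'
#' `t = mean_d / (sd_d / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided. Degenerate series (zero SD) use the conventions p = 0 when
#' the mean difference is nonzero (flagged) and p = 1 when it is zero.
#'
#' @param mean_d Mean of the paired differences.
#' @param sd_d Sample SD of the differences.
#' @param n Number of pairs (>= 2).
#' @return List with `t`, `df`, `p`, and `degenerate` flag.
#' @export
paired_t_test <- function(mean_d, sd_d, n) {
  if (n < 2) fm_stop("fm_data_error", "paired t-test needs n >= 2")
  if (sd_d < 0) fm_stop("fm_value_error", "sd must be >= 0")
  df <- n - 1
  if (sd_d == 0) {
    if (mean_d == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(mean_d) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- mean_d / (sd_d / sqrt(n))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

report_row <- function(measurement, version, n, mean_ref, sd_ref,
                       mean_am, sd_am, mean_diff, sd_diff) {
  tt <- paired_t_test(mean_diff, sd_diff, n)
  data.frame(measurement = measurement, version = version, n = n,
             mean_cm = mean_ref, sd_cm = sd_ref,
             mean_am = mean_am, sd_am = sd_am,
             mean_diff = mean_diff, sd_diff = sd_diff,
             t = tt$t, df = tt$df, p = tt$p,
             sig_05 = tt$p < 0.05, sig_01 = tt$p < 0.01)
}

#' Build the full agreement report
#'
#' For every measurement M1-M9 and every automated version supplied,
#' computes group means +/- SD per method, the mean +/- SD of the paired
#' differences (CM - AM), the paired t statistic and two-sided p-value,
#' and significance flags at the 5% and 1% levels. No multiple-testing
#' correction is applied; raw p-values are reported.
#'
#' @param cm Data frame of conventional measurements (`subject_id`,
#'   `M1`-`M9`).
#' @param am1 Data frame of automated measurements, version 1.
#' @param am2 Optional data frame for version 2.
#' @return Data frame, one row per measurement x version.
#' @export
build_report <- function(cm, am1, am2 = NULL) {
  versions <- list(AM1 = am1)
  if (!is.null(am2)) versions$AM2 <- am2
  mids <- paste0("M", 1:9)
  for (df in c(list(cm), versions)) {
    missing <- setdiff(c("subject_id", mids), names(df))
    if (length(missing)) {
      fm_stop("fm_data_error", "measurement table misses column %s", missing[1])
    }
  }
  cm <- cm[order(cm$subject_id), ]
  rows <- list()
  for (v in names(versions)) {
    am <- versions[[v]]
    if (!setequal(cm$subject_id, am$subject_id)) {
      fm_stop("fm_pairing_error", "subject ids differ between CM and %s", v)
    }
    am <- am[order(am$subject_id), ]
    for (m in mids) {
      s <- paired_series(m, cm$subject_id, cm[[m]], am[[m]])
      d <- paired_differences(s)
      rows[[length(rows) + 1L]] <- report_row(
        m, v, d$n, mean(s$reference), sd(s$reference),
        mean(s$automated), sd(s$automated), d$mean, d$sd)
    }
  }
  do.call(rbind, rows)
}

#' Agreement report from published summary statistics
#'
#' Rebuilds the t-tests and significance flags directly from per-row
#' summary statistics (mean +/- SD of the paired differences at a given
#' n), as when recomputing a printed comparison table.
#'
#' @param stats Data frame with columns `measurement`, `version`, `n`,
#'   `mean_diff`, `sd_diff` and optionally the group `mean_cm`, `sd_cm`,
#'   `mean_am`, `sd_am`.
#' @return Data frame in the [build_report()] layout.
#' @export
agreement_from_summary <- function(stats) {
  need <- c("measurement", "version", "n", "mean_diff", "sd_diff")
  missing <- setdiff(need, names(stats))
  if (length(missing)) {
    fm_stop("fm_data_error", "summary table misses column %s", missing[1])
  }
  opt <- function(col, i) if (col %in% names(stats)) stats[[col]][i] else NA_real_
  do.call(rbind, lapply(seq_len(nrow(stats)), function(i) {
    report_row(stats$measurement[i], stats$version[i], stats$n[i],
               opt("mean_cm", i), opt("sd_cm", i),
               opt("mean_am", i), opt("sd_am", i),
               stats$mean_diff[i], stats$sd_diff[i])
  }))
}

#' Count measurements in significant disagreement
#'
#' @param report A [build_report()] / [agreement_from_summary()] data frame.
#' @param alpha Significance level (default 0.01).
#' @param require_both Count a measurement only when p < alpha in every
#'   version present (default TRUE); otherwise any version suffices.
#' @return Number of measurements flagged.
#' @export
count_significant <- function(report, alpha = 0.01, require_both = TRUE) {
  sig <- tapply(report$p < alpha, report$measurement,
                if (require_both) all else any)
  sum(sig)
}

#' Write the agreement report as CSV
#'
#' @param report A [build_report()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 4)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Published 20-subject caliper-vs-program comparison
#'
#' Summary statistics of the clinical validation of the original program:
#' per measurement and program version (AM1 trained 200 epochs, AM2
#' trained 1000), the group mean +/- SD under conventional caliper
#' measurement (CM) and under the program, and the mean +/- SD of the
#' paired differences (CM - AM), all in mm, n = 20 adults. These are the
#' reference inputs for reproducing the published t-tests; small
#' inconsistencies between the printed difference rows and the printed
#' group means (e.g. M4 -1.71 vs -1.72) are printed-rounding artifacts of
#' the source tables.
#'
#' @return Data frame with columns `measurement`, `label`, `version`, `n`,
#'   `mean_cm`, `sd_cm`, `mean_am`, `sd_am`, `mean_diff`, `sd_diff`.
#' @export
reference_agreement_stats <- function() {
  label <- c("middle third", "lower third", "intercanthal distance",
             "alar base", "upper lip", "upper lip vermilion",
             "lower lip", "lower lip vermilion", "interlabial gap")
  cm_mean <- c(62.47, 67.42, 32.02, 33.36, 20.55, 9.27, 45.21, 11.96, 2.20)
  cm_sd   <- c(5.05, 6.22, 2.41, 3.54, 3.08, 1.35, 4.79, 1.88, 0.93)
  am1_mean <- c(56.33, 63.95, 32.01, 35.08, 19.23, 8.94, 42.39, 9.51, 2.34)
  am1_sd   <- c(2.50, 3.94, 2.30, 2.59, 1.30, 1.01, 3.35, 1.01, 0.59)
  am2_mean <- c(56.09, 65.84, 32.83, 34.35, 19.54, 8.12, 43.55, 10.22, 2.81)
  am2_sd   <- c(3.06, 3.62, 2.40, 3.60, 1.33, 1.51, 2.93, 1.60, 0.98)
  d1_mean <- c(6.14, 3.47, 0.01, -1.71, 1.32, 0.33, 2.82, 2.44, -0.13)
  d1_sd   <- c(5.32, 6.55, 2.90, 3.41, 3.18, 1.61, 5.56, 1.68, 1.15)
  d2_mean <- c(6.38, 1.58, -0.81, -0.99, 1.01, 1.15, 1.66, 1.74, -0.61)
  d2_sd   <- c(6.08, 7.07, 3.01, 4.18, 3.51, 2.04, 4.98, 1.62, 1.43)
  rbind(
    data.frame(measurement = paste0("M", 1:9), label = label,
               version = "AM1", n = 20L,
               mean_cm = cm_mean, sd_cm = cm_sd,
               mean_am = am1_mean, sd_am = am1_sd,
               mean_diff = d1_mean, sd_diff = d1_sd),
    data.frame(measurement = paste0("M", 1:9), label = label,
               version = "AM2", n = 20L,
               mean_cm = cm_mean, sd_cm = cm_sd,
               mean_am = am2_mean, sd_am = am2_sd,
               mean_diff = d2_mean, sd_diff = d2_sd))
}
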