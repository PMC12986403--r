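# Cohort summaries and the normality-gated two-group comparison framework.
#
# Continuous metrics are the TIA/SIA/DV magnitudes, CI, ME, AE and IOS.
# Binary metrics are the clinical thresholds |ME| <= 0.50 D, |ME| <= 1.00 D
# and |AE| <= 15 deg. The gate: if both groups pass a one-sample
# Kolmogorov-Smirnov test of their z-standardized values against N(0,1)
# (asymptotic p > 0.05), parametric tests are used (paired or pooled-variance
# two-sample t); otherwise Wilcoxon signed-rank / rank-sum.

CONTINUOUS_METRICS <- c(
  TIA = "tia_mag", SIA = "sia_mag", DV = "dv_mag",
  CI = "ci", ME = "me", AE = "ae", IOS = "ios"
)

BINARY_METRICS <- c(
  "ME within ±0.50 D" = "me_within_050",
  "ME within ±1.00 D" = "me_within_100",
  "AE within ±15°" = "ae_within_15"
)

binary_flags <- function(metrics) {
  data.frame(
    me_within_050 = abs(metrics$me) <= 0.50,
    me_within_100 = abs(metrics$me) <= 1.00,
    ae_within_15 = abs(metrics$ae) <= 15
  )
}

#' Summarize a group's per-eye vector metrics
#'
#' Computes the arithmetic mean and sample (n-1) standard deviation of each
#' of the seven continuous metrics, the geometric mean of CI and IOS (values
#' equal to 0 are left out of the geometric mean, with the count recorded),
#' and the clinically relevant proportions: eyes with an ME within ±0.50 D
#' and ±1.00 D, and an AE within ±15°, greater than 15°, or less than −15°
#' (closed thresholds: boundary values count as within).
#'
#' @param metrics Per-eye metrics from [compute_eye_metrics()].
#' @return A \code{group_summary} object.
#' @export
summarize_group <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) {
    stop("cannot summarize an empty group")
  }
  n <- nrow(metrics)
  stats_tab <- lapply(CONTINUOUS_METRICS, function(col) {
    x <- metrics[[col]]
    list(mean = mean(x), sd = if (n > 1) stats::sd(x) else NA_real_)
  })
  geo <- lapply(c(CI = "ci", IOS = "ios"), function(col) {
    x <- metrics[[col]]
    pos <- x[x > 0]
    list(geometric_mean = if (length(pos) > 0) exp(mean(log(pos)))
         else NA_real_,
         n_zero_excluded = sum(x == 0))
  })
  me <- metrics$me
  ae <- metrics$ae
  props <- c(
    pct_me_within_050 = 100 * mean(abs(me) <= 0.50),
    pct_me_within_100 = 100 * mean(abs(me) <= 1.00),
    pct_ae_within_15 = 100 * mean(abs(ae) <= 15),
    pct_ae_gt_15 = 100 * mean(ae > 15),
    pct_ae_lt_m15 = 100 * mean(ae < -15)
  )
  structure(list(n_included = n, stats = stats_tab, geometric = geo,
                 proportions = props),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> n =", x$n_included, "\n")
  for (m in names(x$stats)) {
    cat(sprintf("  %-4s %7.3f ± %s\n", m, x$stats[[m]]$mean,
                ifelse(is.na(x$stats[[m]]$sd), "NA",
                       sprintf("%.3f", x$stats[[m]]$sd))))
  }
  cat(sprintf("  geometric mean CI %.3f, IOS %.3f\n",
              x$geometric$CI$geometric_mean,
              x$geometric$IOS$geometric_mean))
  cat(sprintf("  %%ME<=0.50: %.1f  %%ME<=1.00: %.1f  %%|AE|<=15: %.1f\n",
              x$proportions["pct_me_within_050"],
              x$proportions["pct_me_within_100"],
              x$proportions["pct_ae_within_15"]))
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' Standardizes the values (z = (x - mean) / sd) and tests them against the
#' standard normal with a one-sample Kolmogorov-Smirnov test, returning the
#' asymptotic p-value. A zero-variance sample cannot be standardized and is
#' flagged degenerate (treated as non-normal by the test-selection gate).
#'
#' @param values Numeric vector, length >= 4.
#' @return List with \code{p} (NA when degenerate) and \code{degenerate}.
#' @export
test_normality <- function(values) {
  if (length(values) < 4) stop("normality screen needs n >= 4")
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    return(list(p = NA_real_, degenerate = TRUE))
  }
  z <- (values - mean(values)) / s
  p <- suppressWarnings(stats::ks.test(z, "pnorm", exact = FALSE)$p.value)
  list(p = p, degenerate = FALSE)
}

#' Normality-gated comparison of a continuous metric
#'
#' If both groups pass the normality screen (p > alpha), a t-test is used
#' (paired or pooled-variance two-sample, per design); if the screen fails in
#' either or both groups, the Wilcoxon signed-rank (paired) or rank-sum
#' (unpaired) test is used. Two-sided throughout. Cohen's d is always
#' reported alongside.
#'
#' @param a,b Numeric vectors of the metric in the two groups.
#' @param design \code{"paired"} or \code{"unpaired"}.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @param metric Optional metric name carried into the result.
#' @return One-row data frame: \code{metric}, \code{type},
#'   \code{test_used}, \code{p_value}, \code{cohens_d}, \code{normality_p_a},
#'   \code{normality_p_b}.
#' @export
compare_continuous <- function(a, b, design = c("unpaired", "paired"),
                               alpha = 0.05, metric = NA_character_) {
  design <- match.arg(design)
  if (design == "paired" && length(a) != length(b)) {
    stop("paired comparison requires equal-length groups")
  }
  if (length(a) < 4 || length(b) < 4) {
    return(comparison_row(metric, "continuous", "not available", NA, NA, NA, NA))
  }
  na <- test_normality(a)
  nb <- test_normality(b)
  normal_ok <- !na$degenerate && !nb$degenerate &&
    na$p > alpha && nb$p > alpha
  d <- cohens_d(a, b, design)
  if (design == "paired" && all(a - b == 0)) {
    # identical pairs: no variance in the differences, p = 1 by convention
    test <- if (normal_ok) "paired t-test" else "Wilcoxon signed-rank"
    return(comparison_row(metric, "continuous", test, 1, 0, na$p, nb$p))
  }
  if (normal_ok) {
    if (design == "paired") {
      test <- "paired t-test"
      p <- stats::t.test(a, b, paired = TRUE)$p.value
    } else {
      test <- "two-sample t-test"
      p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    }
  } else {
    if (design == "paired") {
      test <- "Wilcoxon signed-rank"
      p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    } else {
      test <- "Wilcoxon rank-sum"
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
  }
  comparison_row(metric, "continuous", test, p, d, na$p, nb$p)
}

comparison_row <- function(metric, type, test, p, d, np_a, np_b) {
  data.frame(metric = metric, type = type, test_used = test,
             p_value = as.numeric(p), cohens_d = as.numeric(d),
             normality_p_a = as.numeric(np_a),
             normality_p_b = as.numeric(np_b),
             stringsAsFactors = FALSE)
}

#' Cohen's d effect size
#'
#' Unpaired: difference of means over the pooled (n-1 weighted) standard
#' deviation. Paired: mean of the within-pair differences over their standard
#' deviation (d_z). Sign follows group A minus group B.
#'
#' @param a,b Numeric vectors.
#' @param design \code{"paired"} or \code{"unpaired"}.
#' @return The effect size, or NA when the denominator is zero.
#' @export
cohens_d <- function(a, b, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  if (design == "paired") {
    dd <- a - b
    s <- stats::sd(dd)
    if (is.na(s) || s == 0) {
      return(if (mean(dd) == 0) 0 else NA_real_)
    }
    return(mean(dd) / s)
  }
  na <- length(a)
  nb <- length(b)
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                   (na + nb - 2))
  if (is.na(pooled) || pooled == 0) {
    return(if (mean(a) == mean(b)) 0 else NA_real_)
  }
  (mean(a) - mean(b)) / pooled
}

#' Comparison of a binary (threshold) metric
#'
#' Unpaired: 2x2 chi-square on the success counts, without continuity
#' correction. Paired: McNemar's test on the discordant counts b and c —
#' exact two-sided binomial when b + c < 25, otherwise the large-sample
#' chi-square (b - c)^2 / (b + c). A degenerate table (the same outcome for
#' every eye in both groups, or no discordant pairs) yields p = 1 by
#' convention.
#'
#' @param flags_a,flags_b Logical vectors (threshold met per eye).
#' @param design \code{"paired"} or \code{"unpaired"}.
#' @param metric Optional metric name carried into the result.
#' @return One-row data frame as in [compare_continuous()] (effect size and
#'   normality columns are NA for binary metrics).
#' @export
compare_binary <- function(flags_a, flags_b,
                           design = c("unpaired", "paired"),
                           metric = NA_character_) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(flags_a) != length(flags_b)) {
      stop("paired comparison requires equal-length groups")
    }
    b <- sum(flags_a & !flags_b)
    cc <- sum(!flags_a & flags_b)
    if (b + cc == 0) {
      return(comparison_row(metric, "binary", "McNemar (no discordant pairs)",
                            1, NA, NA, NA))
    }
    if (b + cc < 25) {
      p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
      test <- "McNemar exact"
    } else {
      p <- stats::pchisq((b - cc)^2 / (b + cc), df = 1, lower.tail = FALSE)
      test <- "McNemar chi-square"
    }
    return(comparison_row(metric, "binary", test, p, NA, NA, NA))
  }
  s_a <- sum(flags_a)
  s_b <- sum(flags_b)
  tab <- rbind(c(s_a, length(flags_a) - s_a),
               c(s_b, length(flags_b) - s_b))
  if (any(colSums(tab) == 0)) {
    # every eye in both groups on the same side of the threshold
    return(comparison_row(metric, "binary", "chi-square (degenerate table)",
                          1, NA, NA, NA))
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  comparison_row(metric, "binary", "chi-square", p, NA, NA, NA)
}

#' Compare two groups on all vector metrics
#'
#' Runs the continuous comparison for the TIA, SIA and DV magnitudes, CI,
#' ME, AE and IOS, then the binary comparison for the ME-within-±0.50 D,
#' ME-within-±1.00 D and AE-within-±15° thresholds, in table-row order. With
#' a single group (\code{metrics_b = NULL}) the result is empty: the table
#' is purely descriptive.
#'
#' @param metrics_a,metrics_b Per-eye metric frames from
#'   [compute_eye_metrics()]; \code{metrics_b} may be NULL.
#' @param design \code{"paired"} or \code{"unpaired"}; paired requires
#'   aligned rows.
#' @param alpha Significance level of the normality gate.
#' @return Data frame of comparison rows (possibly empty).
#' @export
compare_groups <- function(metrics_a, metrics_b = NULL,
                           design = c("unpaired", "paired"), alpha = 0.05) {
  design <- match.arg(design)
  if (is.null(metrics_b)) {
    return(comparison_row(character(), character(), character(), numeric(),
                          numeric(), numeric(), numeric())[0, ])
  }
  cont <- do.call(rbind, lapply(names(CONTINUOUS_METRICS), function(m) {
    col <- CONTINUOUS_METRICS[[m]]
    compare_continuous(metrics_a[[col]], metrics_b[[col]], design,
                       alpha = alpha, metric = m)
  }))
  fa <- binary_flags(metrics_a)
  fb <- binary_flags(metrics_b)
  bin <- do.call(rbind, lapply(names(BINARY_METRICS), function(m) {
    col <- BINARY_METRICS[[m]]
    compare_binary(fa[[col]], fb[[col]], design, metric = m)
  }))
  rbind(cont, bin)
}
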