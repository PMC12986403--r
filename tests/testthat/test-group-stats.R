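# Cohort summaries and the normality-gated comparison framework.

test_that("summaries count threshold proportions with closed bounds", {
  m <- data.frame(tia_mag = 1, tia_axis = 0, sia_mag = 1, sia_axis = 0,
                  dv_mag = 0, dv_axis = 0, ci = c(0.8, 1.25, 1, 1),
                  me = c(0.25, -0.60, 0.45, 1.20),
                  ae = c(5, -20, 10, 16),
                  ios = c(0.1, 0.2, 0.3, 0.4))
  s <- summarize_group(m)
  expect_equal(unname(s$proportions["pct_me_within_050"]), 50)
  expect_equal(unname(s$proportions["pct_me_within_100"]), 75)
  expect_equal(unname(s$proportions["pct_ae_within_15"]), 50)
  expect_equal(unname(s$proportions["pct_ae_gt_15"]), 25)
  expect_equal(unname(s$proportions["pct_ae_lt_m15"]), 25)
  # the three AE buckets always partition 100%
  expect_equal(sum(s$proportions[c("pct_ae_within_15", "pct_ae_gt_15",
                                   "pct_ae_lt_m15")]), 100)
  # geometric mean: product 0.8 * 1.25 = 1
  s2 <- summarize_group(m[1:2, ])
  expect_equal(s2$geometric$CI$geometric_mean, 1)
  expect_error(summarize_group(m[0, ]), "empty group")
  # single eye: SD is not available
  s1 <- summarize_group(m[1, ])
  expect_true(is.na(s1$stats$TIA$sd))
  expect_equal(s1$stats$TIA$mean, 1)
})

test_that("boundary ME and AE values count as within the window", {
  m <- data.frame(tia_mag = 1, tia_axis = 0, sia_mag = 1, sia_axis = 0,
                  dv_mag = 0, dv_axis = 0, ci = 1,
                  me = c(0.50, -0.50, 1.00), ae = c(15, -15, 0), ios = 0)
  s <- summarize_group(m)
  expect_equal(unname(s$proportions["pct_me_within_050"]), 200 / 3,
               tolerance = 1e-12)
  expect_equal(unname(s$proportions["pct_me_within_100"]), 100)
  expect_equal(unname(s$proportions["pct_ae_within_15"]), 100)
})

test_that("the KS screen accepts normal and rejects lognormal samples", {
  set.seed(1001)
  x <- rnorm(100)
  y <- rlnorm(100)
  px <- test_normality(x)
  py <- test_normality(y)
  expect_false(px$degenerate)
  expect_gt(px$p, 0.05)
  expect_lt(py$p, 0.05)
  expect_true(test_normality(rep(1, 10))$degenerate)
  expect_error(test_normality(1:3), "n >= 4")
  # asymptotic p agrees with the independent reference implementation
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  ref <- reference_pvalues(list(nx = list(kind = "ks", x = zx),
                                ny = list(kind = "ks", x = zy)))
  expect_equal(round(px$p, 4), round(ref[["nx"]], 4))
  expect_equal(round(py$p, 4), round(ref[["ny"]], 4))
})

test_that("the gate dispatches t-tests for normal and Wilcoxon for skewed data", {
  set.seed(1002)
  a <- rnorm(60)
  b <- rnorm(60, 0.5)
  r <- compare_continuous(a, b, "unpaired")
  expect_equal(r$test_used, "two-sample t-test")
  expect_equal(r$p_value, t.test(a, b, var.equal = TRUE)$p.value)

  skew <- rlnorm(60, 0, 2)
  r2 <- compare_continuous(a, skew, "unpaired")
  expect_equal(r2$test_used, "Wilcoxon rank-sum")
  expect_equal(r2$p_value, wilcox.test(a, skew)$p.value)

  r3 <- compare_continuous(a, a + rnorm(60, 0.2, 0.3), "paired")
  expect_equal(r3$test_used, "paired t-test")
  r4 <- compare_continuous(skew, skew * runif(60, 0.4, 0.9), "paired")
  expect_equal(r4$test_used, "Wilcoxon signed-rank")

  # identical groups: no difference to detect
  r5 <- compare_continuous(a, a, "unpaired")
  expect_equal(r5$p_value, 1)
  r6 <- compare_continuous(a, a, "paired")
  expect_equal(r6$p_value, 1)
  expect_equal(r6$cohens_d, 0)
  # too small for inference
  r7 <- compare_continuous(a[1:3], b[1:3], "unpaired")
  expect_equal(r7$test_used, "not available")
  expect_true(is.na(r7$p_value))
})

test_that("Cohen's d follows the pooled-SD and within-pair formulas", {
  a <- c(0.5, 1.0, 1.5)   # mean 1.0, sd 0.5
  b <- c(0.0, 0.5, 1.0)   # mean 0.5, sd 0.5
  expect_equal(cohens_d(a, b, "unpaired"), 1.00)
  expect_equal(cohens_d(a, a, "unpaired"), 0)
  # paired: differences with mean 0.3, sd 0.6 -> d_z = 0.50
  d <- c(-0.3, 0.3, 0.9)
  expect_equal(sd(d), 0.6)
  expect_equal(cohens_d(d, rep(0, 3), "paired"), 0.5)
  expect_true(is.na(cohens_d(c(1, 1), c(2, 2), "unpaired")))
})

test_that("binary comparisons match their closed forms", {
  # identical proportions: chi-square statistic 0
  r <- compare_binary(rep(c(TRUE, FALSE), 25), rep(c(TRUE, FALSE), 25),
                      "unpaired")
  expect_equal(r$p_value, 1)
  # 40/50 vs 30/50: chi-square = N(ad-bc)^2 / (r1 r2 c1 c2) = 4.7619
  fa <- rep(c(TRUE, FALSE), c(40, 10))
  fb <- rep(c(TRUE, FALSE), c(30, 20))
  r2 <- compare_binary(fa, fb, "unpaired")
  stat <- 100 * (40 * 20 - 10 * 30)^2 / (50 * 50 * 70 * 30)
  expect_equal(r2$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(r2$p_value, 4), 0.0291)
  # degenerate: everyone on the same side in both groups
  r3 <- compare_binary(rep(TRUE, 20), rep(TRUE, 20), "unpaired")
  expect_equal(r3$p_value, 1)

  # paired, discordant b=1, c=9: exact two-sided binomial tail
  fa <- c(rep(TRUE, 30), rep(TRUE, 1), rep(FALSE, 9), rep(FALSE, 10))
  fb <- c(rep(TRUE, 30), rep(FALSE, 1), rep(TRUE, 9), rep(FALSE, 10))
  r4 <- compare_binary(fa, fb, "paired")
  expect_equal(r4$test_used, "McNemar exact")
  expect_equal(r4$p_value, 2 * sum(choose(10, 0:1)) / 2^10)
  expect_equal(round(r4$p_value, 4), 0.0215)
  # no discordant pairs
  r5 <- compare_binary(fa, fa, "paired")
  expect_equal(r5$p_value, 1)
  # large discordant count switches to the chi-square form
  fa6 <- c(rep(TRUE, 20), rep(FALSE, 15))
  fb6 <- c(rep(FALSE, 20), rep(TRUE, 15))
  r6 <- compare_binary(fa6, fb6, "paired")
  expect_equal(r6$test_used, "McNemar chi-square")
  expect_equal(r6$p_value, pchisq(25 / 35, 1, lower.tail = FALSE))
})

test_that("compare_groups runs the full metric panel in table order", {
  set.seed(1003)
  ma <- compute_eye_metrics(random_eye_rows(60, seed = 61))
  mb <- compute_eye_metrics(random_eye_rows(60, seed = 62))
  out <- compare_groups(ma, mb, "unpaired")
  expect_equal(out$metric,
               c("TIA", "SIA", "DV", "CI", "ME", "AE", "IOS",
                 "ME within ±0.50 D", "ME within ±1.00 D",
                 "AE within ±15°"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_true(all(is.na(out$cohens_d[out$type == "binary"])))

  # single-group mode is purely descriptive
  expect_equal(nrow(compare_groups(ma, NULL, "unpaired")), 0)

  # a group against itself, paired: nothing to find
  self <- compare_groups(ma, ma, "paired")
  cont <- self[self$type == "continuous", ]
  expect_true(all(cont$p_value == 1))
  expect_true(all(cont$cohens_d == 0))
})

test_that("a true CI difference is detected end to end", {
  pa <- sim_params(n = 100, ci_true = 1.0, rot_sd = 5, mag_noise_sd = 0.1,
                   residual_sphere_sd = 0.1, seed = 71)
  pb <- sim_params(n = 100, ci_true = 0.8, rot_sd = 5, mag_noise_sd = 0.1,
                   residual_sphere_sd = 0.1, seed = 72)
  ma <- compute_eye_metrics(generate_cohort(pa))
  mb <- compute_eye_metrics(generate_cohort(pb))
  out <- compare_groups(ma, mb, "unpaired")
  ci_row <- out[out$metric == "CI", ]
  expect_lt(ci_row$p_value, 0.05)
  expect_gt(ci_row$cohens_d, 0)  # group A corrects more than group B
})

test_that("every test's p-value matches the reference implementation to 4 dp", {
  set.seed(1004)
  cases <- list()
  expected <- list()
  for (i in 1:12) {
    n <- sample(12:30, 1)
    a <- rnorm(n, sample(c(0, 0.5), 1))
    b <- rnorm(n, 0, sample(c(1, 2), 1))
    sk <- rlnorm(n)
    cases[[paste0("t", i)]] <- list(kind = "t", a = a, b = b)
    expected[[paste0("t", i)]] <- t.test(a, b, var.equal = TRUE)$p.value
    cases[[paste0("tp", i)]] <- list(kind = "t_paired", a = a, b = b)
    expected[[paste0("tp", i)]] <- t.test(a, b, paired = TRUE)$p.value
    cases[[paste0("rs", i)]] <- list(kind = "ranksum", a = a, b = sk)
    expected[[paste0("rs", i)]] <- wilcox.test(a, sk)$p.value
    cases[[paste0("sr", i)]] <- list(kind = "signedrank", a = a, b = sk)
    expected[[paste0("sr", i)]] <- wilcox.test(a, sk, paired = TRUE)$p.value
    z <- (a - mean(a)) / sd(a)
    cases[[paste0("ks", i)]] <- list(kind = "ks", x = z)
    expected[[paste0("ks", i)]] <- test_normality(a)$p
  }
  for (i in 1:6) {
    s1 <- sample(5:45, 1); s2 <- sample(5:45, 1)
    tab <- rbind(c(s1, 50 - s1), c(s2, 50 - s2))
    cases[[paste0("cs", i)]] <- list(kind = "chisq", table = tab)
    expected[[paste0("cs", i)]] <- compare_binary(
      rep(c(TRUE, FALSE), tab[1, ]), rep(c(TRUE, FALSE), tab[2, ]),
      "unpaired")$p_value
    bb <- sample(0:10, 1); cc <- sample(1:10, 1)
    tab2 <- rbind(c(20, bb), c(cc, 20))
    cases[[paste0("mn", i)]] <- list(kind = "mcnemar_exact", table = tab2)
    fa <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, bb, cc, 20))
    fb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, bb, cc, 20))
    expected[[paste0("mn", i)]] <- compare_binary(fa, fb, "paired")$p_value
    bb2 <- sample(12:25, 1); cc2 <- sample(13:25, 1)
    tab3 <- rbind(c(5, bb2), c(cc2, 5))
    cases[[paste0("mc", i)]] <- list(kind = "mcnemar_chisq", table = tab3)
    fa3 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(5, bb2, cc2, 5))
    fb3 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, bb2, cc2, 5))
    expected[[paste0("mc", i)]] <- compare_binary(fa3, fb3, "paired")$p_value
  }
  ref <- reference_pvalues(cases)
  for (nm in names(expected)) {
    expect_equal(round(expected[[nm]], 4), round(ref[[nm]], 4), label = nm)
  }
})
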