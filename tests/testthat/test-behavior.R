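test_that("effect sizes reproduce the standard conversions at their printed rounding", {
  expect_equal(round(effect_r_from_z(-5.001, 68), 3), -0.606)
  expect_equal(round(effect_r_from_z(-3.753, 68), 3), -0.455)
  expect_equal(round(effect_r_from_z(-0.043, 68), 3), -0.005)
  expect_equal(effect_r_from_z(0, 100), 0)
  expect_equal(round(effect_r_from_t(4.69, 27), 2), 0.67)
  expect_equal(round(effect_r_from_t(-4.69, 27), 2), -0.67)
  expect_equal(effect_r_from_t(0, 10), 0)
})

test_that("condition rates partition to 100% and track configured probabilities", {
  beh <- data.frame(trial_id = 1:10, condition = rep(c("correct", "error"),
                                                     each = 5))
  tab <- condition_rates(list(beh))
  expect_equal(tab$mean_pct[tab$condition == "correct"], 50)
  expect_equal(sum(tab$mean_pct), 100)

  cfg <- synth_config(n_trials = 2000, seed = 51)
  behs <- lapply(1:4, function(s) generate_behavior(cfg, s))
  tab2 <- condition_rates(behs)
  rates <- attr(tab2, "rates")
  expect_equal(unname(rowSums(rates)), rep(100, 4), tolerance = 1e-9)
  p <- cfg$condition_probs
  for (cd in names(p)) {
    se <- 100 * sqrt(p[[cd]] * (1 - p[[cd]]) / (4 * 2000))
    expect_lt(abs(tab2$mean_pct[tab2$condition == cd] - 100 * p[[cd]]),
              3 * se + 1e-9)
  }
})

test_that("the Friedman statistic matches its closed form and enumeration", {
  # all 10 subjects rank the three conditions identically: chi2 = 20
  x <- matrix(c(runif(10, 1.0, 1.1), runif(10, 2.0, 2.1), runif(10, 3, 3.1)),
              ncol = 3)
  f <- friedman_rt(x)
  expect_equal(f$statistic, 20, tolerance = 1e-9)
  expect_equal(f$df, 2)

  # identical columns: no effect at all
  y <- matrix(rep(runif(6, 1, 2), 3), ncol = 3)
  f0 <- friedman_rt(y)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p, 1)

  # small-sample p against exhaustive enumeration of within-subject rankings
  set.seed(61)
  z <- cbind(rnorm(6, 1.1, 0.25), rnorm(6, 1.2, 0.25), rnorm(6, 1.5, 0.25))
  p_exact <- exact_friedman_p(z)
  p_chi2 <- friedman_rt(z)$p
  expect_lt(abs(p_exact - p_chi2), 0.05)

  expect_error(friedman_rt(cbind(1:4, 2:5)), "exactly 3")
})

test_that("the Wilcoxon Z, its p, and the exact enumeration agree", {
  # symmetric differences: Z near 0
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  w0 <- suppressWarnings(wilcoxon_z(x, y))
  expect_lt(abs(w0$statistic), 0.1)
  expect_equal(w0$n, 16L)

  # a fixed 6-pair sample: normal-approximation p close to the exact one
  d <- c(0.42, 0.51, 0.38, 0.47, 0.55, 0.61)
  w <- suppressWarnings(wilcoxon_z(d + 1, rep(1, 6)))
  p_ex <- exact_wilcoxon_p(d)
  expect_equal(p_ex, 2 / 64, tolerance = 1e-12)
  expect_lt(abs(w$p - p_ex), 0.02)
  expect_equal(w$effect_r, w$statistic / sqrt(12), tolerance = 1e-12)

  # cross-check the tie-corrected p against the stats implementation
  set.seed(71)
  a <- rnorm(30); b <- a + rnorm(30, 0.4)
  wz <- wilcoxon_z(b, a)
  wt <- wilcox.test(b, a, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(wz$p, wt$p.value, tolerance = 1e-9)

  # the printed two-tailed normal p-values follow from their Z values
  expect_equal(2 * pnorm(-abs(-5.001)), 6e-7, tolerance = 0.06)
  expect_equal(2 * pnorm(-abs(-3.753)), 0.000175, tolerance = 0.005)
})

test_that("Spearman correlation handles the exact and approximate regimes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_test(x, x * 2 + 1)$statistic, 1)
  expect_equal(spearman_test(x, -x)$statistic, -1)
  expect_equal(spearman_test(x, x)$p, 0)

  set.seed(81)
  y <- rnorm(7); z <- 0.6 * y + rnorm(7, sd = 0.6)
  pt_ <- spearman_test(y, z, method = "t")$p
  pp <- spearman_test(y, z, method = "permutation", n_perm = 5000, seed = 2)$p
  se <- sqrt(pp * (1 - pp) / 5000)
  expect_lt(abs(pt_ - pp), 2 * se + 0.05)
  expect_error(spearman_test(1:3, 1:3), "4 complete")
})

test_that("serial-position accuracy reports per-position rates and the recency boost", {
  full <- data.frame(trial_id = 1:3, sp1 = c(1, 1, NA), sp2 = c(1, NA, 1),
                     sp3 = c(NA, 1, 1), sp4 = c(1, 1, 1))
  out <- serial_position_accuracy(list(full, full))
  expect_equal(out$table$mean_pct, rep(100, 4))

  # a position never probed is missing, not zero
  part <- data.frame(trial_id = 1:2, sp1 = c(1, 0), sp2 = c(NA, NA),
                     sp3 = c(1, 1), sp4 = c(1, 1))
  out2 <- serial_position_accuracy(list(part))
  expect_true(is.na(out2$rates[1, 2]))
  expect_equal(unname(out2$rates[1, 1]), 50)

  cfg <- synth_config(n_trials = 600, seed = 91)
  behs <- lapply(1:6, function(s) generate_behavior(cfg, s))
  out3 <- serial_position_accuracy(behs)
  expect_gt(out3$table$mean_pct[4], max(out3$table$mean_pct[1:3]))
  expect_lt(out3$recency$p, 0.05)
})

test_that("the Lilliefors normality screen is calibrated and powerful", {
  set.seed(101)
  normal_ok <- mean(replicate(20, ks_normality(rnorm(200))$p > 0.05))
  expect_gte(normal_ok, 0.9)
  skew_hit <- mean(replicate(20, ks_normality(rlnorm(34, 0, 1))$p < 0.05))
  expect_gte(skew_hit, 0.9)
  expect_error(ks_normality(rep(3, 10)), "degenerate")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("cluster-power/RT correlation excludes ellipse outliers and detects planted dependence", {
  set.seed(111)
  chn <- c("P4", "P8", "O2")
  freqs <- c(16, 18, 20); times <- seq(1.5, 1.75, 0.05)
  cluster <- list(triplets = data.frame(
    channel = c("O2", "O2", "P4"), freq = c(18, 18, 18),
    time = c(1.5, 1.55, 1.55)), mass = 10, sign = 1)
  mk_means <- function(p) {
    a <- array(rnorm(3 * 3 * 6, sd = 0.2), c(3, 3, 6),
               dimnames = list(chn, as.character(freqs),
                               as.character(round(times, 6))))
    a[, "18", ] <- a[, "18", ] + p
    a
  }
  # independent power and RT: mostly non-significant over replications
  nulls <- replicate(20, {
    pows <- runif(12, 0, 6)
    sm <- lapply(pows, mk_means)
    rts <- runif(12, 1, 2)
    suppressMessages(power_rt_correlation(cluster, sm, rts))$p
  })
  expect_gte(mean(nulls > 0.05), 0.75)

  # RT made monotone in the planted power: strong positive correlation
  pows <- seq(0.5, 6, length.out = 12)
  sm <- lapply(pows, mk_means)
  rts <- 1 + 0.15 * pows + rnorm(12, sd = 0.02)
  dep <- suppressMessages(power_rt_correlation(cluster, sm, rts))
  expect_gt(dep$statistic, 0.5)
  expect_lt(dep$p, 0.05)

  # all points inside the ellipse: nothing excluded
  expect_length(dep$detail$excluded, 0)

  # one wild bivariate outlier is excluded before correlating
  rts2 <- rts; rts2[12] <- 30
  sm2 <- sm; sm2[[12]] <- mk_means(50)
  expect_message(out <- power_rt_correlation(cluster, sm2, rts2), "excluded")
  expect_equal(out$detail$excluded, 12L)
})

test_that("stat_result validates its ranges", {
  expect_error(stat_result("x", 1, p = 1.2), "p must")
  expect_error(stat_result("x", 1, p = 0.5, effect_r = 1.4), "effect size")
  s <- stat_result("ok", 2.2, df = 3, p = 0.1)
  expect_s3_class(s, "wm_stat")
  expect_output(print(s), "ok")
})
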