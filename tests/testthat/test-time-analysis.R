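test_that("time summaries report the documented statistics", {
  s <- summarize_times(c(10, 20, 30, 40))
  est <- setNames(s$estimate, s$statistic)
  expect_equal(est[["mean"]], 25)
  expect_equal(est[["median"]], 25)
  expect_equal(est[["min"]], 10)
  expect_equal(est[["max"]], 40)
  expect_equal(est[["p25"]], 17.5)  # linear interpolation between orders

  # a constant series has equal percentiles and zero-width intervals
  const <- summarize_times(rep(12, 20))
  expect_true(all(const$estimate == 12))
  expect_true(all(const$conf.low[!is.na(const$conf.low)] == 12))
  expect_true(all(const$conf.high[!is.na(const$conf.high)] == 12))

  expect_error(summarize_times(5), "at least 2")
  expect_error(summarize_times(c(-1, 3)), "non-negative")
})

test_that("percentile ordering invariant holds on random data", {
  order_stats <- c("min", "p25", "median", "p75", "p90", "p95", "max")
  for (seed in 1:10) {
    times <- withr::with_seed(seed, rlnorm(sample(5:200, 1),
                                           meanlog = 3.5, sdlog = 0.4))
    s <- summarize_times(times)
    est <- setNames(s$estimate, s$statistic)[order_stats]
    expect_true(all(diff(est) >= -1e-12))
    # order-statistic intervals bracket their point estimates
    qs <- dplyr::filter(s, grepl("^p|median", statistic))
    expect_true(all(qs$conf.low <= qs$estimate + 1e-12))
    expect_true(all(qs$conf.high >= qs$estimate - 1e-12))
  }
})

test_that("mean interval for calibrated samples covers the calibration", {
  tm <- asav_time_model()
  times <- withr::with_seed(7, {
    p <- tm$params$red
    rlnorm(1000, p$meanlog, p$sdlog)
  })
  s <- dplyr::filter(summarize_times(times), statistic == "mean")
  expect_gt(41.8, s$conf.low)
  expect_lt(41.8, s$conf.high)
})

test_that("ANOVA matches the sums-of-squares oracle", {
  df <- withr::with_seed(5, data.frame(
    g = rep(c("a", "b", "c"), times = c(8, 12, 7)),
    t = c(rnorm(8, 30, 5), rnorm(12, 36, 5), rnorm(7, 40, 5))
  ))
  fit <- anova_bonferroni(df, t, g)

  # brute-force sums of squares
  grand <- mean(df$t)
  by_g <- split(df$t, df$g)
  ss_between <- sum(vapply(by_g, function(x) length(x) * (mean(x) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(by_g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_oracle <- (ss_between / 2) / (ss_within / (nrow(df) - 3))
  expect_equal(fit$f_statistic, f_oracle, tolerance = 1e-9)
  expect_equal(glance(fit)$df, 2)
  expect_equal(nrow(tidy(fit)), 3)  # three pairwise comparisons
  expect_true(all(tidy(fit)$p.adj <= 1))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  df <- withr::with_seed(6, data.frame(
    g = rep(c("a", "b"), each = 10),
    t = c(rnorm(10, 33, 6), rnorm(10, 38, 6))
  ))
  fit <- anova_bonferroni(df, t, g)
  tt <- t.test(t ~ g, data = df, var.equal = TRUE)
  expect_equal(fit$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-9)
  # with two groups the single Bonferroni comparison equals the omnibus p
  expect_equal(tidy(fit)$p.adj, tt$p.value, tolerance = 1e-9)
})

test_that("identical groups give a null ANOVA", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                   t = rep(c(20, 30, 40, 50), times = 3))
  fit <- anova_bonferroni(df, t, g)
  expect_equal(fit$f_statistic, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1, tolerance = 1e-12)
  expect_error(anova_bonferroni(data.frame(g = "a", t = 1), t, g),
               "at least 2 groups")
  expect_error(anova_bonferroni(data.frame(g = c("a", "a", "b"),
                                           t = c(1, 2, 3)), t, g),
               "at least 2 observations")
})

test_that("planning mean weighs category means by the casualty mix", {
  means <- c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8)
  expect_equal(planning_mean(planning_mix(0.2, 0.2, 0.6, 0), means), 24.84)
  expect_equal(planning_mean(planning_mix(0, 0, 1, 0), means), 14.5)
  expect_equal(planning_mean(planning_mix(0.25, 0.25, 0.25, 0.25), means), 31)
  expect_error(planning_mean(planning_mix(0.5, 0.5, 0, 0),
                             c(red = 40, yellow = NA, green = 10, black = 20)),
               "yellow")
})

test_that("planning mean is linear in the mix", {
  means <- c(red = 41.8, yellow = 38.9, green = 14.5, black = 28.8)
  a <- planning_mix(0.2, 0.2, 0.6, 0)
  b <- planning_mix(0.4, 0.3, 0.25, 0.05)
  for (alpha in c(0, 0.3, 0.7, 1)) {
    blended <- alpha * a + (1 - alpha) * b
    expect_equal(planning_mean(blended, means),
                 alpha * planning_mean(a, means) +
                   (1 - alpha) * planning_mean(b, means))
  }
})

test_that("incident simulation is exact in the degenerate case", {
  const <- time_model(family = "empirical",
                      samples = list(red = 30, yellow = 30, green = 30,
                                     black = 30))
  sim <- simulate_incident(1, 1, planning_mix(0, 0, 1, 0), const,
                           replicates = 5, seed = 1)
  expect_true(all(sim$completion_seconds == 30))
  expect_identical(sim,
                   simulate_incident(1, 1, planning_mix(0, 0, 1, 0), const,
                                     replicates = 5, seed = 1))
})

test_that("incident per-patient times agree with the planning mean", {
  mix <- planning_mix(0.2, 0.2, 0.6, 0)
  tm <- asav_time_model()
  sim <- simulate_incident(50, 5, mix, tm, replicates = 400, seed = 9)
  pm <- planning_mean(mix, time_model_means(tm))
  mc_se <- sd(sim$mean_seconds_per_patient) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$mean_seconds_per_patient) - pm), 3 * mc_se)
  # completion of the slowest team can never beat an even split
  expect_true(all(sim$completion_seconds >= sim$total_seconds / 5))
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
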