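test_that("channel variance is the unbiased sample variance", {
  expect_equal(channel_variance(rep(4, 8)), 0)
  expect_equal(channel_variance(c(0, 2)), 2)
  expect_true(is.na(channel_variance(c(3, NA, NA))))
  # translation-invariant, scales as c^2
  dz <- c(1, 4, -2, 8, 0, 3, -5, 2)
  expect_equal(channel_variance(dz + 100), channel_variance(dz))
  expect_equal(channel_variance(3 * dz), 9 * channel_variance(dz))
})

test_that("Levene's test matches the ANOVA-on-absolute-deviations oracle", {
  # identical groups: W = 0, p = 1
  res <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # definitional oracle on random data
  for (s in 1:5) {
    x <- withr::with_seed(s, c(rnorm(9, sd = 4), rnorm(9, sd = 1)))
    g <- rep(c("a", "b"), each = 9)
    res <- levene_test(x, g)
    d <- abs(x - ave(x, g))
    fit <- stats::anova(stats::lm(d ~ factor(g)))
    expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-12)
    expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-12)
  }
  # invariant under per-group translation
  x <- withr::with_seed(9, rnorm(12))
  g <- rep(c("a", "b"), each = 6)
  shifted <- x + ifelse(g == "a", 50, -20)
  expect_equal(levene_test(shifted, g)$statistic,
               levene_test(x, g)$statistic, tolerance = 1e-10)
  expect_error(levene_test(1:5, rep("a", 5)), "2 groups")
})

test_that("Welch's t agrees with a permutation oracle", {
  res <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(res2$p_value, 0.05)
  # permutation p-value within 0.02 of Welch p on a 9-vs-9 moderate effect
  withr::with_seed(31, {
    a <- rnorm(9, mean = 1.1, sd = 1)
    b <- rnorm(9, mean = 0, sd = 2)
    w <- welch_t(a, b)
    pooled <- c(a, b)
    t_obs <- abs(w$statistic)
    perm <- vapply(1:4000, function(i) {
      idx <- sample(18, 9)
      abs(welch_t(pooled[idx], pooled[-idx])$statistic) >= t_obs
    }, logical(1))
    expect_lt(abs(mean(perm) - w$p_value), 0.02)
  })
})

test_that("ANOM decision limits flag separated event classes", {
  # equal means, zero spread: no flags
  flat <- tibble::tibble(event = rep(c("a", "b", "c"), each = 4),
                         std = rep(5, 12))
  expect_length(anom_std(flat)$flagged_events, 0)
  # one event shifted by 10 pooled sds: flagged
  d <- tibble::tibble(event = rep(c("a", "b", "c"), each = 4),
                      std = withr::with_seed(2, rnorm(12, 10, 1)))
  d$std[d$event == "c"] <- d$std[d$event == "c"] + 10
  res <- anom_std(d)
  expect_true("c" %in% res$flagged_events)
  # h approaches the Bonferroni-adjusted normal quantile at large df
  big <- tibble::tibble(event = rep(c("a", "b", "c"), each = 200),
                        std = withr::with_seed(3, rnorm(600, 10, 1)))
  res_big <- anom_std(big, alpha = 0.05)
  expect_equal(res_big$h, qnorm(1 - 0.05 / 6), tolerance = 0.05)
  # unbalanced groups warn and use per-group n
  unb <- tibble::tibble(event = c(rep("a", 4), rep("b", 8)),
                        std = withr::with_seed(4, rnorm(12, 10, 1)))
  expect_warning(res_u <- anom_std(unb), "unbalanced")
  lim <- res_u$limits
  width <- lim$upper - lim$lower
  expect_lt(width[lim$event == "b"], width[lim$event == "a"])
})

test_that("focal events show larger channel variance than global events", {
  an <- analyze_cohort(simulate_cohort(9, seed = 8, fs = 0.5))
  vs <- an$variance
  expect_true(all(vs$within_subject$focal_greater))
  expect_lt(vs$levene$p_value, 0.05)
  expect_lt(vs$welch$p_value, 0.05)
  # ANOM flags the high-variance stepped focal events, not only noise
  expect_true(any(c("inflation", "deflation") %in%
                    vs$anom$flagged_events))
})

test_that("Levene discrimination power grows with focal gain", {
  # W is scale-free once the focal response dwarfs measurement noise, so the
  # monotone-power property is probed across the noise-comparable regime
  w <- vapply(c(0.02, 0.5, 30), function(g) {
    scn <- injury_scenario(protocol = tiny_protocol(), focal_gain = g,
                           seed = 12)
    rec <- synthesize_recording(scn, fs = 0.5)
    det <- detrend_recording(rec, scn$protocol)$recording
    m <- compute_event_metrics(det, scn$protocol)
    ch <- m$channels
    cls <- ifelse(ch$phase %in% c("inflation", "deflation"), "focal",
                  ifelse(ch$phase == "global_terminal", "global", NA))
    keep <- !is.na(cls) & is.finite(ch$delta_z)
    levene_test(ch$delta_z[keep], cls[keep])$statistic
  }, numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_gt(w[3], w[1])
})
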