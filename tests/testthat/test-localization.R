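test_that("min-max normalization spans 0-1 and carries missing channels", {
  expect_equal(normalize_deltas(c(4, 2, 1, NA, NA, NA, NA, NA)),
               c(1, 1/3, 0, NA, NA, NA, NA, NA))
  for (s in 1:5) {
    dz <- withr::with_seed(s, rnorm(8, sd = 20))
    nd <- normalize_deltas(dz)
    expect_equal(min(nd), 0)
    expect_equal(max(nd), 1)
    expect_equal(which.max(nd), which.max(dz))
  }
  # flat vectors are degenerate: all 0.5 with a warning
  expect_warning(nd <- normalize_deltas(rep(3, 8)), "degenerate")
  expect_equal(nd, rep(0.5, 8))
  # resolution floor: spread below the floor is also degenerate
  expect_warning(nd2 <- normalize_deltas(c(0, 0.4, rep(0.2, 6)),
                                         flat_range_ohm = 7.1), "degenerate")
  expect_equal(nd2, rep(0.5, 8))
  expect_error(normalize_deltas(c(1, rep(NA, 7))), "at least 2")
})

test_that("normalization and classification are affine-invariant", {
  for (s in 1:10) {
    dz <- withr::with_seed(s, rnorm(8, sd = 30))
    a <- withr::with_seed(s + 100, runif(1, 0.1, 10))
    b <- withr::with_seed(s + 200, rnorm(1, sd = 50))
    expect_equal(normalize_deltas(a * dz + b), normalize_deltas(dz))
    expect_equal(classify_event(normalize_deltas(a * dz + b)),
                 classify_event(normalize_deltas(dz)))
  }
})

test_that("channel permutation permutes the classified element identically", {
  dz <- c(2, 5, 36, 6, 1, -2, 0, -1)
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(8))
    cls <- classify_event(normalize_deltas(dz))
    cls_p <- classify_event(normalize_deltas(dz[perm]))
    expect_equal(cls_p$label, cls$label)
    expect_equal(perm[cls_p$element], cls$element)
  }
})

test_that("cohort mean maps average subject maps elementwise", {
  m <- withr::with_seed(3, matrix(runif(8), nrow = 1))
  expect_equal(cohort_mean_map(m), as.numeric(m))
  # a map and its complement average to 0.5 everywhere
  expect_equal(cohort_mean_map(rbind(m, 1 - m)), rep(0.5, 8))
  # missing-aware
  m2 <- rbind(c(NA, rep(1, 7)), c(0.2, rep(0, 7)))
  expect_equal(cohort_mean_map(m2)[1], 0.2)
})

test_that("the threshold rule separates focal from global maps", {
  expect_equal(classify_event(rep(0.5, 8))$label, "global")
  # a dominant element above 2/3 -> model-ischemia focal at that element
  hi <- c(0.5, 0.55, 0.9, 0.6, 0.5, 0.45, 0.4, 0.5)
  expect_equal(classify_event(hi),
               tibble::tibble(label = "focal_high_z", element = 3L),
               ignore_attr = TRUE)
  # a dominant element below 1/3 -> hemorrhage focal at that element
  lo <- c(0.5, 0.55, 0.1, 0.6, 0.5, 0.45, 0.4, 0.5)
  expect_equal(classify_event(lo)$label, "focal_low_z")
  expect_equal(classify_event(lo)$element, 3L)
  # everything inside (1/3, 2/3) -> global
  expect_equal(classify_event(c(0.4, 0.5, 0.6, 0.45, 0.55, 0.5, 0.35, 0.65))$label,
               "global")
  # both thresholds crossed: the extreme isolated from the bulk wins
  both_hi <- c(0, 0.1, 1, 0.15, 0.05, 0.1, 0.2, 0.1)   # bulk low -> high focal
  expect_equal(classify_event(both_hi),
               tibble::tibble(label = "focal_high_z", element = 3L),
               ignore_attr = TRUE)
  both_lo <- 1 - both_hi                                # bulk high -> low focal
  expect_equal(classify_event(both_lo),
               tibble::tibble(label = "focal_low_z", element = 3L),
               ignore_attr = TRUE)
})

test_that("cohort localization recovers the seeded inclusion sector", {
  for (s in c(3, 14)) {
    an <- analyze_cohort(simulate_cohort(5, seed = s, fs = 0.5))
    cls <- an$localization$classification
    focal <- cls[cls$phase %in% c("inflation", "deflation", "hematoma"), ]
    expect_true(all(focal$element == 3))
    expect_equal(cls$label[cls$phase == "inflation"], "focal_high_z")
    expect_equal(cls$label[cls$phase == "hematoma"], "focal_low_z")
    expect_true(all(cls$label[grepl("^global", cls$phase)] == "global"))
  }
})
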