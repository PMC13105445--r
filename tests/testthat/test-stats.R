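test_that("the normality gate flags non-normal and passes normal samples", {
  set.seed(101)
  flagged <- replicate(1000, {
    x <- c(rnorm(11), rnorm(3, mean = 12))     # heavy-tailed mixture
    g <- normality_gate(tibble::tibble(value = x, condition = "A"))
    !g$normal
  })
  expect_gte(mean(flagged), 0.95)

  set.seed(102)
  normal_ok <- replicate(1000, {
    g <- normality_gate(tibble::tibble(value = rnorm(14), condition = "A"))
    g$normal
  })
  expect_gt(mean(normal_ok), 0.90)   # type-I calibration around 5%
  expect_lt(mean(normal_ok), 0.985)

  g <- normality_gate(tibble::tibble(value = rep(1, 14), condition = "A"))
  expect_false(g$normal)

  expect_warning(
    g2 <- normality_gate(tibble::tibble(value = rnorm(2), condition = "A")),
    "fewer than 3"
  )
  expect_true(attr(g2, "nonparametric"))
})

test_that("Friedman test matches the rank-sum arithmetic", {
  # identical conditions: no effect at all
  d0 <- tibble::tibble(participant = rep(1:5, each = 3),
                       condition = rep(c("a", "b", "c"), 5),
                       value = rep(rnorm(5), each = 3))
  f0 <- friedman_conditions(d0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  # ranks always (1, 2, 3) over 3 blocks: chi2 = 12/(3*3*4)*126 - 36 = 6
  d1 <- tibble::tibble(participant = rep(1:3, each = 3),
                       condition = rep(c("a", "b", "c"), 3),
                       value = rep(c(1, 2, 3), 3) + rep(rnorm(3), each = 3))
  f1 <- friedman_conditions(d1)
  expect_equal(f1$statistic, 6)
  expect_equal(f1$p_value, pchisq(6, df = 2, lower.tail = FALSE))

  # participants with missing cells are excluded, not imputed
  d2 <- d1
  d2$value[2] <- NA
  expect_warning(f2 <- friedman_conditions(d2), "excluded")
  expect_equal(f2$n, 2)
})

test_that("Friedman statistic is invariant under per-participant monotone maps", {
  set.seed(5)
  d <- tibble::tibble(participant = rep(1:10, each = 3),
                      condition = rep(c("a", "b", "c"), 10),
                      value = rnorm(30))
  d2 <- dplyr::mutate(d, value = exp(value) + 100 * participant)
  expect_equal(friedman_conditions(d)$statistic,
               friedman_conditions(d2)$statistic)
})

test_that("Friedman test holds its size under the null", {
  set.seed(404)
  rej <- replicate(2000, {
    m <- matrix(rnorm(14 * 3), ncol = 3)
    stats::friedman.test(m)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("signed-rank Z reproduces the closed-form extreme configurations", {
  # all 14 differences positive: W = n(n+1)/2 = 105
  a <- 1:14 + (1:14) / 10
  b <- rep(0, 14)
  w <- wilcoxon_paired(a, b)
  expect_equal(w$statistic, 105)
  expect_equal(w$z, 52.5 / sqrt(14 * 15 * 29 / 24), tolerance = 1e-12)
  expect_equal(effect_size_r(w$z, 14), 0.8809, tolerance = 1e-4)

  # one negative difference holding the smallest absolute rank: W = 104
  d <- c(-0.5, 1:13 + 0.7)
  w2 <- wilcoxon_paired(d, rep(0, 14))
  expect_equal(w2$statistic, 104)
  expect_equal(w2$z, 51.5 / sqrt(253.75), tolerance = 1e-12)
  expect_equal(round(effect_size_r(w2$z, 14), 2), 0.86)

  # antisymmetric differences: signed ranks cancel
  w3 <- wilcoxon_paired(c(-3, -1, 1, 3), rep(0, 4))
  expect_equal(w3$z, 0)
  expect_equal(w3$p_value, 1)
})

test_that("signed-rank agrees with stats::wilcox.test without continuity", {
  set.seed(33)
  for (k in 1:20) {
    a <- rnorm(14)
    b <- rnorm(14)
    if (k %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # induce ties
    w <- wilcoxon_paired(a, b)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
    )
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
    # sign flip: negating the differences negates Z
    wf <- wilcoxon_paired(b, a)
    expect_equal(wf$z, -w$z, tolerance = 1e-12)
  }
})

test_that("rank-sum variant agrees with the Mann-Whitney reference", {
  set.seed(34)
  a <- rnorm(14); b <- rnorm(14) + 0.5
  w <- wilcoxon_paired(a, b, method = "rank_sum")
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  )
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate pairings are reported missing", {
  w <- wilcoxon_paired(rep(1, 5), rep(1, 5))
  expect_true(is.na(w$z))
  expect_true(is.na(w$p_value))
})

test_that("signed-rank test holds its size under the null", {
  set.seed(505)
  rej <- replicate(4000, {
    wilcoxon_paired(rnorm(14), rnorm(14))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("effect sizes and tiers follow the conventional thresholds", {
  expect_equal(round(effect_size_r(3.2958, 14), 2), 0.88)
  expect_equal(effect_size_r(0, 14), 0)
  expect_equal(effect_size_r(1.5, 14), 0.4009, tolerance = 1e-4)
  expect_equal(effect_magnitude(c(0.05, 0.2, 0.4, 0.7)),
               c("negligible", "small", "medium", "large"))
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("ns", "*", "**", "***", NA))
})

test_that("compare_conditions gates pairwise tests on the omnibus", {
  set.seed(55)
  null_data <- tidyr::expand_grid(participant = 1:14,
                                  condition = c("Free", "RF", "RP"),
                                  metric = "mdist_cm")
  null_data$value <- rnorm(nrow(null_data))
  cc <- compare_conditions(null_data)
  if (cc$omnibus$p_value >= 0.05) {
    expect_equal(nrow(cc$pairwise), 0)
  }

  effect_data <- null_data
  effect_data$value <- effect_data$value +
    2 * (effect_data$condition != "Free")
  cc2 <- compare_conditions(effect_data)
  expect_lt(cc2$omnibus$p_value, 0.05)
  pw <- tidy(cc2)
  expect_equal(nrow(pw), 3)
  expect_true(all(c("z", "p_value", "r", "tier") %in% names(pw)))
  expect_true(all(abs(pw$r) <= 1))
  expect_s3_class(glance(cc2), "tbl_df")
  # Free differs from both robot conditions, which do not differ
  ffr <- pw[pw$condition_a == "Free" & pw$condition_b == "RF", ]
  expect_lt(ffr$p_value, 0.01)
})
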