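test_that("mean distance recovers analytic geometries", {
  c1 <- circle_xy(r = 2, n = 2000, center = c(5, -3))
  expect_equal(mean_distance(c1$ml, c1$ap), 2, tolerance = 1e-9)
  expect_equal(mean_distance(rep(1.3, 10), rep(-0.2, 10)), 0)
  expect_equal(mean_distance(c(1, -1, 0, 0), c(0, 0, 1, -1)), 1)
  expect_true(is.na(mean_distance(NA_real_, NA_real_)))
})

test_that("mean velocity equals path length over duration", {
  # closed circle of radius 1 traversed once in 2 s: speed pi cm/s
  th <- seq(0, 2 * pi, length.out = 1001)
  rate <- 1000 / 2
  v <- mean_velocity(cos(th), sin(th), rate)
  expect_equal(v, pi, tolerance = 1e-3)

  expect_equal(mean_velocity(rep(0, 100), rep(0, 100), 100), 0)
  # straight line, 10 cm in 5 s
  n <- 501
  expect_equal(mean_velocity(seq(0, 10, length.out = n), rep(0, n),
                             (n - 1) / 5), 2)
})

test_that("confidence ellipse area matches the bivariate normal oracle", {
  set.seed(2024)
  n <- 1e5
  area <- confidence_ellipse_area(rnorm(n), rnorm(n))
  expect_equal(area, pi * 5.991, tolerance = 0.03)

  # quadratic scaling
  set.seed(7)
  x <- rnorm(500); y <- rnorm(500, sd = 0.5)
  expect_equal(confidence_ellipse_area(3 * x, 3 * y),
               9 * confidence_ellipse_area(x, y), tolerance = 1e-9)

  # collinear sway: degenerate covariance
  expect_warning(a0 <- confidence_ellipse_area(1:50, 2 * (1:50) + 3),
                 "degenerate")
  expect_equal(a0, 0)
})

test_that("sway area recovers swept-area geometries", {
  n <- 2000
  c1 <- circle_xy(r = 1, n = n)
  rate <- (n - 1) / 1   # one revolution in 1 s
  expect_equal(sway_area(c1$ml, c1$ap, rate), pi, tolerance = 0.005)

  # back-and-forth along a line sweeps nothing
  x <- c(seq(0, 5, length.out = 50), seq(5, 0, length.out = 50))
  expect_equal(sway_area(x, 0.5 * x, 99), 0, tolerance = 1e-12)

  # same geometry at half the rate: doubled duration, halved value
  a1 <- sway_area(c1$ml, c1$ap, rate)
  a2 <- sway_area(c1$ml, c1$ap, rate / 2)
  expect_equal(a2, a1 / 2, tolerance = 1e-12)
})

test_that("all four metrics are translation- and rotation-invariant", {
  set.seed(31)
  for (k in 1:5) {
    w <- random_walk_xy(300)
    th <- runif(1, 0, 2 * pi)
    rml <- cos(th) * w$ml - sin(th) * w$ap
    rap <- sin(th) * w$ml + cos(th) * w$ap
    sml <- w$ml + 12.3; sap <- w$ap - 4.5
    expect_equal(mean_distance(rml, rap), mean_distance(w$ml, w$ap),
                 tolerance = 1e-10)
    expect_equal(mean_distance(sml, sap), mean_distance(w$ml, w$ap),
                 tolerance = 1e-10)
    expect_equal(mean_velocity(rml, rap, 100), mean_velocity(w$ml, w$ap, 100),
                 tolerance = 1e-10)
    expect_equal(confidence_ellipse_area(rml, rap),
                 confidence_ellipse_area(w$ml, w$ap), tolerance = 1e-9)
    expect_equal(sway_area(rml, rap, 100), sway_area(w$ml, w$ap, 100),
                 tolerance = 1e-10)
    expect_equal(sway_area(sml, sap, 100), sway_area(w$ml, w$ap, 100),
                 tolerance = 1e-10)
  }
})

test_that("swept area is bounded by mean velocity times mean distance", {
  set.seed(77)
  for (k in 1:20) {
    w <- random_walk_xy(250)
    rate <- 100
    expect_lte(sway_area(w$ml, w$ap, rate),
               mean_velocity(w$ml, w$ap, rate) * mean_distance(w$ml, w$ap) +
                 1e-12)
  }
})

test_that("invalid samples are dropped without fabricating excursions", {
  # a gap across a large jump must not add path length
  ml <- c(seq(0, 1, length.out = 50), NA, seq(10, 11, length.out = 50))
  ap <- rep(0, 101)
  v <- mean_velocity(ml, ap, 100)
  # 98 valid adjacent chords of 1/49 cm each, over 0.98 s at 100 Hz
  expect_equal(v, 2 / 0.98, tolerance = 1e-9)
})

test_that("sway_metrics computes one row per manipulation cycle", {
  n <- 500
  c1 <- circle_xy(r = 2, n = n)
  cop <- tibble::tibble(ml = c1$ml, ap = c1$ap, valid = TRUE)
  cycles <- tibble::tibble(cycle = 1:2, start = c(1, 251), end = c(250, 500))
  m <- sway_metrics(cop, cycles, rate_hz = 250)
  expect_equal(nrow(m), 2)
  expect_equal(m$n_samples, c(250, 250))
  expect_equal(m$duration_s, c(0.996, 0.996))
  expect_true(all(m$mdist_cm > 0))
})

test_that("aggregation averages cycles within trials, then trials", {
  base <- tibble::tibble(
    participant = 1, condition = "Free", trial = 1, cycle = 1:3,
    n_samples = 100, duration_s = 1, mdist_cm = c(1, 2, 3)
  )
  agg <- aggregate_sway(base)
  expect_equal(agg$value[agg$metric == "mdist_cm"], 2)

  trials <- tibble::tibble(
    participant = 1, condition = "Free", trial = rep(1:3, each = 1),
    cycle = 1, n_samples = 100, duration_s = 1, mdist_cm = c(2, 2, 5)
  )
  agg2 <- aggregate_sway(trials)
  expect_equal(agg2$value[agg2$metric == "mdist_cm"], 3)

  # idempotence: identical cycles aggregate to the cycle value
  same <- dplyr::mutate(base, mdist_cm = 1.23)
  expect_equal(aggregate_sway(same)$value, 1.23)

  # a condition with no valid cycle flags the participant incomplete
  bad <- dplyr::mutate(base, mdist_cm = NA_real_)
  expect_warning(agg3 <- aggregate_sway(bad), "incomplete")
  expect_true(is.na(agg3$value))
})
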