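test_that("time-delay embedding follows the definition", {
  s <- c(1, 2, 3, 4, 5)
  expect_equal(embed_series(s, m = 1, tau = 3), matrix(s, ncol = 1))
  expect_equal(embed_series(s, m = 2, tau = 2),
               matrix(c(1, 2, 3, 3, 4, 5), ncol = 2))
  expect_equal(nrow(embed_series(rnorm(10), m = 3, tau = 4)), 2)
  expect_error(embed_series(rnorm(8), m = 3, tau = 4), "too short")
})

test_that("cycle delay is the rounded mean manipulation interval", {
  cyc <- function(lens) {
    starts <- cumsum(c(1, lens[-length(lens)] + 10))
    tibble::tibble(cycle = seq_along(lens), start = starts,
                   end = starts + lens - 1)
  }
  expect_equal(cycle_delay(cyc(c(500, 500, 500))), 500L)
  expect_equal(cycle_delay(cyc(c(400, 500, 600))), 500L)
  expect_equal(cycle_delay(cyc(3)), 3L)
  expect_error(cycle_delay(tibble::tibble()), "empty")
})

test_that("radial component is the centroid distance series", {
  c1 <- circle_xy(r = 3, n = 500, center = c(2, 2))
  expect_equal(radial_component(c1$ml, c1$ap), rep(3, 500), tolerance = 1e-9)
  ap <- sin(seq(0, 10, length.out = 200))
  expect_equal(radial_component(rep(1, 200), ap), abs(ap - mean(ap)))
  expect_equal(radial_component(c(1, -1, 0, 0), c(0, 0, 1, -1)), rep(1, 4))
})

test_that("recurrence matrix matches brute force on random state sets", {
  set.seed(8)
  for (k in 1:10) {
    n <- sample(20:60, 1)
    m <- sample(1:3, 1)
    states <- matrix(rnorm(n * m), ncol = m)
    nrm <- sample(c("euclidean", "maximum"), 1)
    eps <- runif(1, 0.05, 0.3)
    R <- recurrence_matrix(states, eps, "fraction", nrm)
    dmax <- max(as.matrix(stats::dist(states, method = nrm)))
    expect_identical(R, oracle_recurrence(states, eps * dmax, nrm))
    expect_true(isSymmetric(R))
    expect_true(all(diag(R)))
  }
})

test_that("recurrence matrix edge cases behave", {
  expect_true(all(recurrence_matrix(matrix(1, 3, 1), 0.1, "absolute")))
  expect_error(recurrence_matrix(matrix(1, 3, 1), 0.1, "fraction"),
               "absolute")
  R <- recurrence_matrix(matrix(c(0, 1), ncol = 1), epsilon = 0.5,
                         "absolute")
  expect_equal(R, diag(2) == 1, ignore_attr = TRUE)
})

test_that("recurrence rate counts admissible pairs only", {
  expect_equal(recurrence_rate(matrix(TRUE, 4, 4)), 1)
  expect_equal(recurrence_rate(diag(4) == 1, theiler = 0), 0)
  expect_error(recurrence_rate(matrix(TRUE, 3, 3), theiler = 5),
               "no admissible")
})

test_that("determinism separates isolated points from diagonal structures", {
  # isolated recurrent points only
  R <- diag(6) == 1
  R[1, 4] <- R[4, 1] <- TRUE
  R[2, 6] <- R[6, 2] <- TRUE
  expect_equal(determinism(R), 0)
  # full admissible region: one maximal run per diagonal; only the two
  # single-point corner diagonals fall below l_min = 2, so DET = 9/10
  expect_equal(determinism(matrix(TRUE, 5, 5)), 0.9)
  expect_equal(determinism(matrix(TRUE, 40, 40)),
               oracle_rec_det(matrix(TRUE, 40, 40))$det)
  # no recurrent point at all
  expect_true(is.na(determinism(diag(3) == 1)))
})

test_that("REC and DET match the brute-force oracle on structured series", {
  set.seed(12)
  for (k in 1:6) {
    n <- sample(60:120, 1)
    x <- sin(seq(0, runif(1, 4, 10) * pi, length.out = n)) + rnorm(n, 0, 0.2)
    v <- embed_series(x, 2, sample(3:8, 1))
    R <- recurrence_matrix(v, 0.15, "fraction")
    o <- oracle_rec_det(R, l_min = 2, theiler = 0)
    expect_equal(recurrence_rate(R, 0), o$rec)
    expect_equal(determinism(R, 2, 0), o$det)
  }
})

test_that("ratio is determinism over recurrence", {
  expect_equal(rqa_ratio(0.5, 0.9), 1.8)
  expect_equal(rqa_ratio(0.4, 0.4), 1)
  expect_equal(rqa_ratio(0.31, 1), 1 / 0.31)
  expect_true(is.na(rqa_ratio(0, 0.5)))
})

test_that("run_rqa is deterministic and respects its length contract", {
  tr <- generate_trial(default_presets()$Free, seed = 5)
  res <- process_trial(tr)
  res2 <- process_trial(tr)
  expect_identical(res$rqa, res2$rqa)

  cop <- tibble::tibble(ml = rnorm(50), ap = rnorm(50), valid = TRUE)
  cycles <- tibble::tibble(cycle = 1, start = 1, end = 50)
  expect_error(run_rqa(cop, cycles, rqa_config(m = 2)), "too short")
})

test_that("REC grows with the radius and DET sees periodic structure", {
  set.seed(9)
  t <- seq(0, 8 * pi, length.out = 300)
  periodic <- sin(t)
  noise <- rnorm(300)
  cyc <- tibble::tibble(cycle = 1:4, start = c(1, 76, 151, 226),
                        end = c(75, 150, 225, 300))
  mk <- function(x) tibble::tibble(ml = x, ap = x, valid = TRUE)
  cfgs <- lapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                 function(e) rqa_config(epsilon = e, tau = 19))
  recs <- vapply(cfgs, function(cf) {
    run_rqa(mk(periodic), cyc, cf)$rec[1]
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))

  r_per <- run_rqa(mk(periodic), cyc, rqa_config(tau = 19))
  r_noi <- run_rqa(mk(noise), cyc, rqa_config(tau = 19))
  expect_gt(r_per$det[1], r_noi$det[1])
  expect_gt(r_per$ratio[1], r_noi$ratio[1])
})

test_that("RQA is invariant to offset, and to scale with fractional radius", {
  set.seed(14)
  x <- sin(seq(0, 12 * pi, length.out = 250)) + rnorm(250, 0, 0.1)
  v1 <- embed_series(x, 2, 5)
  v2 <- embed_series(x + 57, 2, 5)
  v3 <- embed_series(x * 3.7, 2, 5)
  R1 <- recurrence_matrix(v1, 0.1, "fraction")
  expect_identical(R1, recurrence_matrix(v2, 0.1, "fraction"))
  expect_identical(R1, recurrence_matrix(v3, 0.1, "fraction"))
})
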