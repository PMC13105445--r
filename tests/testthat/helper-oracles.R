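# Independent oracles, deliberately written as naive enumerations so they
# share no code path with the package implementation.

# brute-force recurrence matrix: explicit O(N^2) pairwise loop
oracle_recurrence <- function(states, eps_abs, norm = "euclidean") {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  n <- nrow(states)
  R <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- states[i, ] - states[j, ]
      dist_ij <- if (norm == "euclidean") sqrt(sum(d^2)) else max(abs(d))
      R[i, j] <- dist_ij <= eps_abs
    }
  }
  R
}

# recurrence rate and determinism by direct pair counting and an explicit
# diagonal-by-diagonal run scan over the full matrix
oracle_rec_det <- function(R, l_min = 2, theiler = 0) {
  n <- nrow(R)
  n_rec <- 0
  n_adm <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) > theiler) {
        n_adm <- n_adm + 1
        if (R[i, j]) n_rec <- n_rec + 1
      }
    }
  }
  on_lines <- 0
  for (k in setdiff(seq(-(n - 1), n - 1), seq(-theiler, theiler))) {
    run <- 0
    for (i in seq_len(n)) {
      j <- i + k
      inside <- j >= 1 && j <= n
      if (inside && R[i, j]) {
        run <- run + 1
      } else {
        if (run >= l_min) on_lines <- on_lines + run
        run <- 0
      }
    }
    if (run >= l_min) on_lines <- on_lines + run
  }
  list(
    rec = n_rec / n_adm,
    det = if (n_rec == 0) NA_real_ else on_lines / n_rec
  )
}

# uniformly sampled circle trajectory (one full revolution, closed start)
circle_xy <- function(r = 1, n = 1000, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  list(ml = center[1] + r * cos(th), ap = center[2] + r * sin(th))
}

# bounded 2-D random walk segment for invariance properties
random_walk_xy <- function(n = 400) {
  list(ml = cumsum(rnorm(n, sd = 0.1)), ap = cumsum(rnorm(n, sd = 0.1)))
}

expect_no_warning_value <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    stop("unexpected warning: ", conditionMessage(w))
  })
}
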