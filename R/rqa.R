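#' Recurrence-analysis configuration
#'
#' Bundles the tunable parameters of the recurrence quantification analysis.
#' The defaults reflect posturographic practice for cycle-structured COP
#' series: a low embedding dimension (`m = 2`), recurrence radius expressed
#' as a fraction (10%) of the attractor diameter so trials of different
#' amplitude are comparable, minimum diagonal length 2, and a Theiler
#' exclusion of the main diagonal only (`theiler = 0` removes the trivial
#' self-matches i = j from both numerator and denominator).
#'
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1), or `NULL` to derive it from the cycle
#'   structure via [cycle_delay()].
#' @param epsilon Recurrence radius; interpretation set by `epsilon_unit`.
#' @param epsilon_unit `"fraction"` (of the maximal phase-space distance) or
#'   `"absolute"` (same units as the embedded signal, cm).
#' @param l_min Minimum diagonal line length in samples (>= 2).
#' @param theiler Half-width of the excluded band around the main diagonal;
#'   pairs with `|i - j| <= theiler` are ignored.
#' @param norm Phase-space distance: `"euclidean"` or `"maximum"`.
#' @return A list of class `rqa_config`.
#' @export
rqa_config <- function(m = 2, tau = NULL, epsilon = 0.10,
                       epsilon_unit = c("fraction", "absolute"),
                       l_min = 2, theiler = 0,
                       norm = c("euclidean", "maximum")) {
  epsilon_unit <- match.arg(epsilon_unit)
  norm <- match.arg(norm)
  stopifnot(m >= 1, is.null(tau) || tau >= 1, epsilon > 0, l_min >= 2,
            theiler >= 0)
  structure(
    list(m = as.integer(m), tau = if (is.null(tau)) NULL else as.integer(tau),
         epsilon = epsilon, epsilon_unit = epsilon_unit,
         l_min = as.integer(l_min), theiler = as.integer(theiler),
         norm = norm),
    class = "rqa_config"
  )
}

#' Radial component of a COP segment
#'
#' Distance of each COP sample from the centroid of the analyzed series:
#' the scalar series combining ML and AP sway that the planar
#' (anteroposterior-mediolateral) recurrence analysis is run on.
#'
#' @param ml,ap COP coordinates, cm.
#' @return Numeric vector, cm.
#' @export
radial_component <- function(ml, ap) {
  sqrt((ml - mean(ml))^2 + (ap - mean(ap))^2)
}

#' Embedding delay from the cycle structure
#'
#' The delay is tied to the task's own time scale: the average manipulation
#' interval length of the trial, rounded to the nearest sample (minimum 1).
#'
#' @param cycles Tibble of intervals (`start`, `end`, 1-based inclusive).
#' @return Integer delay in samples.
#' @export
cycle_delay <- function(cycles) {
  if (is.null(cycles) || nrow(cycles) == 0) {
    stop("cannot derive a delay from an empty cycle set", call. = FALSE)
  }
  max(1L, as.integer(round(mean(cycles$end - cycles$start + 1))))
}

#' Time-delay embedding
#'
#' Builds the sequence of m-dimensional delay vectors
#' \eqn{v_i = (s_i, s_{i+\tau}, \dots, s_{i+(m-1)\tau})}.
#'
#' @param x Numeric series of length N; requires `N > (m-1) * tau`.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return Matrix with `N - (m-1)*tau` rows and `m` columns.
#' @export
embed_series <- function(x, m, tau) {
  stopifnot(m >= 1, tau >= 1)
  n <- length(x)
  n_states <- n - (m - 1) * tau
  if (n_states < 1) {
    stop("series too short for embedding: need length > ", (m - 1) * tau,
         " (m = ", m, ", tau = ", tau, "), got ", n, call. = FALSE)
  }
  idx <- outer(seq_len(n_states), (seq_len(m) - 1L) * tau, "+")
  matrix(x[idx], nrow = n_states, ncol = m)
}

#' Recurrence matrix of a set of embedded states
#'
#' Binary symmetric matrix with `R[i, j] = 1` iff the phase-space distance
#' between states i and j is at most the recurrence radius. A fractional
#' radius is resolved against the maximal pairwise distance (the attractor
#' diameter).
#'
#' @param states Numeric matrix of embedded states (rows) from
#'   [embed_series()], or a vector (treated as 1-D states).
#' @param epsilon Radius; see `epsilon_unit`.
#' @param epsilon_unit `"fraction"` of the diameter or `"absolute"`.
#' @param norm `"euclidean"` or `"maximum"` distance.
#' @return Logical matrix, symmetric with `TRUE` diagonal.
#' @export
recurrence_matrix <- function(states, epsilon,
                              epsilon_unit = c("fraction", "absolute"),
                              norm = c("euclidean", "maximum")) {
  epsilon_unit <- match.arg(epsilon_unit)
  norm <- match.arg(norm)
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  if (nrow(states) < 2) stop("need at least 2 states", call. = FALSE)
  stopifnot(epsilon > 0)
  d <- if (norm == "euclidean") {
    sq <- rowSums(states^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(states)
    sqrt(pmax(d2, 0))
  } else {
    dm <- matrix(0, nrow(states), nrow(states))
    for (jj in seq_len(ncol(states))) {
      dm <- pmax(dm, abs(outer(states[, jj], states[, jj], "-")))
    }
    dm
  }
  eps_abs <- if (epsilon_unit == "fraction") {
    dmax <- max(d)
    if (dmax == 0) {
      stop("all states identical: diameter is 0, use an absolute epsilon",
           call. = FALSE)
    }
    epsilon * dmax
  } else {
    epsilon
  }
  d <= eps_abs
}

#' Recurrence rate
#'
#' Density of recurrent pairs in the admissible region of the recurrence
#' plot: pairs with `|i - j| > theiler` (with the default `theiler = 0` the
#' trivial identity line i = j is excluded from both numerator and
#' denominator).
#'
#' @param R Logical recurrence matrix.
#' @param theiler Excluded band half-width.
#' @return Fraction in `[0, 1]`.
#' @export
recurrence_rate <- function(R, theiler = 0) {
  n <- nrow(R)
  n_adm <- n_admissible(n, theiler)
  if (n_adm == 0) {
    stop("Theiler window leaves no admissible pairs", call. = FALSE)
  }
  2 * nrow(upper_recurrences(R, theiler)) / n_adm
}

# pairs with |i - j| > theiler among n^2
n_admissible <- function(n, theiler) {
  band <- sum(pmax(0, n - abs(seq(-theiler, theiler))))
  n^2 - band
}

# recurrent (i, j) pairs with j - i > theiler, as a 2-column matrix
upper_recurrences <- function(R, theiler) {
  pts <- which(R, arr.ind = TRUE)
  pts[pts[, 2] - pts[, 1] > theiler, , drop = FALSE]
}

#' Determinism
#'
#' Fraction of admissible recurrent points that lie on diagonal line
#' structures of length at least `l_min` — maximal runs of recurrences
#' parallel to the main diagonal, outside the Theiler band. High determinism
#' means postural states that recur do so in extended, predictable
#' stretches.
#'
#' @inheritParams recurrence_rate
#' @param l_min Minimum diagonal line length.
#' @return Fraction in `[0, 1]`; `NA` when the admissible region holds no
#'   recurrent point.
#' @export
determinism <- function(R, l_min = 2, theiler = 0) {
  pts <- upper_recurrences(R, theiler)
  if (nrow(pts) == 0) return(NA_real_)
  # maximal diagonal runs: consecutive points on the same j - i offset;
  # the lower triangle mirrors the upper, so DET follows from one triangle
  k <- pts[, 2] - pts[, 1]
  ord <- order(k, pts[, 1])
  i_s <- pts[ord, 1]
  k_s <- k[ord]
  new_run <- c(TRUE, diff(i_s) != 1L | diff(k_s) != 0L)
  run_len <- rle(cumsum(new_run))$lengths
  sum(run_len[run_len >= l_min]) / nrow(pts)
}

#' Determinism-to-recurrence ratio
#'
#' @param rec,det Recurrence rate and determinism.
#' @return `det / rec`; `NA` when `rec` is zero or either input is missing.
#' @export
rqa_ratio <- function(rec, det) {
  ifelse(is.na(rec) | is.na(det) | rec == 0, NA_real_, det / rec)
}

# REC/DET/RATIO for one scalar series under a resolved config
rqa_stats <- function(x, config) {
  v <- embed_series(x, config$m, config$tau)
  R <- recurrence_matrix(v, config$epsilon, config$epsilon_unit, config$norm)
  rec <- recurrence_rate(R, config$theiler)
  det <- determinism(R, config$l_min, config$theiler)
  tibble(rec = rec, det = det, ratio = rqa_ratio(rec, det))
}

#' Recurrence quantification of a trial's manipulation phases
#'
#' Concatenates the manipulation-phase COP samples of a trial and computes
#' REC, DET and RATIO on three scalar components: the planar radial
#' component (labelled `APML`), and the anteroposterior (`AP`) and
#' mediolateral (`ML`) coordinates alone. Unless given in `config`, the
#' embedding delay is the trial's average manipulation interval length
#' ([cycle_delay()]), anchoring the analysis to the task's cycle structure.
#'
#' @param cop COP tibble at the kinematic rate (`ml`, `ap`, optional
#'   `valid`).
#' @param cycles Manipulation intervals from
#'   [extract_manipulation_phases()].
#' @param config An [rqa_config()]; `config$tau = NULL` derives the delay
#'   from `cycles`.
#' @return A tibble with one row per component: `component`, `rec`, `det`,
#'   `ratio`, `n_states`, `m`, `tau`, `epsilon`, `epsilon_unit`, `l_min`,
#'   `theiler`, `norm`.
#' @export
run_rqa <- function(cop, cycles, config = rqa_config()) {
  stopifnot(inherits(config, "rqa_config"))
  idx <- unlist(purrr::map2(cycles$start, cycles$end, seq.int))
  keep <- if ("valid" %in% names(cop)) cop$valid[idx] else TRUE
  idx <- idx[keep & is.finite(cop$ml[idx]) & is.finite(cop$ap[idx])]
  ml <- cop$ml[idx]
  ap <- cop$ap[idx]
  cfg <- config
  if (is.null(cfg$tau)) cfg$tau <- cycle_delay(cycles)
  need <- (cfg$m - 1) * cfg$tau + cfg$l_min
  if (length(ml) <= need) {
    stop("concatenated manipulation series too short for RQA: need > ",
         need, " samples, got ", length(ml), call. = FALSE)
  }
  comps <- list(
    APML = radial_component(ml, ap),
    AP = ap,
    ML = ml
  )
  purrr::imap_dfr(comps, function(x, nm) {
    res <- rqa_stats(x, cfg)
    tibble(
      component = nm, rec = res$rec, det = res$det, ratio = res$ratio,
      n_states = length(x) - (cfg$m - 1) * cfg$tau,
      m = cfg$m, tau = cfg$tau, epsilon = cfg$epsilon,
      epsilon_unit = cfg$epsilon_unit, l_min = cfg$l_min,
      theiler = cfg$theiler, norm = cfg$norm
    )
  })
}
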