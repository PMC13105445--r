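#' Linear sway statistics of a COP segment
#'
#' The four conventional stabilogram statistics, each computed on one
#' manipulation-phase segment of the COP trajectory:
#'
#' * `mean_distance()` — mean radial distance (cm) of the COP from the
#'   segment centroid: the extent of postural displacement.
#' * `mean_velocity()` — total COP path length divided by segment duration
#'   (cm/s): the speed of postural adjustments.
#' * `confidence_ellipse_area()` — area (cm²) of the 95% confidence ellipse
#'   of the (ML, AP) samples under a bivariate normal model,
#'   \eqn{\pi\,\chi^2_{2,.95}\sqrt{\lambda_1\lambda_2}} with \eqn{\lambda}
#'   the eigenvalues of the sample covariance; captures the spread and
#'   directionality of sway.
#' * `sway_area()` — area per unit time (cm²/s) swept by the vector from the
#'   centroid to the moving COP, accumulated as shoelace triangle areas:
#'   a hybrid extent/speed measure of postural instability.
#'
#' Invalid (`NA`) samples are dropped for `mean_distance` and
#' `confidence_ellipse_area`; for the path-based measures the chord across a
#' gap is not counted and the duration is reduced accordingly, so missing
#' epochs never fabricate excursions.
#'
#' @param ml,ap Numeric vectors, COP coordinates in cm (equal length).
#' @param rate_hz Sampling rate in Hz (path-based measures only).
#' @return A single non-negative number; `NA` if fewer than 2 (3 for the
#'   areas) valid samples remain.
#' @name sway_statistics
NULL

#' @rdname sway_statistics
#' @export
mean_distance <- function(ml, ap) {
  ok <- is.finite(ml) & is.finite(ap)
  if (sum(ok) < 2) return(NA_real_)
  x <- ml[ok] - mean(ml[ok])
  y <- ap[ok] - mean(ap[ok])
  mean(sqrt(x^2 + y^2))
}

#' @rdname sway_statistics
#' @export
mean_velocity <- function(ml, ap, rate_hz) {
  stopifnot(rate_hz > 0)
  ok <- is.finite(ml) & is.finite(ap)
  if (sum(ok) < 2) return(NA_real_)
  # chords between samples adjacent in time and both valid
  pair_ok <- ok[-length(ok)] & ok[-1]
  if (!any(pair_ok)) return(NA_real_)
  dml <- diff(ml)[pair_ok]
  dap <- diff(ap)[pair_ok]
  sum(sqrt(dml^2 + dap^2)) / (sum(pair_ok) / rate_hz)
}

#' @rdname sway_statistics
#' @export
confidence_ellipse_area <- function(ml, ap) {
  ok <- is.finite(ml) & is.finite(ap)
  if (sum(ok) < 3) return(NA_real_)
  s <- stats::cov(cbind(ml[ok], ap[ok]))
  d <- s[1, 1] * s[2, 2] - s[1, 2]^2
  if (d <= .Machine$double.eps * (s[1, 1] + s[2, 2])^2) {
    warning("degenerate (collinear) COP segment: ellipse area 0", call. = FALSE)
    return(0)
  }
  pi * qchisq(0.95, df = 2) * sqrt(d)
}

#' @rdname sway_statistics
#' @export
sway_area <- function(ml, ap, rate_hz) {
  stopifnot(rate_hz > 0)
  ok <- is.finite(ml) & is.finite(ap)
  if (sum(ok) < 3) return(NA_real_)
  x <- ml - mean(ml[ok])
  y <- ap - mean(ap[ok])
  pair_ok <- ok[-length(ok)] & ok[-1]
  if (!any(pair_ok)) return(NA_real_)
  i <- which(pair_ok)
  tri <- abs(x[i + 1] * y[i] - x[i] * y[i + 1])
  sum(tri) / (2 * (sum(pair_ok) / rate_hz))
}

#' Per-cycle sway metrics for one trial
#'
#' Applies the four linear sway statistics to every manipulation-phase
#' segment of a COP trajectory.
#'
#' @param cop Tibble from [combine_cop()] (after resampling to the kinematic
#'   rate): columns `ml`, `ap`, `valid`.
#' @param cycles Tibble of manipulation intervals from
#'   [extract_manipulation_phases()]: columns `cycle`, `start`, `end`.
#' @param rate_hz Kinematic sampling rate, Hz.
#' @return A tibble with one row per cycle: `cycle`, `n_samples`,
#'   `duration_s`, `mdist_cm`, `mvelo_cm_s`, `area_ce_cm2`, `area_sw_cm2_s`.
#' @export
sway_metrics <- function(cop, cycles, rate_hz = 250) {
  stopifnot(all(c("ml", "ap") %in% names(cop)),
            all(c("cycle", "start", "end") %in% names(cycles)))
  ml <- ifelse(if ("valid" %in% names(cop)) cop$valid else TRUE,
               cop$ml, NA_real_)
  ap <- ifelse(if ("valid" %in% names(cop)) cop$valid else TRUE,
               cop$ap, NA_real_)
  vals <- mapply(function(start, end) {
    seg <- seq.int(start, min(end, length(ml)))
    c(length(seg), (length(seg) - 1) / rate_hz,
      mean_distance(ml[seg], ap[seg]),
      mean_velocity(ml[seg], ap[seg], rate_hz),
      confidence_ellipse_area(ml[seg], ap[seg]),
      sway_area(ml[seg], ap[seg], rate_hz))
  }, cycles$start, cycles$end)
  tibble(
    cycle = cycles$cycle, n_samples = as.integer(vals[1, ]),
    duration_s = vals[2, ], mdist_cm = vals[3, ], mvelo_cm_s = vals[4, ],
    area_ce_cm2 = vals[5, ], area_sw_cm2_s = vals[6, ]
  )
}

#' Aggregate per-cycle sway metrics to participant-by-condition means
#'
#' Cycle values are averaged (unweighted) within each trial, and trial means
#' are averaged within each condition, yielding one value per participant,
#' condition and metric — the unit of the within-subject statistical
#' analysis.
#'
#' @param cycle_metrics Long-format tibble with columns `participant`,
#'   `condition`, `trial` and the metric columns produced by
#'   [sway_metrics()] (any subset of numeric metric columns is accepted).
#' @return A tibble with columns `participant`, `condition`, `metric`,
#'   `value`; participants lacking valid cycles in a condition get `NA` and
#'   are flagged with a warning.
#' @export
aggregate_sway <- function(cycle_metrics) {
  stopifnot(all(c("participant", "condition", "trial") %in% names(cycle_metrics)))
  metric_cols <- setdiff(
    names(cycle_metrics)[vapply(cycle_metrics, is.numeric, logical(1))],
    c("participant", "trial", "cycle", "n_samples", "duration_s")
  )
  long <- tidyr::pivot_longer(
    cycle_metrics,
    cols = all_of(metric_cols), names_to = "metric", values_to = "value"
  )
  out <- long %>%
    group_by(.data$participant, .data$condition, .data$trial, .data$metric) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$participant, .data$condition, .data$metric) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  out$value[is.nan(out$value)] <- NA_real_
  if (anyNA(out$value)) {
    warning("participant(s) with no valid cycles in a condition: ",
            "flagged incomplete (NA)", call. = FALSE)
  }
  out
}
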