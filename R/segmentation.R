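#' Detect task-repetition boundaries from the wrist mediolateral trace
#'
#' Each repetition of the manipulation task ends with the right wrist at its
#' maximum rightward (mediolateral) excursion, so repetition boundaries are
#' the prominent local maxima of the wrist ML coordinate. Detection is
#' two-pass: a permissive pass keeps all local maxima whose topographic
#' prominence is at least `prominence_min` (default 10% of the trace range);
#' a second pass enforces a minimum inter-peak distance of `distance_frac`
#' times the median spacing of the first-pass peaks, discarding the less
#' prominent peak of any close pair. This is robust to measurement noise
#' without assuming a fixed cycle duration.
#'
#' @param ml Numeric vector, wrist ML coordinate (cm) at the kinematic rate.
#' @param prominence_min Minimum peak prominence in cm; `NULL` (default) uses
#'   10% of the trace range.
#' @param distance_frac Minimum inter-peak distance as a fraction of the
#'   median first-pass spacing.
#' @param n_expected Number of repetitions expected in the trial; fewer
#'   detected boundaries raise a warning (partial result), zero is an error.
#'
#' @return Integer vector of boundary sample indices (1-based), strictly
#'   increasing; each marks the completion of one repetition.
#' @export
detect_cycle_boundaries <- function(ml, prominence_min = NULL,
                                    distance_frac = 0.5, n_expected = 5) {
  stopifnot(is.numeric(ml), length(ml) >= 3)
  if (!all(is.finite(ml))) stop("wrist ML trace must be finite", call. = FALSE)
  rng <- diff(range(ml))
  if (is.null(prominence_min)) prominence_min <- 0.1 * rng

  peaks <- local_maxima(ml)
  if (length(peaks) == 0 || rng == 0) {
    stop("segmentation failure: no local maxima in the wrist ML trace",
         call. = FALSE)
  }
  # cheap thinning before the O(N) prominence scan: a peak that is not even
  # the maximum of its local window cannot be a repetition completion
  if (length(peaks) > 20) {
    w <- max(2L, as.integer(0.01 * length(ml)))
    peaks <- peaks[ml[peaks] >= sliding_max(ml, w)[peaks]]
  }
  prom <- peak_prominence(ml, peaks)
  keep <- prom >= prominence_min
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) == 0) {
    stop("segmentation failure: no peak reaches the prominence threshold",
         call. = FALSE)
  }
  if (length(peaks) > 1) {
    d_min <- distance_frac * median(diff(peaks))
    ord <- order(prom, decreasing = TRUE)
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(peaks[i] - peaks[kept]) >= d_min)) kept <- c(kept, i)
    }
    peaks <- sort(peaks[kept])
  }
  if (length(peaks) < n_expected) {
    warning("detected ", length(peaks), " boundaries, expected ", n_expected,
            "; returning partial result", call. = FALSE)
  }
  peaks
}

# O(N) centered sliding maximum over windows [i - w, i + w] (van Herk:
# blockwise forward/backward cumulative maxima)
sliding_max <- function(x, w) {
  n <- length(x)
  l <- 2L * w + 1L
  n_pad <- ceiling((n + 2L * w) / l) * l
  xp <- c(rep(-Inf, w), x, rep(-Inf, n_pad - n - w))
  m <- matrix(xp, nrow = l)
  left <- apply(m, 2, cummax)
  right <- apply(m[rev(seq_len(l)), , drop = FALSE], 2, cummax)
  right <- right[rev(seq_len(l)), , drop = FALSE]
  i <- seq_len(n) + w       # position in padded series
  pmax(as.vector(right)[i - w], as.vector(left)[i + w])
}

# indices of local maxima; plateaus contribute their central sample
local_maxima <- function(x) {
  n <- length(x)
  # collapse plateaus via run-length encoding
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3) return(integer(0))
  v <- r$values
  is_peak <- c(FALSE, v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m], FALSE)
  idx <- which(is_peak)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

# topographic prominence: height above the higher of the two key saddles,
# where each side's saddle is the minimum between the peak and the nearest
# strictly higher sample (or the series end)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l)) min(x[(max(higher_l) + 1):p]) else min(x[1:p])
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r)) {
      min(x[p:(p + min(higher_r) - 1)])
    } else {
      min(x[p:length(x)])
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Extract manipulation phases from segmented cycles
#'
#' Restricts each repetition cycle to its manipulation phase — the epoch when
#' the hand is away from its rightmost rest/grasp station and actively at the
#' object — excluding rest, object pick-up and object release. Cycle k spans
#' from the previous boundary (or the trial start) to boundary k. Within a
#' cycle, the manipulation interval is the longest contiguous run where the
#' wrist ML coordinate lies left of the threshold
#' \eqn{\theta = ML_{rest} - c\,(ML_{rest} - ML_{min})}, with `ML_rest` the
#' wrist's rest/grasp station (estimated robustly as the 85th percentile of
#' the ML trace, insensitive to a brief rightward overshoot at completion)
#' and `ML_min` the leftmost excursion of the trial. The rule is invariant
#' to any constant offset of the wrist trace.
#'
#' @param boundaries Integer vector from [detect_cycle_boundaries()].
#' @param ml Wrist ML coordinate (cm), same series the boundaries were
#'   detected on.
#' @param c_frac Fraction `c` of the rest-to-minimum excursion that must be
#'   covered for a sample to count as manipulation (default 0.8).
#'
#' @return A tibble with one row per retained cycle: `cycle`, `start`, `end`
#'   (1-based inclusive sample indices at the kinematic rate). Cycles whose
#'   manipulation interval is empty are dropped with a warning; an error is
#'   raised if none remain.
#' @export
extract_manipulation_phases <- function(boundaries, ml, c_frac = 0.8) {
  stopifnot(length(boundaries) >= 1, c_frac > 0, c_frac <= 1)
  boundaries <- sort(as.integer(boundaries))
  rest_ml <- unname(stats::quantile(ml, 0.85))
  theta <- rest_ml - c_frac * (rest_ml - min(ml))
  starts <- c(1L, head(boundaries, -1) + 1L)
  out <- vector("list", length(boundaries))
  dropped <- 0L
  for (k in seq_along(boundaries)) {
    seg <- seq.int(starts[k], boundaries[k])
    below <- ml[seg] < theta
    if (!any(below)) {
      dropped <- dropped + 1L
      next
    }
    r <- rle(below)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    runs <- which(r$values)
    j <- runs[which.max(r$lengths[runs])]
    out[[k]] <- tibble(cycle = k, start = seg[starts_r[j]], end = seg[ends_r[j]])
  }
  if (dropped > 0) {
    warning(dropped, " cycle(s) without a manipulation interval dropped",
            call. = FALSE)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    stop("no cycle contains a manipulation interval (wrist never crosses ",
         "the threshold)", call. = FALSE)
  }
  res$cycle <- seq_len(nrow(res))
  res
}

#' Read a phase-annotation file and convert it to cycle intervals
#'
#' When manually annotated manipulation phases are available they override
#' the wrist-threshold heuristic. The file is a CSV with columns `cycle`,
#' `start_s`, `end_s` (seconds from trial start).
#'
#' @param path CSV file path.
#' @param rate_hz Kinematic sampling rate used to convert seconds to samples.
#' @return A tibble with columns `cycle`, `start`, `end` (1-based samples).
#' @export
read_phase_annotations <- function(path, rate_hz = 250) {
  ann <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("cycle", "start_s", "end_s") %in% names(ann)))
  tibble(
    cycle = as.integer(ann$cycle),
    start = as.integer(round(ann$start_s * rate_hz)) + 1L,
    end = as.integer(round(ann$end_s * rate_hz))
  )
}
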