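#' Center of pressure from one force platform
#'
#' Converts the six raw channels of a force platform (forces in N, moments in
#' N·m) into the center-of-pressure (COP) trajectory under that foot,
#' expressed in the lab frame in cm. The standard plate kinetics are used:
#' with vertical offset `h` between the plate origin and its top surface,
#' \deqn{COP_x = \frac{-M_y - F_x h}{F_z} + x_0, \qquad
#'       COP_y = \frac{M_x - F_y h}{F_z} + y_0.}
#' Samples where the vertical load is below `fz_min` (an unloaded or nearly
#' unloaded foot) are flagged invalid: the COP is undefined there and the
#' division would blow up.
#'
#' @param plate Data frame with numeric columns `fx`, `fy`, `fz` (N) and
#'   `mx`, `my`, `mz` (N·m), one row per sample.
#' @param origin Length-2 numeric, (x, y) position of the plate origin in the
#'   lab frame, cm. ML = x (rightward positive), AP = y (forward positive).
#' @param surface_offset Vertical distance from the plate origin to its top
#'   surface, cm.
#' @param fz_min Minimum vertical force (N) for a sample to be considered
#'   loaded; below it the sample is flagged invalid.
#'
#' @return A tibble with columns `ml`, `ap` (cm, lab frame), `fz` (N) and
#'   `valid` (logical), one row per input sample. `ml`/`ap` are `NA` at
#'   invalid samples.
#' @examples
#' plate <- tibble::tibble(fx = 0, fy = 0, fz = 700, mx = 0, my = -70, mz = 0)
#' cop_from_plate(plate)  # COP 10 cm to the right of the plate origin
#' @export
cop_from_plate <- function(plate, origin = c(0, 0), surface_offset = 0,
                           fz_min = 20) {
  cols <- c("fx", "fy", "fz", "mx", "my", "mz")
  names(plate) <- tolower(names(plate))
  if (!all(cols %in% names(plate))) {
    stop("`plate` must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(plate)
  lens <- vapply(plate[cols], length, integer(1))
  if (any(lens != n)) stop("plate channels must have equal length", call. = FALSE)
  stopifnot(length(origin) == 2, is.finite(surface_offset), fz_min >= 0)

  h_m <- surface_offset / 100
  fz <- plate$fz
  valid <- is.finite(fz) & abs(fz) >= fz_min
  if (!any(valid)) {
    stop("unusable plate recording: no sample carries vertical load >= ",
         fz_min, " N", call. = FALSE)
  }
  # SI computation, then metres -> cm; lab offsets are already in cm
  ml <- (-plate$my - plate$fx * h_m) / fz * 100 + origin[1]
  ap <- ( plate$mx - plate$fy * h_m) / fz * 100 + origin[2]
  ml[!valid] <- NA_real_
  ap[!valid] <- NA_real_
  tibble::new_tibble(list(ml = ml, ap = ap, fz = fz, valid = valid), nrow = n)
}

#' Total COP as the load-weighted average of the two plates
#'
#' Combines the per-foot COP trajectories into the whole-body COP. At each
#' sample the total COP is the average of the left and right COP weighted by
#' the instantaneous vertical force on each plate (clamped at zero); during
#' single support the total equals the loaded plate's COP exactly. The output
#' frame is the lab frame the per-plate COPs were expressed in, conventionally
#' centered between the two plates.
#'
#' @param left,right Tibbles as returned by [cop_from_plate()], time-aligned
#'   and of equal length.
#' @param rate_hz Sampling rate of the series, Hz (used for the `time`
#'   column).
#' @param meta Optional named list of trial metadata (e.g. `participant`,
#'   `condition`, `trial`) prepended as constant columns.
#'
#' @return A tibble with columns `time` (s), `ml`, `ap` (cm) and `valid`;
#'   samples where neither plate is loaded are invalid (`NA` coordinates).
#' @export
combine_cop <- function(left, right, rate_hz = 500, meta = NULL) {
  if (nrow(left) != nrow(right)) {
    stop("left and right COP series must have equal length", call. = FALSE)
  }
  stopifnot(rate_hz > 0)
  wl <- pmax(left$fz, 0) * left$valid
  wr <- pmax(right$fz, 0) * right$valid
  wtot <- wl + wr
  valid <- wtot > 0
  ml_l <- left$ml; ml_l[!left$valid] <- 0
  ap_l <- left$ap; ap_l[!left$valid] <- 0
  ml_r <- right$ml; ml_r[!right$valid] <- 0
  ap_r <- right$ap; ap_r[!right$valid] <- 0
  ml <- (ml_l * wl + ml_r * wr) / wtot
  ap <- (ap_l * wl + ap_r * wr) / wtot
  ml[!valid] <- NA_real_
  ap[!valid] <- NA_real_
  out <- tibble::new_tibble(
    list(time = (seq_len(nrow(left)) - 1) / rate_hz,
         ml = ml, ap = ap, valid = valid),
    nrow = nrow(left)
  )
  if (!is.null(meta)) out <- tibble::add_column(out, !!!meta, .before = 1)
  out
}

#' Anti-aliased decimation to a lower sampling rate
#'
#' Resamples series from `from_hz` to `to_hz` when the ratio is an integer
#' `k`, by zero-phase low-pass filtering (4th-order Butterworth at
#' 0.4·`to_hz`, applied forward and backward so no phase lag biases velocity
#' estimates) followed by keeping every k-th sample. Edge transients are
#' suppressed by reflecting the series at both ends before filtering.
#'
#' @param x Numeric vector, or a data frame whose numeric columns are all
#'   resampled (logical columns are reduced blockwise with "all").
#' @param from_hz,to_hz Input and output rates, Hz; `from_hz / to_hz` must be
#'   a positive integer.
#' @return Vector (or tibble) of length `floor(n / k)`.
#' @export
resample_to <- function(x, from_hz, to_hz) {
  stopifnot(from_hz > 0, to_hz > 0)
  k <- from_hz / to_hz
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("from_hz must be an integer multiple of to_hz", call. = FALSE)
  }
  k <- as.integer(round(k))
  if (is.data.frame(x)) {
    out <- lapply(x, function(col) {
      if (is.logical(col)) {
        n_out <- floor(length(col) / k)
        blocks <- matrix(col[seq_len(n_out * k)], nrow = k)
        colSums(!blocks) == 0L
      } else if (is.numeric(col)) {
        resample_to(col, from_hz, to_hz)
      } else {
        n_out <- floor(length(col) / k)
        col[seq(1, by = k, length.out = n_out)]
      }
    })
    return(tibble::new_tibble(out, nrow = length(out[[1]])))
  }
  n <- length(x)
  n_out <- floor(n / k)
  if (k == 1L) return(x[seq_len(n_out)])
  filt <- signal::butter(4, 0.4 * to_hz / (from_hz / 2))
  pad <- min(n - 1L, as.integer(3 * k * 10))
  # reflect about the end points to avoid edge transients
  left  <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- zero_phase(filt$b, filt$a, xp)[pad + seq_len(n)]
  y[seq(1, by = k, length.out = n_out)]
}

# forward-backward IIR filtering with zero initial conditions; the caller
# is responsible for padding against edge transients
zero_phase <- function(b, a, x) {
  one_pass <- function(x) {
    v <- stats::filter(c(rep(0, length(b) - 1), x), b,
                       method = "convolution", sides = 1)
    v <- v[-seq_len(length(b) - 1)]
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  rev(one_pass(rev(one_pass(x))))
}
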