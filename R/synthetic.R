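#' Condition presets for the synthetic cohort
#'
#' A preset describes the COP dynamics of one experimental condition of the
#' collaborative-manipulation protocol. Each trial holds 5 repetitions of a
#' cyclic manipulation task; per cycle the COP travels a smooth closed loop
#' (anteroposterior-dominant forward lean, thin mediolateral width), cycles
#' get random center offsets so the whole-trial trace fills the condition's
#' target ranges, and a band-limited Gaussian drift rides under everything.
#' During the rest fraction of each cycle the COP collapses to the baseline
#' point.
#'
#' The three default presets encode the study conditions: `Free` (compact
#' sway, roughly 5 cm in both directions), `RF` (robot free: anteroposterior
#' range grows to about 15 cm) and `RP` (robot plane: about 10 cm
#' anteroposterior). The two robot presets share identical per-cycle loop
#' amplitudes — they differ only in the trial-level anteroposterior spread —
#' reflecting that per-cycle sway magnitude did not differ between the two
#' robot-assisted modes.
#'
#' @param name Condition label.
#' @param ap_range_cm,ml_range_cm Target whole-trial peak-to-peak COP
#'   excursions, cm.
#' @param loop_ap_cm,loop_ml_cm Per-cycle loop peak-to-peak amplitudes, cm
#'   (calibration constants of the generator).
#' @param cycle_period_s Mean cycle duration, s.
#' @param period_jitter,amp_jitter Lognormal sd of the per-cycle period and
#'   amplitude multipliers.
#' @param noise_cm,noise_hz Drift amplitude (sd, cm) and bandwidth (Hz).
#' @param rest_fraction Fraction of each cycle outside the manipulation
#'   phase (rest plus the two hand transits); must be in `[0, 0.5)`.
#' @return A list of class `condition_preset`.
#' @export
condition_preset <- function(name, ap_range_cm, ml_range_cm,
                             loop_ap_cm, loop_ml_cm,
                             cycle_period_s = 3, period_jitter = 0.05,
                             amp_jitter = 0.08,
                             noise_cm = 0.25, noise_hz = 1,
                             rest_fraction = 0.35) {
  stopifnot(ap_range_cm > 0, ml_range_cm > 0, loop_ap_cm > 0, loop_ml_cm > 0,
            cycle_period_s > 0, rest_fraction >= 0, rest_fraction < 0.5,
            loop_ap_cm <= ap_range_cm + 1e-9, noise_cm >= 0, noise_hz > 0)
  if (noise_cm > min(ap_range_cm, ml_range_cm)) {
    stop("drift amplitude exceeds the preset sway range", call. = FALSE)
  }
  structure(
    list(name = name, ap_range_cm = ap_range_cm, ml_range_cm = ml_range_cm,
         loop_ap_cm = loop_ap_cm, loop_ml_cm = loop_ml_cm,
         cycle_period_s = cycle_period_s, period_jitter = period_jitter,
         amp_jitter = amp_jitter, noise_cm = noise_cm, noise_hz = noise_hz,
         rest_fraction = rest_fraction),
    class = "condition_preset"
  )
}

#' @rdname condition_preset
#' @export
default_presets <- function() {
  list(
    Free = condition_preset("Free", ap_range_cm = 5, ml_range_cm = 5,
                            loop_ap_cm = 4.6, loop_ml_cm = 0.5),
    RF = condition_preset("RF", ap_range_cm = 15, ml_range_cm = 5,
                          loop_ap_cm = 6.35, loop_ml_cm = 1.2),
    RP = condition_preset("RP", ap_range_cm = 10, ml_range_cm = 5,
                          loop_ap_cm = 6.35, loop_ml_cm = 1.2)
  )
}

# band-limited stationary Gaussian drift via Fourier synthesis: K equal
# frequency bins below the bandwidth with random phases, scaled to sd
band_limited_drift <- function(t, sd_cm, bw_hz, k = 10) {
  if (sd_cm == 0) return(numeric(length(t)))
  f <- seq(bw_hz / k, bw_hz, length.out = k)
  phi <- runif(k, 0, 2 * pi)
  a <- sd_cm * sqrt(2 / k)
  ph <- matrix(phi, nrow = length(t), ncol = k, byrow = TRUE)
  drop(cos(outer(t, 2 * pi * f) + ph) %*% rep(a, k))
}

#' Generate one synthetic trial
#'
#' Builds the raw recordings of one trial — two 6-channel force-plate series
#' at the force rate and a right-wrist marker trajectory at the kinematic
#' rate — together with the ground truth that produced them: the true COP,
#' the true repetition boundaries and the per-sample phase labels. Plate
#' channels are synthesized by exact inversion of the plate kinetics for a
#' stated body weight split across the two plates, so recomputing the COP
#' from the emitted channels reproduces the truth to numerical precision.
#' The wrist mediolateral trace rests at its rightmost station between
#' cycles and carries one sharp rightward overshoot at each repetition
#' completion.
#'
#' @param preset A [condition_preset()].
#' @param seed Integer seed; the trial is a pure function of
#'   `(preset, seed, effects)`.
#' @param participant,condition,trial Metadata stored with the trial.
#' @param effects Participant-level random effects: `amp` (sway amplitude
#'   multiplier), `period` (cycle period multiplier), `weight_n` (body
#'   weight, N).
#' @param n_cycles Repetitions per trial.
#' @param rate_plate,rate_kin Plate and kinematic sampling rates, Hz
#'   (`rate_plate` must be an integer multiple of `rate_kin`).
#' @return A list of class `coprqa_trial` with elements `left`, `right`
#'   (plate channel tibbles), `wrist` (marker tibble `x`, `y`, `z`),
#'   `plate_geom`, `rate_plate`, `rate_kin`, `meta` and `truth` (`cop` at
#'   the kinematic rate, `cop_plate` at the plate rate, `boundaries`,
#'   `phase`, `preset`).
#' @export
generate_trial <- function(preset, seed, participant = 1L,
                           condition = preset$name, trial = 1L,
                           effects = list(amp = 1, period = 1,
                                          weight_n = 71 * 9.81),
                           n_cycles = 5, rate_plate = 500, rate_kin = 250) {
  stopifnot(inherits(preset, "condition_preset"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  k_dec <- rate_plate / rate_kin
  stopifnot(abs(k_dec - round(k_dec)) < 1e-9)

  # --- timeline -----------------------------------------------------------
  lead_in <- 0.5
  periods <- preset$cycle_period_s * effects$period *
    exp(rnorm(n_cycles, 0, preset$period_jitter))
  cycle_ends <- lead_in + cumsum(periods)
  total <- cycle_ends[n_cycles] + 0.2
  n_hi <- floor(total * rate_plate)
  t_hi <- (seq_len(n_hi) - 1) / rate_plate

  # within-cycle segment fractions: rest | reach | manipulation | return
  f_tr <- min(0.04, preset$rest_fraction / 3)
  f_rest <- preset$rest_fraction - 2 * f_tr
  f_manip <- 1 - preset$rest_fraction

  # envelope s(t): 0 at rest, raised-cosine transits, 1 during manipulation;
  # u(t): progress through the manipulation loop
  s <- numeric(n_hi)
  u <- numeric(n_hi)
  phase <- rep("rest", n_hi)
  starts <- c(lead_in, head(cycle_ends, -1))
  for (kk in seq_len(n_cycles)) {
    tt <- (t_hi - starts[kk]) / periods[kk]
    inside <- tt >= 0 & tt < 1
    w <- tt[inside]
    sk <- numeric(length(w))
    uk <- numeric(length(w))
    ph <- rep("rest", length(w))
    reach <- w >= f_rest & w < f_rest + f_tr
    manip <- w >= f_rest + f_tr & w < f_rest + f_tr + f_manip
    ret <- w >= f_rest + f_tr + f_manip
    sk[reach] <- (1 - cos(pi * (w[reach] - f_rest) / f_tr)) / 2
    sk[manip] <- 1
    sk[ret] <- (1 + cos(pi * (w[ret] - f_rest - f_tr - f_manip) / f_tr)) / 2
    uk[manip] <- (w[manip] - f_rest - f_tr) / f_manip
    uk[ret] <- 1
    ph[reach] <- "reach"; ph[manip] <- "manipulation"; ph[ret] <- "return"
    s[inside] <- sk
    u[inside] <- uk
    phase[inside] <- ph
  }

  # --- true COP ------------------------------------------------------------
  amp_k <- exp(rnorm(n_cycles, 0, preset$amp_jitter)) * effects$amp
  ap_off <- runif(n_cycles, -1, 1) *
    pmax(0, (preset$ap_range_cm - preset$loop_ap_cm) / 2)
  ml_off <- runif(n_cycles, -1, 1) *
    pmax(0, (preset$ml_range_cm - preset$loop_ml_cm) / 2)
  cyc_idx <- pmin(n_cycles, findInterval(t_hi, c(-Inf, cycle_ends)) + 1L)
  g <- amp_k[cyc_idx]
  ap_true <- band_limited_drift(t_hi, preset$noise_cm, preset$noise_hz) +
    s * (ap_off[cyc_idx] + g * preset$loop_ap_cm / 2 * (1 - cos(2 * pi * u)))
  ml_true <- band_limited_drift(t_hi, preset$noise_cm, preset$noise_hz) +
    s * (ml_off[cyc_idx] + g * preset$loop_ml_cm / 2 * sin(2 * pi * u))

  # --- wrist marker (kinematic rate) --------------------------------------
  lo <- seq(1, n_hi, by = k_dec)
  t_lo <- t_hi[lo]
  rest_ml <- 40
  bump <- rowSums(vapply(cycle_ends, function(te) {
    6 * exp(-(t_lo - te)^2 / (2 * 0.02^2))
  }, numeric(length(t_lo))))
  wrist_x <- rest_ml - rest_ml * s[lo] + bump + rnorm(length(lo), 0, 0.05)
  wrist_y <- 50 * s[lo] + rnorm(length(lo), 0, 0.05)
  wrist_z <- 100 - 10 * s[lo] + rnorm(length(lo), 0, 0.05)
  boundaries <- vapply(cycle_ends, function(te) which.min(abs(t_lo - te)),
                       integer(1))

  # --- plate synthesis by exact inversion ---------------------------------
  geom <- list(origin_left = c(-15, 0), origin_right = c(15, 0),
               surface_offset = 4)
  w_r <- pmin(0.9, pmax(0.1, 0.5 + 0.8 * ml_true / (2 * 15)))
  make_plate <- function(w, x0) {
    fz <- w * effects$weight_n
    fx <- 2 * sin(2 * pi * 0.7 * t_hi + runif(1, 0, 2 * pi))
    fy <- 3 * sin(2 * pi * 0.4 * t_hi + runif(1, 0, 2 * pi))
    cx <- x0 + 0.2 * ml_true          # per-plate COP stays under the foot
    cy <- ap_true
    h_m <- geom$surface_offset / 100
    my <- -((cx - x0) / 100 * fz + fx * h_m)
    mx <- (cy - 0) / 100 * fz + fy * h_m
    mz <- 0.3 * sin(2 * pi * 0.6 * t_hi + runif(1, 0, 2 * pi))
    tibble::new_tibble(list(fx = fx, fy = fy, fz = fz, mx = mx, my = my,
                            mz = mz), nrow = n_hi)
  }
  left <- make_plate(1 - w_r, geom$origin_left[1])
  right <- make_plate(w_r, geom$origin_right[1])

  structure(
    list(
      left = left, right = right, plate_geom = geom,
      rate_plate = rate_plate, rate_kin = rate_kin,
      wrist = tibble(x = wrist_x, y = wrist_y, z = wrist_z),
      meta = list(participant = participant, condition = condition,
                  trial = trial, seed = seed),
      truth = list(
        cop = tibble(time = t_lo, ml = ml_true[lo], ap = ap_true[lo]),
        cop_plate = tibble(ml = ml_true, ap = ap_true),
        boundaries = boundaries,
        phase = phase[lo],
        preset = preset
      )
    ),
    class = "coprqa_trial"
  )
}

#' Plan and generate a synthetic cohort
#'
#' `cohort_plan()` lays out the full design — `n` participants x 3
#' conditions x `trials_per_condition` trials — drawing per-participant
#' random effects (lognormal sway-amplitude and cycle-period multipliers,
#' normal body weight) and one sub-seed per trial from the single cohort
#' seed. `generate_cohort()` materializes every trial of the plan (and
#' optionally writes the file tree with a manifest via [write_cohort()]).
#'
#' @param n Number of participants.
#' @param seed Cohort seed; all randomness derives from it.
#' @param presets Named list of [condition_preset()]s.
#' @param trials_per_condition Trials per participant and condition.
#' @return `cohort_plan()`: a tibble with one row per trial (`participant`,
#'   `condition`, `trial`, `trial_seed`, `amp`, `period`, `weight_n`).
#'   `generate_cohort()`: a list of class `coprqa_cohort` with `plan` and
#'   `trials` (list of `coprqa_trial`).
#' @export
cohort_plan <- function(n = 14, seed = 1, presets = default_presets(),
                        trials_per_condition = 3) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eff <- tibble(
    participant = seq_len(n),
    amp = stats::rlnorm(n, 0, 0.25),
    period = stats::rlnorm(n, 0, 0.08),
    weight_n = rnorm(n, 71, 7) * 9.81
  )
  grid <- tidyr::expand_grid(
    participant = seq_len(n),
    condition = names(presets),
    trial = seq_len(trials_per_condition)
  )
  grid$trial_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  left_join(grid, eff, by = "participant")
}

#' @rdname cohort_plan
#' @param out_dir Optional directory; when given the cohort file tree and
#'   manifest are written there.
#' @export
generate_cohort <- function(n = 14, seed = 1, presets = default_presets(),
                            trials_per_condition = 3, out_dir = NULL) {
  plan <- cohort_plan(n, seed, presets, trials_per_condition)
  trials <- purrr::pmap(plan, function(participant, condition, trial,
                                       trial_seed, amp, period, weight_n) {
    generate_trial(presets[[condition]], seed = trial_seed,
                   participant = participant, condition = condition,
                   trial = trial,
                   effects = list(amp = amp, period = period,
                                  weight_n = weight_n))
  })
  cohort <- structure(list(plan = plan, trials = trials, seed = seed),
                      class = "coprqa_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
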