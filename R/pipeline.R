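#' Pipeline configuration
#'
#' All tunable parameters of the analysis chain in one serializable object:
#' COP validity threshold, segmentation parameters, RQA settings and the
#' statistics options. A snapshot is embedded in every [run_pipeline()]
#' result (and written as `config.yaml` next to the outputs).
#'
#' @param fz_min Minimum vertical force (N) for a valid COP sample.
#' @param c_frac Manipulation-threshold fraction of
#'   [extract_manipulation_phases()].
#' @param n_expected Repetitions expected per trial.
#' @param rqa An [rqa_config()] (set `rqa = NULL` to skip the recurrence
#'   analysis).
#' @param alpha Significance level of the statistical chain.
#' @param pairwise_method Pairwise test variant, see [wilcoxon_paired()].
#' @return A list of class `coprqa_config`.
#' @export
coprqa_config <- function(fz_min = 20, c_frac = 0.8, n_expected = 5,
                          rqa = rqa_config(), alpha = 0.05,
                          pairwise_method = "signed_rank") {
  structure(
    list(fz_min = fz_min, c_frac = c_frac, n_expected = n_expected,
         rqa = rqa, alpha = alpha, pairwise_method = pairwise_method),
    class = "coprqa_config"
  )
}

config_as_yaml <- function(config) {
  x <- unclass(config)
  if (!is.null(x$rqa)) x$rqa <- unclass(x$rqa)
  yaml::as.yaml(x)
}

#' Process one trial: raw channels to COP, cycles, sway and RQA
#'
#' Runs the single-trial part of the chain: per-plate COP, load-weighted
#' total COP, anti-aliased resampling to the kinematic rate, repetition
#' segmentation from the wrist marker, manipulation-phase extraction,
#' per-cycle sway metrics and (optionally) recurrence quantification.
#'
#' @param trial A `coprqa_trial` from [generate_trial()] or [read_trial()].
#' @param config A [coprqa_config()].
#' @return A list with `cop` (tibble at the kinematic rate), `cycles`,
#'   `sway` (per-cycle metrics) and `rqa` (per-component results or `NULL`),
#'   each carrying the trial's metadata columns.
#' @export
process_trial <- function(trial, config = coprqa_config()) {
  stopifnot(inherits(trial, "coprqa_trial") || is.list(trial))
  g <- trial$plate_geom
  cop_l <- cop_from_plate(trial$left, g$origin_left, g$surface_offset,
                          config$fz_min)
  cop_r <- cop_from_plate(trial$right, g$origin_right, g$surface_offset,
                          config$fz_min)
  cop_hi <- combine_cop(cop_l, cop_r, trial$rate_plate)
  cop <- resample_to(cop_hi[c("ml", "ap", "valid")],
                     trial$rate_plate, trial$rate_kin)
  cop <- tibble::new_tibble(
    list(time = (seq_len(nrow(cop)) - 1) / trial$rate_kin,
         ml = cop$ml, ap = cop$ap, valid = cop$valid),
    nrow = nrow(cop)
  )
  boundaries <- detect_cycle_boundaries(trial$wrist$x,
                                        n_expected = config$n_expected)
  cycles <- extract_manipulation_phases(boundaries, trial$wrist$x,
                                        config$c_frac)
  cycles$end <- pmin(cycles$end, nrow(cop))
  sway <- sway_metrics(cop, cycles, trial$rate_kin)
  rqa <- if (!is.null(config$rqa)) run_rqa(cop, cycles, config$rqa) else NULL
  with_meta <- function(df) {
    tibble::new_tibble(
      c(list(participant = rep(trial$meta$participant, nrow(df)),
             condition = rep(trial$meta$condition, nrow(df)),
             trial = rep(trial$meta$trial, nrow(df))),
        as.list(df)),
      nrow = nrow(df)
    )
  }
  list(
    cop = with_meta(cop),
    cycles = with_meta(cycles),
    sway = with_meta(sway),
    rqa = if (!is.null(rqa)) with_meta(rqa)
  )
}

#' Run the full analysis pipeline over a cohort
#'
#' Orchestrates synthesis/ingest, COP extraction, segmentation, sway
#' metrics, recurrence analysis and the within-subject statistics for every
#' trial of a cohort, isolating per-trial failures in a machine-readable
#' error ledger. Input is one of: an in-memory `coprqa_cohort`, a directory
#' written by [write_cohort()] (`input_dir`), or a cohort generated on the
#' fly from `seed` (trials are then synthesized one at a time and
#' discarded, keeping memory flat).
#'
#' @param cohort Optional `coprqa_cohort`.
#' @param input_dir Optional directory with a `manifest.csv` and trial
#'   subdirectories.
#' @param seed Cohort seed used when neither `cohort` nor `input_dir` is
#'   given.
#' @param n_participants,presets,trials_per_condition Design of the
#'   generated cohort (ignored for `cohort`/`input_dir` input).
#' @param config A [coprqa_config()].
#' @param out_dir Optional output directory: writes `sway.csv`, `rqa.csv`,
#'   `stats.csv`, `errors.csv`, `log.csv`, `config.yaml`, `report.md` and
#'   figure PNGs.
#' @param keep_cop Keep the per-trial COP trajectories in the result (off
#'   by default: they dominate memory).
#' @return A list of class `coprqa_run`: `sway` (per-cycle), `rqa`
#'   (per-trial per-component), `sway_summary` and `rqa_summary`
#'   (participant x condition means), `stats_sway` and `stats_rqa`
#'   ([compare_conditions()] objects), `errors`, `log` (per-trial status
#'   and timing), `config`, `cop` (if kept).
#' @export
run_pipeline <- function(cohort = NULL, input_dir = NULL, seed = 1,
                         n_participants = 14, presets = default_presets(),
                         trials_per_condition = 3,
                         config = coprqa_config(), out_dir = NULL,
                         keep_cop = FALSE) {
  fetch <- trial_source(cohort, input_dir, seed, n_participants, presets,
                        trials_per_condition)
  sway <- list(); rqa <- list(); cops <- list(); errs <- list()
  log <- vector("list", fetch$n)
  for (i in seq_len(fetch$n)) {
    info <- fetch$meta[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      process_trial(fetch$get(i), config),
      error = function(e) e
    )
    failed <- inherits(res, "error")
    log[[i]] <- tibble(
      participant = info$participant, condition = info$condition,
      trial = info$trial, status = if (failed) "error" else "ok",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
    )
    if (failed) {
      errs[[length(errs) + 1]] <- tibble(
        participant = info$participant, condition = info$condition,
        trial = info$trial, error = conditionMessage(res)
      )
    } else {
      sway[[length(sway) + 1]] <- res$sway
      if (!is.null(res$rqa)) rqa[[length(rqa) + 1]] <- res$rqa
      if (keep_cop) cops[[length(cops) + 1]] <- res$cop
    }
  }
  sway <- bind_rows(sway)
  rqa <- bind_rows(rqa)
  errors <- bind_rows(errs)
  if (nrow(sway) == 0) stop("no trial could be processed", call. = FALSE)

  sway_summary <- aggregate_sway(sway)
  stats_sway <- compare_conditions(sway_summary, alpha = config$alpha,
                                   pairwise_method = config$pairwise_method)
  rqa_summary <- NULL; stats_rqa <- NULL
  if (nrow(rqa) > 0) {
    rqa_summary <- rqa %>%
      tidyr::pivot_longer(c("rec", "det", "ratio"),
                          names_to = "measure", values_to = "value") %>%
      mutate(metric = paste(.data$measure, .data$component, sep = "_")) %>%
      group_by(.data$participant, .data$condition, .data$metric) %>%
      summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    stats_rqa <- compare_conditions(rqa_summary, alpha = config$alpha,
                                    pairwise_method = config$pairwise_method)
  }
  run <- structure(
    list(sway = sway, rqa = rqa, sway_summary = sway_summary,
         rqa_summary = rqa_summary, stats_sway = stats_sway,
         stats_rqa = stats_rqa, errors = errors, log = bind_rows(log),
         config = config, cop = if (keep_cop) bind_rows(cops)),
    class = "coprqa_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# uniform access to the three input routes of run_pipeline()
trial_source <- function(cohort, input_dir, seed, n, presets,
                         trials_per_condition) {
  if (!is.null(cohort)) {
    list(n = length(cohort$trials), meta = cohort$plan,
         get = function(i) cohort$trials[[i]])
  } else if (!is.null(input_dir)) {
    manifest <- readr::read_csv(file.path(input_dir, "manifest.csv"),
                                show_col_types = FALSE)
    list(n = nrow(manifest), meta = manifest,
         get = function(i) {
           read_trial(file.path(input_dir, manifest$path[i], "trial.yaml"))
         })
  } else {
    plan <- cohort_plan(n, seed, presets, trials_per_condition)
    list(n = nrow(plan), meta = plan,
         get = function(i) {
           row <- plan[i, ]
           generate_trial(presets[[row$condition]], seed = row$trial_seed,
                          participant = row$participant,
                          condition = row$condition, trial = row$trial,
                          effects = list(amp = row$amp, period = row$period,
                                         weight_n = row$weight_n))
         })
  }
}

#' @export
print.coprqa_run <- function(x, ...) {
  cat("coprqa pipeline run: ", nrow(x$sway), " cycles from ",
      length(unique(x$sway$participant)), " participants\n", sep = "")
  if (nrow(x$errors)) {
    cat(nrow(x$errors), "trial(s) failed; see $errors\n")
  }
  cat("\n-- Sway metrics --\n"); print(x$stats_sway)
  if (!is.null(x$stats_rqa)) {
    cat("\n-- RQA metrics --\n"); print(x$stats_rqa)
  }
  invisible(x)
}

# write the results tree: CSVs, config snapshot, report, figures
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f),
                                        progress = FALSE)
  wr(run$sway, "sway.csv")
  if (nrow(run$rqa)) wr(run$rqa, "rqa.csv")
  stats <- bind_rows(
    tibble::add_column(tidy(run$stats_sway), family = "sway", .before = 1),
    if (!is.null(run$stats_rqa)) {
      tibble::add_column(tidy(run$stats_rqa), family = "rqa", .before = 1)
    }
  )
  omnibus <- bind_rows(
    tibble::add_column(glance(run$stats_sway), family = "sway", .before = 1),
    if (!is.null(run$stats_rqa)) {
      tibble::add_column(glance(run$stats_rqa), family = "rqa", .before = 1)
    }
  )
  wr(stats, "stats.csv")
  wr(omnibus, "stats_omnibus.csv")
  if (nrow(run$errors)) wr(run$errors, "errors.csv")
  wr(run$log, "log.csv")
  writeLines(config_as_yaml(run$config), file.path(out_dir, "config.yaml"))
  report_md(run, file.path(out_dir, "report.md"))
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  try({
    ggsave(file.path(fig_dir, "sway_boxplots.png"),
           autoplot(run$stats_sway), width = 8, height = 6, dpi = 120)
    if (!is.null(run$stats_rqa)) {
      ggsave(file.path(fig_dir, "rqa_boxplots.png"),
             autoplot(run$stats_rqa), width = 9, height = 8, dpi = 120)
    }
  }, silent = TRUE)
  invisible(out_dir)
}

report_md <- function(run, path) {
  fmt_tbl <- function(df) {
    df[] <- lapply(df, function(c) if (is.numeric(c)) signif(c, 4) else c)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(header, sep, rows)
  }
  lines <- c(
    "# Postural-control analysis report", "",
    sprintf("Participants: %d; cycles analyzed: %d; failed trials: %d.",
            length(unique(run$sway$participant)), nrow(run$sway),
            nrow(run$errors)),
    "", "## Sway metrics: Friedman omnibus", "",
    fmt_tbl(glance(run$stats_sway)),
    "", "## Sway metrics: pairwise comparisons", "",
    if (nrow(tidy(run$stats_sway))) fmt_tbl(tidy(run$stats_sway)) else
      "No metric passed the omnibus gate."
  )
  if (!is.null(run$stats_rqa)) {
    lines <- c(lines, "", "## RQA metrics: Friedman omnibus", "",
               fmt_tbl(glance(run$stats_rqa)),
               "", "## RQA metrics: pairwise comparisons", "",
               if (nrow(tidy(run$stats_rqa))) fmt_tbl(tidy(run$stats_rqa))
               else "No metric passed the omnibus gate.")
  }
  writeLines(unlist(lines), path)
}
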