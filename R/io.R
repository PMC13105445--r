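#' Read force-plate and marker CSV files
#'
#' Plate files are delimited text with a header row and the six channel
#' columns `Fx, Fy, Fz, Mx, My, Mz` (any case); forces in N, moments in N·m
#' or N·mm as declared. Marker files carry `X, Y, Z` columns in mm or cm.
#' All coordinates are converted to the package-internal units (cm) on read.
#'
#' @param path File path (CSV or TSV; delimiter sniffed by readr).
#' @param moment_unit `"Nm"` or `"Nmm"`.
#' @return A tibble with lower-case channel columns.
#' @export
read_plate_csv <- function(path, moment_unit = c("Nm", "Nmm")) {
  moment_unit <- match.arg(moment_unit)
  x <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(x) <- tolower(names(x))
  need <- c("fx", "fy", "fz", "mx", "my", "mz")
  if (!all(need %in% names(x))) {
    stop("plate file ", path, " lacks required columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x <- x[need]
  if (moment_unit == "Nmm") {
    x[c("mx", "my", "mz")] <- x[c("mx", "my", "mz")] / 1000
  }
  x
}

#' @rdname read_plate_csv
#' @param unit Marker coordinate unit, `"cm"` or `"mm"`.
#' @export
read_marker_csv <- function(path, unit = c("cm", "mm")) {
  unit <- match.arg(unit)
  x <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(x) <- tolower(names(x))
  if (!all(c("x", "y", "z") %in% names(x))) {
    stop("marker file ", path, " lacks X, Y, Z columns", call. = FALSE)
  }
  x <- x[c("x", "y", "z")]
  if (unit == "mm") x <- x / 10
  x
}

#' Read a trial from its YAML sidecar configuration
#'
#' The sidecar declares the data files, sampling rates, plate geometry,
#' units and trial metadata; [write_trial()] emits the same dialect. File
#' paths inside the sidecar are resolved relative to its directory.
#'
#' @param config_path Path to a `trial.yaml`.
#' @return A list of class `coprqa_trial` (without ground truth).
#' @export
read_trial <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)
  need <- c("rates", "plates", "marker")
  if (!all(need %in% names(cfg))) {
    stop("trial config must declare: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  moment_unit <- cfg$units$moment %||% "Nm"
  marker_unit <- cfg$units$marker %||% "cm"
  rd <- function(side) {
    p <- cfg$plates[[side]]
    list(
      data = read_plate_csv(file.path(dir, p$file), moment_unit),
      origin = as.numeric(p$origin),
      surface_offset = as.numeric(p$surface_offset %||% 0)
    )
  }
  left <- rd("left"); right <- rd("right")
  structure(
    list(
      left = left$data, right = right$data,
      plate_geom = list(origin_left = left$origin,
                        origin_right = right$origin,
                        surface_offset = left$surface_offset),
      rate_plate = as.numeric(cfg$rates$plate),
      rate_kin = as.numeric(cfg$rates$kinematic),
      wrist = read_marker_csv(file.path(dir, cfg$marker$file), marker_unit),
      meta = list(
        participant = cfg$meta$participant %||% NA,
        condition = cfg$meta$condition %||% NA_character_,
        trial = cfg$meta$trial %||% NA,
        seed = cfg$meta$seed %||% NA
      ),
      truth = NULL
    ),
    class = "coprqa_trial"
  )
}

#' Write a trial (and optionally a whole cohort) as a plain-text file tree
#'
#' Emits `left.csv`, `right.csv`, `wrist.csv`, the `trial.yaml` sidecar
#' [read_trial()] consumes, and — for synthetic trials — `truth_cop.csv`
#' (time, true ML/AP, phase label) and the true boundaries inside the
#' sidecar. `write_cohort()` writes one directory per trial plus a
#' `manifest.csv` tying participants, conditions, trials, seeds and paths
#' together.
#'
#' @param trial A `coprqa_trial`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) readr::write_csv(x, file.path(dir, f), progress = FALSE)
  wr(round_df(trial$left), "left.csv")
  wr(round_df(trial$right), "right.csv")
  wr(round_df(trial$wrist), "wrist.csv")
  cfg <- list(
    rates = list(plate = trial$rate_plate, kinematic = trial$rate_kin),
    units = list(force = "N", moment = "Nm", marker = "cm"),
    plates = list(
      left = list(file = "left.csv",
                  origin = as.numeric(trial$plate_geom$origin_left),
                  surface_offset = trial$plate_geom$surface_offset),
      right = list(file = "right.csv",
                   origin = as.numeric(trial$plate_geom$origin_right),
                   surface_offset = trial$plate_geom$surface_offset)
    ),
    marker = list(file = "wrist.csv", label = "RWrist"),
    meta = trial$meta
  )
  if (!is.null(trial$truth)) {
    cfg$truth <- list(file = "truth_cop.csv",
                      boundaries = as.integer(trial$truth$boundaries))
    truth <- trial$truth$cop
    truth$phase <- trial$truth$phase
    wr(round_df(truth), "truth_cop.csv")
  }
  yaml::write_yaml(cfg, file.path(dir, "trial.yaml"))
  invisible(dir)
}

# keep emitted text compact without losing measurement-scale precision
round_df <- function(x) {
  x[] <- lapply(x, function(col) if (is.numeric(col)) signif(col, 8) else col)
  x
}

#' @rdname write_trial
#' @param cohort A `coprqa_cohort` from [generate_cohort()].
#' @param out_dir Root output directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$plan))
  for (i in seq_along(cohort$trials)) {
    row <- cohort$plan[i, ]
    rel <- sprintf("p%02d_%s_t%d", row$participant, row$condition, row$trial)
    write_trial(cohort$trials[[i]], file.path(out_dir, rel))
    paths[i] <- rel
  }
  manifest <- cohort$plan
  manifest$path <- paths
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  yaml::write_yaml(list(cohort_seed = cohort$seed,
                        n_participants = max(cohort$plan$participant),
                        n_trials = nrow(cohort$plan)),
                   file.path(out_dir, "cohort.yaml"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
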