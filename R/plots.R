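#' COP trajectory panels
#'
#' Statokinesigram-style panels (AP against ML, equal axis scaling) of one
#' or more COP trajectories, faceted by condition when a `condition` column
#' is present and colored by cycle when a `cycle` column is present.
#'
#' @param cop Tibble with `ml`, `ap` columns (cm) and optional `condition`,
#'   `cycle` columns, e.g. the `cop` element of [run_pipeline()] results
#'   (with `keep_cop = TRUE`) or [process_trial()].
#' @return A ggplot object.
#' @export
plot_cop_trajectories <- function(cop) {
  stopifnot(all(c("ml", "ap") %in% names(cop)))
  p <- ggplot(cop, aes(x = .data$ml, y = .data$ap))
  p <- if ("cycle" %in% names(cop)) {
    p + geom_path(aes(color = factor(.data$cycle)), linewidth = 0.3) +
      labs(color = "cycle")
  } else {
    p + geom_path(linewidth = 0.3, color = "grey30")
  }
  if ("condition" %in% names(cop)) {
    p <- p + facet_wrap(~condition)
  }
  p + coord_fixed() +
    labs(x = "ML (cm)", y = "AP (cm)", title = "COP trajectories") +
    theme_minimal()
}

#' Recurrence-plot raster
#'
#' Renders a binary recurrence matrix as the conventional recurrence map
#' (sample index against sample index, recurrent pairs filled).
#'
#' @param R Logical recurrence matrix from [recurrence_matrix()].
#' @param max_points Cap on rendered recurrent points; larger matrices are
#'   thinned by regular subsampling to keep the figure light.
#' @return A ggplot object.
#' @export
plot_recurrence <- function(R, max_points = 4e5) {
  n <- nrow(R)
  step <- max(1L, ceiling(n / floor(sqrt(max_points / max(mean(R), 1e-3)))))
  idx <- seq(1, n, by = step)
  sub <- R[idx, idx, drop = FALSE]
  pts <- which(sub, arr.ind = TRUE)
  df <- tibble(i = idx[pts[, 1]], j = idx[pts[, 2]])
  ggplot(df, aes(x = .data$j, y = .data$i)) +
    geom_point(shape = 15, size = 0.3) +
    coord_fixed() +
    labs(x = "sample j", y = "sample i", title = "Recurrence plot") +
    theme_minimal()
}

#' Annotated condition boxplots for a comparison result
#'
#' One boxplot per condition, faceted by metric, with the pairwise
#' significance tiers (`*`, `**`, `***`) drawn as brackets above the
#' distributions — the conventional presentation of within-subject
#' condition effects.
#'
#' @param object A `condition_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_comparison <- function(object, ...) {
  data <- object$data
  conds <- unique(as.character(data$condition))
  data$condition <- factor(data$condition, levels = conds)
  p <- ggplot(data, aes(x = .data$condition, y = .data$value)) +
    geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
  pw <- object$pairwise
  if (!is.null(pw) && nrow(pw)) {
    spans <- data %>%
      group_by(.data$metric) %>%
      summarise(top = max(.data$value, na.rm = TRUE),
                rng = diff(range(.data$value, na.rm = TRUE)), .groups = "drop")
    ann <- pw %>%
      filter(.data$tier != "ns") %>%
      left_join(spans, by = "metric") %>%
      group_by(.data$metric) %>%
      mutate(level = dplyr::row_number()) %>%
      ungroup() %>%
      mutate(
        x = match(.data$condition_a, conds),
        xend = match(.data$condition_b, conds),
        y = .data$top + 0.08 * .data$rng * .data$level
      )
    if (nrow(ann)) {
      p <- p +
        geom_segment(data = ann,
                     aes(x = .data$x, xend = .data$xend,
                         y = .data$y, yend = .data$y),
                     inherit.aes = FALSE, linewidth = 0.3) +
        geom_text(data = ann,
                  aes(x = (.data$x + .data$xend) / 2,
                      y = .data$y + 0.02 * .data$rng, label = .data$tier),
                  inherit.aes = FALSE, size = 3, vjust = 0)
    }
  }
  p
}

#' @rdname autoplot.condition_comparison
#' @param x A `condition_comparison`.
#' @param y Unused.
#' @export
plot.condition_comparison <- function(x, y, ...) print(autoplot(x, ...))
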