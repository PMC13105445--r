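#' Shapiro-Wilk normality gate
#'
#' Tests each condition's distribution of a metric for normality. The
#' pipeline proceeds nonparametrically when at least one condition departs
#' from normality at `alpha` (or when the gate cannot run: fewer than 3
#' values, or a degenerate constant sample).
#'
#' @param data Tibble with one value per participant and condition.
#' @param value,condition Column names (strings) of the metric value and the
#'   grouping condition.
#' @param alpha Significance level of the gate.
#' @return A tibble with columns `condition`, `n`, `shapiro_w`, `shapiro_p`,
#'   `normal`, plus an attribute `nonparametric` (TRUE when any condition
#'   fails or the gate is degenerate).
#' @export
normality_gate <- function(data, value = "value", condition = "condition",
                           alpha = 0.05) {
  groups <- split(data[[value]], data[[condition]])
  rows <- purrr::imap_dfr(groups, function(x, nm) {
    x <- x[is.finite(x)]
    if (length(x) < 3) {
      warning("condition ", nm, ": fewer than 3 values, normality gate ",
              "skipped; nonparametric path forced", call. = FALSE)
      return(tibble(condition = nm, n = length(x), shapiro_w = NA_real_,
                    shapiro_p = NA_real_, normal = FALSE))
    }
    if (diff(range(x)) == 0) {
      return(tibble(condition = nm, n = length(x), shapiro_w = NA_real_,
                    shapiro_p = NA_real_, normal = FALSE))
    }
    sw <- shapiro.test(x)
    tibble(condition = nm, n = length(x),
           shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
           normal = sw$p.value >= alpha)
  })
  attr(rows, "nonparametric") <- any(!rows$normal)
  rows
}

#' Friedman omnibus test across conditions
#'
#' Within-subject (complete randomized block) rank test of a metric across
#' the experimental conditions, via [stats::friedman.test()] (mid-ranks for
#' ties). Participants with missing cells are excluded with a warning.
#'
#' @param data Long tibble with columns for participant, condition and
#'   value.
#' @param value,participant,condition Column names (strings).
#' @return A one-row tibble: `statistic` (chi-squared), `df`, `p_value`,
#'   `n` (participants used), `k` (conditions).
#' @export
friedman_conditions <- function(data, value = "value",
                                participant = "participant",
                                condition = "condition") {
  wide <- tidyr::pivot_wider(
    data[, c(participant, condition, value)],
    names_from = all_of(condition), values_from = all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) with missing cells excluded ",
            "from the Friedman test", call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("Friedman test needs >= 2 complete participants and >= 2 conditions",
         call. = FALSE)
  }
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # every block fully tied: no rank variation at all, hence no effect
    stat <- 0
    p <- 1
  }
  tibble(statistic = stat, df = unname(ft$parameter),
         p_value = p, n = nrow(m), k = ncol(m))
}

#' Paired Wilcoxon comparison with a standardized Z
#'
#' Pairwise comparison between two conditions measured on the same
#' participants. The default is the Wilcoxon signed-rank test on the paired
#' differences: zero differences are dropped, absolute differences are
#' mid-ranked, `W` is the sum of the ranks of the positive differences, and
#' \deqn{Z = \frac{W - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3-t)/48}}}
#' (normal approximation, no continuity correction; the tie term vanishes
#' for untied data). The two-sided p-value comes from the standard normal.
#' A rank-sum (Mann-Whitney) variant, which ignores the pairing, is also
#' available because published reports sometimes name it for within-subject
#' designs; the signed-rank default is the appropriate paired test.
#'
#' @param a,b Paired numeric vectors (condition A and condition B per
#'   participant). Differences are `a - b`.
#' @param method `"signed_rank"` (default) or `"rank_sum"`.
#' @param exact Use the exact signed-rank distribution for the p-value
#'   instead of the normal approximation (requires no ties or zeros; `Z` is
#'   still reported).
#' @return A one-row tibble: `method`, `n` (nonzero pairs used),
#'   `statistic` (W), `z`, `p_value`.
#' @export
wilcoxon_paired <- function(a, b, method = c("signed_rank", "rank_sum"),
                            exact = FALSE) {
  method <- match.arg(method)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (method == "rank_sum") {
    rk <- rank(c(a, b))
    n1 <- length(a); n2 <- length(b)
    w <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
    mu <- n1 * n2 / 2
    tie_tab <- table(rk)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (w - mu) / sqrt(sigma2)
    return(tibble(method = method, n = n1, statistic = w, z = z,
                  p_value = 2 * pnorm(-abs(z))))
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(method = method, n = 0L, statistic = NA_real_,
                  z = NA_real_, p_value = NA_real_))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else NA_real_
  p <- if (exact) {
    stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  } else if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  tibble(method = method, n = n, statistic = w, z = z, p_value = p)
}

#' Effect size r from a standardized test statistic
#'
#' `r = |Z| / sqrt(n)` with `n` the number of participants in the
#' within-subject comparison. Classified by the conventional thresholds:
#' 0.1-0.3 small, 0.3-0.5 medium, above 0.5 large.
#'
#' @param z Standardized statistic.
#' @param n Number of participants.
#' @return Numeric effect size (see also [effect_magnitude()]).
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n > 0)
  abs(z) / sqrt(n)
}

#' @rdname effect_size_r
#' @param r Effect size from [effect_size_r()].
#' @export
effect_magnitude <- function(r) {
  cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = TRUE) |> as.character()
}

#' Significance tier glyphs
#'
#' Maps p-values to the conventional `*` (p < .05), `**` (p < .01),
#' `***` (p < .001) tiers, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Within-subject comparison of metrics across conditions
#'
#' Runs the full inferential chain for each metric: Shapiro-Wilk normality
#' gate, Friedman omnibus test across the conditions, and — only when the
#' omnibus is significant at `alpha` — pairwise Wilcoxon comparisons with
#' standardized `Z`, effect size `r = |Z|/sqrt(n)` and significance tiers.
#' No multiple-testing correction is applied to the pairwise tests; they are
#' gated by the omnibus.
#'
#' @param data Long tibble with columns `participant`, `condition`,
#'   `metric`, `value` (one row per participant x condition x metric, e.g.
#'   from [aggregate_sway()]).
#' @param alpha Significance level for the omnibus gate and the tiers.
#' @param pairwise_method Passed to [wilcoxon_paired()].
#' @return An object of class `condition_comparison` with components
#'   `omnibus`, `pairwise`, `normality` (tibbles), `alpha`, `n`. Use
#'   [tidy()][generics::tidy()] for the pairwise table,
#'   [glance()][generics::glance()] for the omnibus table, and
#'   [autoplot()][ggplot2::autoplot()] for annotated boxplots.
#' @export
compare_conditions <- function(data, alpha = 0.05,
                               pairwise_method = "signed_rank") {
  stopifnot(all(c("participant", "condition", "metric", "value") %in%
                names(data)))
  metrics <- unique(data$metric)
  conds <- unique(as.character(data$condition))
  normality <- purrr::map_dfr(metrics, function(mt) {
    d <- data[data$metric == mt, ]
    g <- normality_gate(d, "value", "condition", alpha)
    tibble::add_column(g, metric = mt, .before = 1)
  })
  omnibus <- purrr::map_dfr(metrics, function(mt) {
    d <- data[data$metric == mt, ]
    res <- friedman_conditions(d)
    tibble::add_column(res, metric = mt, .before = 1)
  })
  omnibus$tier <- significance_tier(omnibus$p_value)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(metrics, function(mt) {
    if (omnibus$p_value[omnibus$metric == mt] >= alpha) return(tibble())
    d <- data[data$metric == mt, ]
    wide <- tidyr::pivot_wider(d[, c("participant", "condition", "value")],
                               names_from = "condition",
                               values_from = "value")
    purrr::map_dfr(pairs, function(pr) {
      w <- wilcoxon_paired(wide[[pr[1]]], wide[[pr[2]]],
                           method = pairwise_method)
      n_part <- sum(is.finite(wide[[pr[1]]]) & is.finite(wide[[pr[2]]]))
      r <- effect_size_r(w$z, n_part)
      tibble(metric = mt, condition_a = pr[1], condition_b = pr[2],
             n = n_part, statistic = w$statistic, z = w$z,
             p_value = w$p_value, r = r,
             magnitude = effect_magnitude(r),
             tier = significance_tier(w$p_value))
    })
  })
  structure(
    list(omnibus = omnibus, pairwise = pairwise, normality = normality,
         alpha = alpha, n = length(unique(data$participant)),
         data = as_tibble(data)),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Within-subject condition comparison (n = ", x$n, " participants)\n",
      sep = "")
  cat("\nFriedman omnibus:\n")
  print(x$omnibus, n = Inf)
  if (nrow(x$pairwise)) {
    cat("\nPairwise Wilcoxon (gated by omnibus p < ", x$alpha, "):\n",
        sep = "")
    print(x$pairwise, n = Inf)
  } else {
    cat("\nNo metric passed the omnibus gate; no pairwise comparisons.\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparison table
#'
#' @param x A `condition_comparison` object.
#' @param ... Unused.
#' @return Tibble of pairwise Wilcoxon results (one row per metric and
#'   condition pair) with `z`, `p_value`, effect size `r` and tier.
#' @exportS3Method generics::tidy
tidy.condition_comparison <- function(x, ...) x$pairwise

#' One-row-per-metric omnibus summary
#'
#' @inheritParams tidy.condition_comparison
#' @return Tibble of Friedman omnibus results per metric.
#' @exportS3Method generics::glance
glance.condition_comparison <- function(x, ...) x$omnibus
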