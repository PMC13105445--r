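# coprqa

Center-of-pressure (COP) posturography and recurrence quantification for
cyclic manipulation tasks performed standing — in particular, tasks shared
with a collaborative robot, where the ergonomic question is whether the
robot's presence degrades the worker's postural control.

The package is aimed at movement scientists and ergonomists who have (or
want to simulate) per-trial recordings of two 6-component force platforms
plus a wrist marker trajectory, and who want the full within-subject
analysis chain:

1. **COP extraction** — per-plate COP from the plate kinetics
   `COP_x = (−M_y − F_x h)/F_z + x_0`, `COP_y = (M_x − F_y h)/F_z + y_0`,
   total COP as the load-weighted average of the two plates, zero-phase
   anti-aliased resampling to the kinematic rate.
2. **Cycle segmentation** — task repetitions from the prominent rightward
   maxima of the wrist ML trace; manipulation phases isolated by a
   threshold rule on the wrist excursion (rest, pick-up and release
   excluded).
3. **Linear sway metrics** per manipulation cycle — mean distance (cm),
   mean velocity (cm/s), 95% confidence-ellipse area
   `π · χ²₂,.95 · √(λ₁λ₂)` (cm²), and sway area (cm²/s).
4. **Recurrence quantification** — cycle-length time-delay embedding of the
   radial, AP and ML COP components; REC (recurrence rate), DET
   (determinism) and RATIO = DET/REC from the recurrence matrix
   `R_ij = [d(v_i, v_j) ≤ ε]`.
5. **Within-subject statistics** — Shapiro-Wilk normality gate, Friedman
   omnibus across conditions, pairwise Wilcoxon signed-rank tests
   (normal approximation, no continuity correction) with effect sizes
   `r = |Z|/√n` and `*`/`**`/`***` significance tiers.
6. **Synthetic cohorts** — a seeded generator that emits raw plate/marker
   recordings with ground-truth COP, boundaries and phase labels for the
   study design (14 participants × 3 conditions × 3 trials × 5
   repetitions), so the whole chain is testable end to end.

Everything is tidyverse-shaped: functions take data frames and return
tibbles, fitted comparison objects support `tidy()`, `glance()` and
`autoplot()`, and the pipeline writes plain CSV/YAML artifacts.

## Worked example

Simulate a cohort at the study's design size, run the linear-metrics
pipeline and inspect the statistics:

```r
library(coprqa)

run <- run_pipeline(seed = 42, n_participants = 14,
                    config = coprqa_config(rqa = NULL))
glance(run$stats_sway)
#> # A tibble: 4 × 7
#>   metric        statistic    df   p_value     n     k tier
#>   <chr>             <dbl> <dbl>     <dbl> <int> <int> <chr>
#> 1 area_ce_cm2        22.3     2 0.0000145    14     3 ***
#> 2 area_sw_cm2_s      21.1     2 0.0000256    14     3 ***
#> 3 mdist_cm           21.1     2 0.0000256    14     3 ***
#> 4 mvelo_cm_s         21.6     2 0.0000207    14     3 ***

tidy(run$stats_sway)[, c("metric", "condition_a", "condition_b",
                         "z", "p_value", "r", "tier")]
#> # A tibble: 12 × 7
#>    metric        condition_a condition_b      z  p_value     r tier
#>  1 area_ce_cm2   Free        RF          -3.30  0.000982 0.881 ***
#>  2 area_ce_cm2   Free        RP          -3.30  0.000982 0.881 ***
#>  3 area_ce_cm2   RF          RP           1.22  0.221    0.327 ns
#>  4 area_sw_cm2_s Free        RF          -3.30  0.000982 0.881 ***
#>  5 area_sw_cm2_s Free        RP          -3.30  0.000982 0.881 ***
#>  6 area_sw_cm2_s RF          RP           0.910 0.363    0.243 ns
#>  7 mdist_cm      Free        RF          -3.30  0.000982 0.881 ***
#>  8 mdist_cm      Free        RP          -3.30  0.000982 0.881 ***
#>  9 mdist_cm      RF          RP           1.16  0.245    0.310 ns
#> 10 mvelo_cm_s    Free        RF          -3.30  0.000982 0.881 ***
#> 11 mvelo_cm_s    Free        RP          -3.30  0.000982 0.881 ***
#> 12 mvelo_cm_s    RF          RP           2.23  0.0258   0.596 *
```

Reading the output: every sway metric is higher under robotic assistance
than in free execution (Friedman `***`, pairwise Free-vs-robot `***` with
the ceiling effect size r = 0.88 at n = 14), while the two robot conditions
share one sway distribution by construction — their comparisons are
non-significant up to ordinary type-I flukes (the lone `*` above at
p = .026 is one such fluke across 12 comparisons).

Recurrence analysis of a single trial:

```r
tr <- generate_trial(default_presets()$Free, seed = 1)
process_trial(tr)$rqa[, c("component", "rec", "det", "ratio", "m", "tau")]
#> # A tibble: 3 × 6
#>   component    rec   det ratio     m   tau
#> 1 APML      0.0682 0.998 14.6      2   509
#> 2 AP        0.148  1.000  6.76     2   509
#> 3 ML        0.149  0.999  6.68     2   509
```

Determinism near 1 with a much smaller recurrence rate is the signature of
quasi-periodic, structured sway: states recur rarely, but when they do they
recur in extended diagonal stretches. Add `out_dir = "results/"` to
`run_pipeline()` to get `sway.csv`, `rqa.csv`, `stats.csv`, a markdown
report, annotated boxplots and a config snapshot; `autoplot()` on the stats
objects and `plot_cop_trajectories()` / `plot_recurrence()` render the
standard figures. A thin CLI over the same functions lives at
`inst/scripts/coprqa.R` (`synth` and `run` subcommands).

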