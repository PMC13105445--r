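---
title: "Postural-control analysis for human-robot collaborative manipulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postural-control analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coprqa` implements a complete posturographic analysis chain for cyclic
manipulation tasks performed standing, with or without assistance from a
collaborative robot: force-plate channels are turned into a center-of-pressure
(COP) trajectory, task repetitions are segmented from a wrist marker, and the
manipulation phases are summarized by four linear sway statistics and by
recurrence quantification analysis (RQA), followed by within-subject
nonparametric statistics across the three experimental conditions (`Free`,
`RF` — robot free, `RP` — robot constrained to a horizontal plane). A seeded
synthetic-cohort generator with ground-truth labels makes every stage testable
without access to raw laboratory recordings.

## From plate channels to the total COP

Each 6-component platform reports forces $(F_x, F_y, F_z)$ in N and moments
$(M_x, M_y, M_z)$ in N·m at 500 Hz. With $h$ the vertical offset between the
plate origin and its top surface, the COP under that foot is

$$COP_x = \frac{-M_y - F_x h}{F_z} + x_0, \qquad
  COP_y = \frac{M_x - F_y h}{F_z} + y_0,$$

expressed in cm in a lab frame whose origin lies midway between the plates
(ML = x, rightward positive; AP = y, forward positive). Samples with
$|F_z| < f_{z,\min}$ (default **20 N**) are flagged invalid rather than
divided through: near-zero vertical load makes the quotient meaningless, and
20 N is a conventional guard for an essentially unloaded foot.

The total COP is the average of the two per-plate COPs weighted by the
instantaneous vertical force on each plate (clamped at zero). The weighting
variable is a design choice — the physically correct combination, since the
resultant ground-reaction point divides the segment between the per-foot COPs
in proportion to the vertical loads. During single support the total COP
equals the loaded plate's COP exactly; samples where neither plate is loaded
are invalid.

Force data are then resampled to the kinematic rate (500 → 250 Hz) by
zero-phase low-pass filtering and decimation. The filter is a 4th-order
Butterworth at $0.4 \times$ the target rate applied forward and backward
(after reflecting the series at both ends to suppress edge transients):
one-directional filtering would introduce a phase lag that biases the
velocity-based sway metrics. Only integer decimation is supported; validity
flags are reduced blockwise with "all".

## Cycle segmentation

A repetition of the manipulation task ends when the right wrist reaches its
maximum rightward (ML) excursion — the hand returning the object to its
station. Boundaries are therefore the prominent local maxima of the wrist ML
trace, found in two passes:

1. all local maxima with topographic prominence of at least 10% of the trace
   range (plateaus contribute their central sample);
2. a minimum inter-peak distance of 50% of the median first-pass spacing,
   keeping the more prominent peak of any close pair.

This is robust to marker noise without assuming a fixed cycle duration.
Fewer boundaries than expected produce a warning with a partial result; none
at all is a segmentation failure.

Within each cycle (previous boundary to current boundary), only the
*manipulation* phase is analyzed; rest, object pick-up and object release are
excluded. How exactly the original analysis delimited manipulation onset and
offset is not documented, so the package uses a declared heuristic: the
longest contiguous run where the wrist ML coordinate is left of

$$\theta = ML_{rest} - c\,(ML_{rest} - ML_{\min}), \qquad c = 0.8,$$

i.e. the hand has covered at least 80% of its excursion from the rest/grasp
station toward its leftmost point. $ML_{rest}$ is estimated as the 85th
percentile of the trace (robust to a brief rightward overshoot at
completion), making the rule invariant to constant offsets of the marker
frame. The heuristic is validated against the generator's ground-truth phase
labels (at default noise, at least 95% of extracted samples are true
manipulation samples); when annotation files exist, they override it.

## Linear sway metrics

For each manipulation segment, with centroid-centered coordinates
$(x_n, y_n)$, $N$ samples spanning $T$ seconds:

* **mean distance** $\frac{1}{N}\sum_n \sqrt{x_n^2 + y_n^2}$ (cm) — extent of
  displacement;
* **mean velocity** — summed chord lengths divided by $T$ (cm/s) — speed of
  postural adjustment;
* **95% confidence-ellipse area**
  $\pi\,\chi^2_{2,.95}\sqrt{\lambda_1\lambda_2}$ with $\lambda_i$ the
  eigenvalues of the sample covariance (cm²) — spread with directionality;
* **sway area** $\frac{1}{2T}\sum_n |x_{n+1} y_n - x_n y_{n+1}|$ (cm²/s) —
  area swept by the centroid-to-COP vector per unit time.

Numerical choices: the ellipse uses the large-sample $\chi^2$ quantile
(5.991) rather than the small-sample F form — manipulation cycles contain
hundreds of samples at 250 Hz, where the two differ by well under 1%; a
rank-deficient covariance (collinear sway) returns area 0 with a warning;
invalid samples are dropped for the distribution-based metrics, while the
path-based metrics skip chords across gaps and reduce the duration
accordingly, so gaps never fabricate excursions. Metrics are computed per
cycle (centering on the cycle's own centroid, consistent with per-cycle
computation), averaged over cycles within a trial, then over the three
trials within a condition: one value per participant × condition × metric.

## Recurrence quantification

RQA is run on the concatenated manipulation samples of each trial (per-cycle
series would be shorter than the delay), on three scalar components: the
radial distance from the series centroid (`APML`), and the AP and ML
coordinates alone. Each component is delay-embedded,
$v_i = (s_i, s_{i+\tau}, \dots, s_{i+(m-1)\tau})$, and the binary recurrence
matrix $R_{ij} = [\,d(v_i, v_j) \le \varepsilon\,]$ computed. Reported
measures:

* **REC** — fraction of recurrent pairs among admissible pairs
  ($|i-j| > $ Theiler window);
* **DET** — fraction of admissible recurrent points lying on diagonal lines
  of length $\ge \ell_{\min}$;
* **RATIO** — DET/REC, the extent to which recurrences are deterministic.

Defaults and their rationale (all configurable via `rqa_config()`):

| parameter | default | rationale |
|---|---|---|
| delay $\tau$ | mean manipulation-interval length of the trial | anchors the embedding to the task's own cycle time scale |
| dimension $m$ | 2 | the lowest dimension consistent with a cycle-structured planar signal and with near-unity determinism |
| radius $\varepsilon$ | 10% of the maximal phase-space distance | fraction-of-diameter convention makes trials of different amplitude comparable; absolute radii (cm) also accepted |
| $\ell_{\min}$ | 2 | shortest run that is a line rather than a point |
| Theiler window | 0 (main diagonal only) | the identity line carries no dynamical information; it is excluded from numerator and denominator |
| norm | Euclidean | conventional for planar COP embeddings |

These conventions are package choices, not published settings. The
implementation is verified exactly against a brute-force $O(N^2)$ pairwise
scan and an explicit diagonal-by-diagonal run histogram on random series.
One finite-size subtlety: on an all-ones admissible region DET is slightly
below 1, because the single-point corner diagonals of a finite matrix cannot
reach $\ell_{\min} = 2$.

## Statistics

Per metric: a Shapiro-Wilk gate per condition (any departure at
$\alpha = .05$, or a degenerate sample, routes the analysis down the
nonparametric path — for this protocol's metrics that path is always taken in
practice); a Friedman omnibus test across the three conditions
(`stats::friedman.test`, mid-ranks, with the fully-tied degenerate case
mapped to $\chi^2 = 0$, $p = 1$); and, only when the omnibus is significant,
the three pairwise Wilcoxon comparisons. The pairwise test is the **paired
signed-rank** test: zero differences dropped, mid-ranked absolute
differences, $W$ the positive-rank sum, and

$$Z = \frac{W - n(n+1)/4}
          {\sqrt{n(n+1)(2n+1)/24 - \textstyle\sum(t^3-t)/48}}$$

— the normal approximation without continuity correction (the tie term
vanishes for untied data). Effect sizes are $r = |Z|/\sqrt{n}$ with $n$ the
number of participants, classified small/medium/large at 0.1/0.3/0.5, and
$p$-values are tiered `*`, `**`, `***` at .05/.01/.001. No multiple-testing
correction is applied beyond the omnibus gate. A rank-sum (Mann-Whitney)
variant is exposed as well, because within-subject reports occasionally name
it; for a paired design the signed-rank default is the appropriate test, and
at $n = 14$ it is the one whose maximal-$Z$ configuration yields the
published ceiling effect size $3.296/\sqrt{14} = 0.88$. Exact small-sample
p-values are available via `exact = TRUE`.

## The synthetic cohort

The generator emulates the study's design — 14 participants × 3 conditions ×
3 trials × 5 repetitions — with known ground truth, so segmentation accuracy,
phase purity and effect recovery can be measured, not assumed. Per trial:

* **cycle structure**: 0.5 s lead-in, then 5 cycles of mean period 3 s
  (lognormal jitter, sd 5%), each split rest/reach/manipulation/return with
  65% manipulation. The 3 s desk-scale period keeps a full cohort cheap to
  simulate; it compresses real task time, so speed-type metrics (mean
  velocity, sway area) run proportionally higher than published group means
  while extent-type metrics and all effect directions are preserved.
* **true COP**: per cycle, a smooth closed loop — forward-leaning,
  AP-dominant with a thin ML width — scaled by per-cycle lognormal amplitude
  jitter (sd 8%) and per-participant lognormal sway multipliers (sd 25%);
  cycle centers get random AP/ML offsets so whole-trial traces fill the
  condition's target ranges; a stationary band-limited Gaussian drift
  (sd 0.25 cm, 0-1 Hz, realized by Fourier synthesis) rides underneath; the
  COP collapses to the baseline point during rest.
* **condition presets**: `Free` targets roughly 5 cm trial ranges in both
  axes; `RF`/`RP` target 15 and 10 cm AP ranges. The two robot presets share
  identical per-cycle loop amplitudes and differ only in trial-level AP
  spread, which per-cycle metrics ignore — encoding the finding that the two
  robot-assisted modes did not differ in per-cycle sway. Loop amplitudes
  (4.6/0.5 cm for Free, 6.35/1.2 cm for the robot presets) were calibrated
  once so cohort means land near the published group means (Free mean
  distance ≈ 1.7 cm, robot ≈ 2.3-2.4 cm; ellipse areas ≈ 8 vs ≈ 23 cm²).
* **raw channels**: plate channels are synthesized by exact inversion of the
  plate kinetics for a body weight drawn per participant (normal,
  71 ± 7 kg), split across the plates with a load share that follows the ML
  COP; recomputing the COP from the emitted channels reproduces the truth to
  numerical precision (`1e-6` cm). The wrist ML trace rests at +40 cm,
  sweeps to 0 during manipulation, and carries a sharp 6 cm rightward
  overshoot at each completion — giving every repetition boundary a unique,
  high-prominence peak, as a natural deposit-and-release overshoot would.
* **seeding**: one cohort seed drives everything; the plan
  (`cohort_plan()`) draws participant effects and one sub-seed per trial, so
  trials are pure functions of `(preset, sub-seed, effects)` and a cohort is
  bitwise reproducible.

What the generator does *not* emulate: multi-segment body dynamics, robot
contact forces, EMG-level muscle activity, marker occlusions, or
participant-specific postural strategies. Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it is pointed at — not
that it would be free of artifacts on arbitrary laboratory data.

## Problem sizes used in validation

The validation suite runs cohort-recovery studies at the full design size
(14 × 3 × 3) over 200 cohort seeds for the effect-direction and
null-recovery checks, 10⁴ replicates for the type-I calibration of the
Friedman and signed-rank tests, 100 random series (N ≤ 200) for exact
brute-force RQA equivalence, and 10⁵-sample draws for the confidence-ellipse
Monte-Carlo oracle. These sizes were chosen to keep the whole suite
desk-scale while leaving the binomial margins of the recovery checks
comfortable.

## Known limitations

* The manipulation-phase heuristic and every RQA convention above are
  package decisions where the original processing is underdocumented; all
  are configurable, and conclusions that hinge on them should be checked
  across settings.
* The Friedman statistic from `stats::friedman.test` applies the standard
  tie correction; with heavily tied data it differs from the uncorrected
  classic formula (continuous posturographic metrics are effectively
  untied).
* C3D ingestion is not provided; recordings enter as delimited text with a
  YAML sidecar (`read_trial()`), the format `write_cohort()` emits.
* Polyphase (non-integer) resampling is out of scope.
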