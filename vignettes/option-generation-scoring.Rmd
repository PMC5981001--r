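---
title: "Scoring option generation: fluency, uniqueness and diversity of drawn paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring option generation: fluency, uniqueness and diversity of drawn paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and its measures

In the option-generation drawing task a participant is shown two circles on
a touchscreen — a start circle at the bottom and a goal circle 204 mm above
it (13 mm radius each) — and is asked to draw, within a 240 s budget, as
many *different* paths from the bottom circle to the top circle as they
can. A path counts as valid when it starts and ends within 21 mm of the
respective circle centers (read inclusively: exactly 21 mm is valid).
Three session-level measures summarize performance:

* **fluency** — the number of valid paths produced within the budget;
* **uniqueness** — how unusual each path is, scored as its distance to the
  most similar other path in a pooled corpus;
* **diversity (exploration area)** — how widely one session's paths spread
  over the space of possible shapes.

`optiongen` implements the full measurement chain for these quantities,
the statistical analyses built on them, and a synthetic-cohort generator
that gives every stage a known ground truth.

## From raw trajectories to a path distance

**Arc-length resampling.** A raw path is an ordered set of timestamped
touch samples. We compute the cumulative arc length
\(s(t_k) = \sum_{\tau \le k} \lVert (x_\tau, y_\tau) - (x_{\tau-1}, y_{\tau-1}) \rVert\)
(after removing consecutive duplicate samples, which touchscreens emit)
and linearly interpolate the coordinates at 200 equally spaced arc lengths
\(kL/199\). Timestamps never enter this step, so the representation is
bit-identical whether the same shape was drawn quickly or slowly — speed
information lives in the separate per-path duration
(\(t_\text{last} - t_\text{first}\)). Resampling an already-resampled
polyline moves coordinates only through the second-order chord-versus-arc
bias; at 200 points this is of order \(10^{-5}\) of the path length for
realistic curvatures and shrinks roughly quadratically with the grid, which
is how the suite tests it.

**Features.** Each path becomes the 480-value vector
\(v = [h_x, h_y, \dot h_x, \dot h_y, \ddot h_x, \ddot h_y]\):
the 200 resampled x and y coordinates, then the first and second discrete
derivatives along the path, bin-averaged over 10 consecutive resampled
indices (20 values per component). After resampling, one index step *is*
one arc-length unit, which is the reading we adopt for "bins of 10 distance
units". The discrete derivative has 199 natural values; we replicate the
first (\(\dot h(1) = \dot h(2)\)) so every component keeps 200 values and
bins evenly. We chose replicate over zero padding because it preserves the
two properties one wants on straight segments — constant first derivative
and exactly zero second derivative — where zero padding injects a spurious
curvature spike into the first bin. Derivatives enter in raw resampled
units (`derivative_weight = 1`); the weight is exposed for sensitivity
analysis because no reweighting of the 80 derivative values against the
400 position values is part of the method's definition.

**Mirror-min distance.** The dissimilarity between paths \(i\) and \(j\)
is
\[
d_{ij} = \min\left( \lVert v_i - v_j \rVert_p,\;
                    \lVert v_i - v'_j \rVert_p \right),
\]
where \(v'_j\) is the feature vector of path \(j\) reflected left–right
about the vertical line through the two circle centers (x-coordinates
reflected, x-derivatives negated). We reflect about the inter-circle axis
rather than the screen midline; the two coincide when the circles are
horizontally centered, and the axis version is the one that stays correct
when they are not. The reflection is norm-preserving, so \(d\) is
symmetric; because of the minimum it need not satisfy the triangle
inequality, which the embedding stage tolerates by design. The norm order
\(p\) is 2 by default with 1 and 3 available; on diverse synthetic corpora
the uniqueness rankings under the three norms correlate above 0.99, the
package's stand-in for a norm-robustness check that can only be run
properly on human data.

**Uniqueness.** A path's score is its nearest-neighbour distance
\(u_i = \min_{j \ne i} d_{ij}\) over the *whole pooled corpus* — all
participants and sessions loaded, never within-participant
(`combine_cohorts()` reproduces multi-study pooling). Exact duplicates and
exact mirror duplicates score 0, and enlarging the corpus can only lower
an existing score. The achieved neighbour is recorded for audit. Ties in
the minimum are broken by first index; they are measure-zero for
continuous data and unremarkable when they occur.

The distance kernel is a small C++ routine that evaluates, for each pair,
the direct distance and both cross-mirror distances, keeping the smallest.
Evaluating both cross terms costs half as much again but makes the matrix
exactly symmetric and guarantees an exact zero for a mirror duplicate
whichever member of the pair was stored mirrored; elementwise evaluation
(rather than a Gram-matrix expansion) avoids catastrophic cancellation for
near-duplicate paths.

## Diversity: embedding and hull area

Each session's valid paths are embedded in 2-D by metric multidimensional
scaling: minimize the normalized stress
\[
\sigma(X) = \frac{\sum_{i<j} (\delta_{ij} - d_{ij})^2}{\sum_{i<j} d_{ij}^2},
\qquad \delta_{ij} = \lVert X_i - X_j \rVert_2,
\]
by iterative majorization (the Guttman transform), starting from classical
scaling plus three seeded random restarts and keeping the best. Stress
decreases monotonically across iterations (asserted in the tests);
iteration stops when the improvement falls below `1e-8` or after 512
iterations, both configurable. Exactly Euclidean-embeddable inputs are
recovered at numerically zero stress directly from the classical start.
The specific algorithm is this package's choice — the numerical internals
of the original analysis tool are not published — so coordinate-level
agreement with any other implementation is not a meaningful target; only
stress quality and isometry-invariant summaries are.

Exploration area is the convex-hull area of the embedded points (hull plus
shoelace). The embedding is unique only up to rotation, reflection and
translation, and the hull area is invariant under exactly that group, so
the indeterminacy cannot leak into the measure. Sessions with fewer than 3
distinct points (or collinear ones) get area 0 with a warning rather than
an error: diversity is undefined but reportable. No normalization by path
count is applied — fluency and diversity are deliberately separate
measures.

## Statistics

* `correlate()` / `partial_correlate()` — Pearson or Spearman association,
  and its partial version via regression residuals (used to show, e.g.,
  that a fluency–motivation association survives regressing out baseline
  drawing speed). A variable fully explained by the controls yields a
  partial correlation of 0 with p = 1 rather than an error.
* `compare_correlations()` — two correlations sharing a variable on the
  same subjects are compared with the Fisher-transform z test for
  dependent overlapping correlations in the Meng–Rosenthal–Rubin (1992)
  formulation; the naive independent-samples Fisher z is available behind
  `dependent = FALSE` for sensitivity. The dependent version is the
  defensible default because the compared correlations share a variable.
* `paired_compare()` — two-sided paired t test between the two conditions
  of a crossover, with an automatic log transform when a Shapiro–Wilk
  pre-check (alpha = 0.05) fails on either condition and all values are
  positive; the decision is recorded in the output. Zero-variance
  differences are flagged with the exact mean difference instead of an
  infinite statistic.
* `tradeoff_mixed_model()` — because fluency and uniqueness trade off, a
  condition's raw effect on uniqueness mixes "paths were faster" with
  "paths were more unusual". The trial-level model
  `uniqueness ~ duration + condition (+ apathy + condition:apathy) +
  (1 | participant)` (lmerTest, Satterthwaite df) conditions on each
  path's duration, exposing the condition contrast at fixed duration
  directly. The random structure is an intercept per participant — the
  smallest structure supporting the within-subject design; random slopes
  are deliberately not fitted by default because the reference analysis
  does not state them and small cohorts rarely identify them.
* `motivation_glm()` — ordinary least squares of the motivation score on
  fluency, mean uniqueness and hull area jointly (a Gaussian GLM), asking
  which correlated measure carries independent information. Predictors are
  not standardized.

Bayes factors are not computed: they are not part of this package's
contribution and no installed routine matches the defaults of the tool
they are usually quoted from.

## The synthetic cohort generator

Human data for this task are not publicly deposited, so the generator is a
first-class, tested module rather than a fixture. One agent draws paths as
composite cubic splines from the start to the goal circle through three
interior control points, laterally offset from the straight chord by draws
with agent-specific scale \(\sigma\) (the mirror side is a fair coin per
path). Timestamps are assigned at constant arc speed; an optional lateral
tremor sinusoid (default 4 Hz) can be superimposed, and `add_tremor()` can
inject it into any existing cohort for controlled comparisons.

The uniqueness–fluency trade-off is generated *mechanically*, not painted
onto summary statistics: each path costs
\(L/\text{speed} + c \cdot \text{(dispersion draw)}\) seconds against the
240 s budget (default cost \(c = 0.35\) s/mm, 1.5 s jittered gaps between
paths, 60 Hz sampling), so agents who draw more unusual paths necessarily
produce fewer of them. Population defaults — 96 agents, log-normal
dispersion with median 12 mm and log-SD 0.5, log-normal speed with median
130 mm/s and log-SD 0.25 — were chosen once as plausible magnitudes for
drawing on a 23-inch screen and produce fluencies of roughly 20–60 paths
per session, the range one expects from healthy adults on this task. A
latent motivation factor loads negatively on log dispersion (0.6) and
positively on log speed (0.4), so motivated agents are fluent while
apathetic agents produce fewer, more unusual paths; the factor is exported
as the `motivation`/`apathy` covariates.

A condition (ON/drug) acts through three orthogonal knobs: a speed
multiplier (default 1.25), a dispersion multiplier (default 0.75), and a
`free_uniqueness` factor (default 1.3) that divides the *time cost* of
dispersion without changing the shapes themselves — raising the
uniqueness attainable at a fixed path duration. The three knobs exist so
the pipeline's central claim — that the mixed model separates the
trade-off from a residual condition effect at fixed duration — is testable
by construction: the first two knobs move fluency and mean uniqueness in
opposite directions, and only the third should surface in the
fixed-duration contrast.

Control tasks are emulated to their stated designs: exactly ten
near-straight lines for motor execution; straight lines to targets cued
one at a time at the task distance and a uniform random angle within ±90°
of vertical under a 90 s budget; and self-chosen straight lines to 24
equally spaced arc targets, also under 90 s.

**What the generator does not emulate.** Spline-sampled paths are smoother
and more stationary than human strokes: there is no motor noise model, no
minimum-jerk or Fitts-law kinematics, no learning, fatigue or
working-memory influence across the session, and condition effects are
homogeneous across agents with no session-level (day-to-day) variability.
Consequences worth keeping in mind: passing tests demonstrate that the
*pipeline* measures what it claims on data with known structure, not that
human cohorts behave this way; and test statistics on synthetic crossovers
are much larger than those from human cohorts of the same size, because
the only noise is path-to-path draw variation. Signs and orderings are the
desk-reproducible surface; magnitudes of t statistics are not.

## Numerical and edge-case policy

* Consecutive duplicate samples are removed before arc-length work; paths
  with fewer than 2 samples, non-monotonic timestamps, or zero length are
  rejected at validation with their path ids and row numbers, never
  silently dropped. Invalid paths stay in the data model, flagged, and are
  excluded from metrics.
* "Within 21 mm" is inclusive. Validity is always judged on the raw
  trajectory; smoothing happens afterwards. For the cued-action and
  option-selection tasks only the start-side check applies, since those
  paths end at targets.
* The tremor-control smoothing is a centered, *time-based* moving average
  (±125 ms, truncated at the ends), so it behaves identically under
  irregular sampling; a 250 ms boxcar has its spectral null exactly at
  4 Hz. In the tremor analysis the smoothing is applied to every
  trajectory before scoring — clean baseline included — mirroring how such
  control analyses preprocess all raw data uniformly; the truncated end
  windows pass a little residual tremor, which is why the uniform
  comparison is the right one.
* Mirroring carries its pre-image, so mirroring twice returns the original
  bit-for-bit; double reflection re-derived arithmetically would be exact
  only to the last ulp.
* CSV round-trips use readr's shortest round-trip numeric formatting; two
  writes of the same cohort are byte-identical.
* One master seed determines every stochastic choice (population draws,
  path draws, embedding restarts); per-session embedding seeds are derived
  as `seed + k`.

## Problem sizes

The test-suite and acceptance-script runs use cohorts of 96 agents for the
trade-off surface, 35-agent crossovers for condition effects, 18 agents
(about 600 paths) for norm robustness, 24 dispersion-laddered agents for
parameter recovery, and 100 replicates of 12-agent crossovers for the
drug-effect recovery rate — sizes chosen to estimate each quantity
stably on a desktop machine while matching the reference cohort sizes
where they are stated (96 healthy participants, 35 patients).

## Known limitations

Uniqueness depends on the pooled corpus: scores from different pools are
not comparable, and the package deliberately refuses to default to
within-participant pooling. The mirror machinery requires a vertical task
axis; other geometries raise an error rather than silently reflecting
about the wrong line. Hull area grows with the number of points even at
fixed dispersion (no normalization is applied, matching the reference
definition), so fluency differences partly propagate into diversity.
Chord-versus-arc bias bounds the fidelity of 200-point resampling for
extremely tortuous paths. And all calibration of the generator is
plausibility-based, not fitted to human data — it defines study
conditions, it does not estimate them.
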