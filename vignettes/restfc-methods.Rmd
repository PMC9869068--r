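---
title: "Methods: models, conventions and design choices in restfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in restfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

restfc analyses cohorts of ROI-parcellated resting-state BOLD series with
four complementary connectivity measures and one shared group-comparison
screen. This vignette records the models, the conventions the implementation
commits to, and the reasoning behind the choices that were genuinely open.

## Data model

A subject is a `T × N` matrix (`roi_ts`): `T` timepoints sampled every `tr`
seconds, `N` ROIs identified by unique labels. Column order is canonical —
it defines edge `(i, j)`, `i < j`, for every downstream matrix — so cohort
validation treats a permuted ROI ordering as an error, not a cosmetic
difference. Time-series files are deliberately plain: tab-separated, one
label header row, one row per timepoint. The repetition time is metadata
about acquisition, not about a particular matrix, so it lives in the run
configuration (or a CLI flag), never in the data file. Symmetric matrices
are stored full rather than triangle-only and symmetry is re-checked on
read; human inspectability was weighted over compactness.

## Preprocessing

`zscore()` standardizes each column to mean 0 and sample SD 1 with
denominator `T − 1`. The same convention is used wherever an SD appears
(windowed variability, group SDs, the MAD screen's consistency constant), so
the point-process threshold "1σ" is exactly 1.0 on a z-scored series.

`bandpass()` applies the same zero-phase (forward–backward) Butterworth
filter, design order 2, to every column. Zero-phase filtering is standard in
rsfMRI because phase distortion would shift events and windows; applying an
identical filter to all columns leaves the expected instantaneous
cross-correlation structure intact. Filtering is off by default: user data
are assumed already preprocessed. A very low band edge (e.g. 0.001 Hz)
cannot be resolved on a 420 s record — its period exceeds the record — so it
acts as a detrend; the function permits it but warns.

## Static FC and the robust outlier screen

`pearson_fc()` is the plain Pearson correlation of entire series. The
outlier screen flags values more than `3 × 1.4826 × MAD` from the group
median. Two details are conventions this package fixes explicitly:

* the scaling constant 1.4826 makes the MAD a consistent SD estimate under
  normality (the standard "scaled MAD");
* the screen is applied **per edge**, and subjects are excluded only from
  that edge's statistics, not from the whole analysis. Whole-subject
  exclusion is a defensible alternative; edge-wise removal matches the
  screen's definition ("each participant in each group" at the flagged
  edge) and is less destructive. Both the pre-removal and post-removal
  statistics are reported (`F_clean`, `p_clean`), because silently replacing
  a result after data exclusion is not auditable.

When the MAD is zero (a degenerate, near-constant sample) any value off the
median is flagged and a warning is raised rather than flagging nothing.

## Sliding-window analysis

Windows are half-open index ranges of length `w` starting every `step`
timepoints, trailing partial windows discarded. The step defaults to 1 —
maximal overlap — which maximizes the number of windows on short records and
matches how the window-length assessment itself increments. No tapering or
weighting is applied. The default analysis window is `w = 30` timepoints
(90 s at TR = 3 s): the assessment curves show that windows shorter than
about 30 timepoints inflate the variability estimate while adding little,
and 30–120 timepoint windows give near-identical results.

Two exact anchors tie the module down: at `w = T` the single window
reproduces the static FC bit-for-bit and the across-window SD is zero, so
both difference curves of the assessment vanish identically there.

## Point-process analysis

Events are suprathreshold samples of the z-scored series; the threshold is
strict (`> 1σ`, not `≥`), reading "surpass" literally — on continuous data
the difference has measure zero but tests need a fixed convention. Two event
definitions are exposed because they serve different purposes:

* `"point"` (default): every suprathreshold sample. The co-activation count
  sums *all* relevant timepoints, so this is the mode the "matrix of
  addition" is defined on; typical per-pair counts (3–11 per scan) are
  consistent with raw point counts, and raw counts (not normalized by total
  events) are what the group comparison uses.
* `"upcrossing"`: only transitions from at-or-below to above the threshold
  (the first sample counts if already above). This is the definition under
  which band-limited BOLD shows its characteristic ~8.5 crossings per 420 s.

`coactivation_matrix()` stores per-ROI event totals on the diagonal, so the
structural bound `count(i,j) ≤ min(count(i,i), count(j,j))` is checkable on
every output.

## Graph measures

Binarization keeps an edge where `r > threshold` with signed values — a
strongly negative correlation is not an edge — and the boundary case
`r = threshold` is excluded (strict inequality, "exceeded"). The default
operating threshold is 0.3 with a 0.1–0.5 sweep in 0.01 steps (41 points)
for sensitivity analysis.

* Degree: row sums; mean over nodes.
* Clustering: `C_i = 2 T_i / (k_i (k_i − 1))` with `C_i = 0` for `k_i < 2`,
  the convention of the standard brain-connectivity toolboxes.
* Characteristic path length: mean shortest-path length over ordered pairs
  with *finite* distance, with the fraction of disconnected pairs reported
  alongside. At the operating threshold realistic FC graphs are nearly
  complete (L ≈ 1.3–1.6), so the treatment of infinite distances is
  low-impact; a harmonic-mean (`"efficiency"`) variant is provided for
  sparse graphs where it is not.

The scale-freeness diagnostic — R² of a straight-line fit to the log–log
degree survival function — is a deliberately labelled heuristic: it screens
for heavy-tailed degree distributions when choosing a threshold, and is not
a formal power-law test. It is undefined (reported `NA`) when fewer than
three distinct positive degrees exist, e.g. on regular graphs.

## Group statistics

The edge-wise screen is a classical one-way ANOVA per upper-triangle edge,
computed vectorized across edges (closed-form sum-of-squares decomposition;
~6.7k edges at N = 116 make per-edge `aov` calls wasteful). Post-hoc
pairwise comparisons use the pooled within-group mean square and its degrees
of freedom, with raw p-values multiplied by `G(G−1)/2` and clamped at 1
(Bonferroni). Tukey-style HSD is deliberately not implemented: the
pooled-`t`-with-Bonferroni construction is the most direct reading of
"multiple comparison tests corrected with Bonferroni".

The open question is which family the Bonferroni factor spans. Edge-level
screening p-values in the 1e-3 range across thousands of edges cannot
survive a correction over all edges, so the default scope
(`"posthoc_only"`) treats the edge screen as uncorrected at `alpha` and
corrects within each edge across the six pairwise tests. The stricter
readings are not discarded: `"edges_bonferroni"`, `"both"` and `"none"` are
implemented, the edges-family-adjusted p is always reported in the table,
and the scope is recorded in the fit object. Degenerate edges (zero
within-group variance with unequal means) are flagged rather than silently
dropped, with p reported as 0.

Scalar measures (global mean FC, global mean variability, global mean
co-activation, and the three graph measures) go through the same
ANOVA + post-hoc machinery via `scalar_anova_table()`; non-finite values
(e.g. an undefined path length on an edgeless graph) are dropped per measure
with a warning.

## The surrogate cohort generator

The generator emulates the acquisition the pipeline targets: 116 ROIs,
140 timepoints at TR = 3 s, four groups sized 35/29/30/34. Each group has a
block-structured baseline correlation matrix (default: 8 contiguous blocks,
`r_within = 0.5`, `r_between = 0.2` — values in the range typical of
within- versus between-network resting-state correlations, and consistent
with near-complete binarized graphs at threshold 0.3); planted effects
overwrite single edges with group-specific target correlations, which is how
known group differences at realistic magnitudes (e.g. 0.13 vs 0.38 at one
edge) are injected.

Temporal structure is imposed by filtering, not by an autoregressive model:
a subject is `T` i.i.d. multivariate normal draws with the group correlation
matrix, passed column-wise through an *ideal* (brick-wall) Fourier band
mask, then rescaled to unit sample variance per column. The ideal mask —
rather than the Butterworth used for user data — makes the in-band spectrum
exactly flat, which is what the analytic crossing-rate predictions assume
and what makes >95% in-band power an exact property. Since every column gets
the same filter, the expected cross-correlation structure equals the input
matrix.

Planting effects can make the requested matrix indefinite; it is repaired by
eigenvalue clipping at zero followed by re-normalization to unit diagonal
(iterated until the smallest eigenvalue exceeds −1e−10), and the repair
magnitude is attached to the result so planted effects can be verified
post-repair. This is the simplest reproducible repair; an
alternating-projections nearest-correlation algorithm would be more exact
but is unnecessary at the perturbation sizes involved.

**The passband default is 0.01–0.05 Hz, not the 0.001–0.1 Hz preprocessing
band.** The only spectral ground truth available for z-scored BOLD is the
empirical 1σ-upcrossing rate of about 8.5 ± 2.8 per 420 s scan. A flat band
spanning the full 0.001–0.1 Hz preprocessing range would yield a
substantially higher crossing rate (the Rice rate grows with the band's
second spectral moment), whereas a flat 0.01–0.05 Hz band predicts ≈8.2–8.3,
inside the empirical band. The generator's job is to emulate realistic BOLD,
so the narrower flat band is the default; it is configurable.

Two analytic crossing predictions are implemented (`expected_upcrossings()`):

* `"rice"`: the continuous-time Rice rate for a flat band `(f₁, f₂)`,
  `sqrt((f₂³ − f₁³) / 3(f₂ − f₁)) · exp(−u²/2)` crossings per second.
* `"exact"`: the exact discrete-time expectation *after per-series
  z-scoring*. A generated series is, up to scale, a uniform random point on
  the sphere of its `2m` kept Fourier coefficients; two consecutive samples
  of the z-scored series therefore follow a bivariate Pearson type II
  distribution whose correlation is the circular lag-1 autocorrelation of
  the band. Numerical integration of that density gives the expected
  transition count. The distinction matters: standardizing by the sample SD
  (which fluctuates with only ~2m ≈ 34 effective degrees of freedom)
  inflates the crossing count by roughly 2% relative to the naive Gaussian
  discrete-time prediction, and the exact form agrees with simulation within
  Monte-Carlo error while the naive form does not.

What the generator does **not** emulate: hemodynamic response convolution,
motion and scanner drift artifacts, physiological noise, spatial
autocorrelation beyond the block structure, non-stationarity (its dynamics
are those of a stationary band-limited Gaussian process), and heavy-tailed
event statistics. Passing tests on surrogate cohorts therefore demonstrate
correctness and calibration of the *computations*, not that real BOLD
satisfies the model assumptions; in particular the sliding-window
variability of surrogate data is pure estimation noise, which is exactly
what the calibration tests need and exactly what real dynamic connectivity
is hoped not to be.

## Validation design and problem sizes

The test suite pins every operation to an independent oracle: brute-force
mean-centred dot products for correlations, per-timepoint outer products for
co-activation, igraph for graph metrics, `aov`/`pairwise.t.test` for the
statistics, and closed forms (complete graphs, paths, stars, rings,
triangle-plus-pendant) exactly. Statistical behaviour is validated at sizes
chosen to keep the full suite within a couple of minutes on one core while
retaining power: null calibration pools 12 cohorts of 4 × 20 subjects at
20 ROIs (2,280 edge tests, binomial 99% bounds around α); planted-effect
recovery uses 100 replicate two-group cohorts (30 per group, 20 ROIs) and
requires the planted edge to rank first with the planted direction in ≥90%;
the crossing-rate check uses 1,000 series against the exact analytic
prediction within 3 Monte-Carlo standard errors. `scripts/acceptance.R`
recomputes the crossing-rate anchor from scratch with a user-supplied seed.

## Known limitations

* The ANOVA assumes exchangeable, roughly normal per-subject values per
  edge; correlation values are bounded and a Fisher z-transform before
  testing would be a defensible refinement (not applied, to keep the screen
  on the same scale as the reported group means).
* Covariate adjustment (age, sex), FDR or permutation alternatives, and
  cluster-level corrections are out of scope.
* Weighted graph metrics, community structure and small-world coefficients
  against rewired nulls are not implemented.
* The PSD repair changes non-planted entries slightly when a planted matrix
  is indefinite; the repair distance is logged so this is visible.
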