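---
title: "Measuring selection coefficients from colony sizes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection coefficients from colony sizes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyfit)
```

`colonyfit` turns daily colony-size images of pinned agar plates into
per-generation selection coefficients, and provides the two companion
assays — liquid growth curves and marked-reference competitions — that such
estimates are validated against. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## 1. From pixels to cells to generations

Colony area and colony cell number follow a power law, so the calibration
is an ordinary least-squares fit of `log10(cells)` on `log10(size)`. The
package ships the published coefficients (slope 1.46397, intercept 3.19251)
as `default_calibration()`, anchored at a mean pinned day-0 size of 57 px,
i.e. 579,506 cells deposited per colony. Two choices are deliberate:

* **Regression direction** is log-cells on log-size (the direction the
  conversion is used in), not orthogonal regression.
* **Unweighted OLS**: no weighting by pinning density or day, since a
  defensible weighting scheme would need replicate-level variance
  information the assay does not produce.

Day-0 anchoring sets every trajectory's starting point to the same pinned
population. Imaging software reports sub-threshold or morphologically
out-of-spec colonies as size 0; those records must carry an explicit
`present`/`absent` flag (`anchor_day0()` refuses to guess): present
colonies are re-incorporated at the day-0 size, absent ones discard the
whole trajectory. An automated guess would silently bias fitness toward
whatever the guesser assumes about small colonies.

All slopes are taken against *ancestor generations*,
`g(day) = log2(N_day / N_0)` averaged over the ancestor replicates of the
plate (both members of the ancestral pair pooled, log taken before
averaging). The selection coefficient of an evolved replicate is its
Malthusian slope minus the mean ancestor slope. With the natural-log
response (the default) an ancestor has slope `ln 2` on its own axis and `s`
is directly comparable to the competitive assay's `ln`-ratio slope; with
`base = "log2"` the ancestor slope is 1 and `s` is a per-generation excess
doubling rate. The two differ by exactly `ln 2`.

Replicates are compared to the *plate-level mean* ancestor slope rather
than to matched ancestor replicates: pairing would inherit a single
ancestor colony's spatial noise, while the mean spreads it. The flip side
is that all replicates on a plate share the ancestor-mean noise term, so
the standard error of a strain's mean `s` must include it
(`sqrt(2 var/n)` is the package's working approximation when evolved and
ancestor replicate slopes have similar spread).

## 2. Spatial effects and normalization

Edge effects — perimeter colonies growing larger — are handled three ways,
mirroring standard practice: snake-randomized layouts, corner exclusion,
and per-plate-day normalization. `make_snake_layout()` walks the plate's
concentric rings outward-in (clockwise from the top-left; the traversal
direction is arbitrary but fixed for reproducibility) laying down a seeded
random strain order cyclically, which balances every strain across layers
to within one colony. Only the four plate corners are excluded by default;
per-ring corner positions can be masked via the `mask` column if desired.

`rowcol_normalize()` implements sequential multiplicative scaling: each
value is scaled by grand-stat/row-stat, statistics are recomputed, then by
grand-stat/column-stat. With the mean this makes the output column means
exactly equal the grand mean and preserves the grand mean overall; an
additive variant is available. One application is one Sinkhorn-style
balancing step: it is a fixed point on exactly separable (row x column)
plates and contracts quickly otherwise, which is why the package applies it
once rather than iterating. Masked entries (corners, discarded
trajectories, `NA`s) are excluded from every statistic but still rescaled.
Normalization is applied per plate-day independently, since edge effects
grow with incubation time.

**Attenuation — read this before comparing normalizations.** Row/column
statistics are computed from the very colonies whose fitness is being
measured, so part of each strain's signal leaks into its own row and
column means and is divided out. On simulated 384-position plates the bias
is multiplicative and grows as strain diversity falls: with 12 strains the
estimated `s` is shrunk by roughly 5%, with 3 strains by roughly 20%.
Median statistics do not help (the strain effects *are* the bulk of the
distribution, not outliers). `layer_normalize()` — scaling by concentric
layer means — is nearly free of this attenuation when layouts are
snake-balanced, because every layer then contains each strain in equal
proportion and the layer means cancel in strain contrasts; its residual
bias (~1-2% of `s`, from the small inner-layer populations) is an order of
magnitude smaller. The package therefore defaults to row/column mean
normalization for fidelity to established colony-assay practice, but uses
layer normalization in its own recovery validation, where the simulated
spatial structure is concentric by construction and the question is whether
the *estimator* is correct. Users with few strains per plate should either
accept the attenuation (it is conservative: effects shrink toward 0),
normalize by layer, or array more strains.

`layer_effect_test()` quantifies residual structure: each outer layer is
compared to the innermost layer with a two-sample t-test,
Benjamini-Hochberg corrected across layers.

## 3. Growth-curve parameters

Four summaries per OD600 curve, computed on natural-log OD (the log base
for rates is a convention; h^-1 in ln units is the field's default):

* `max_growth_rate()`: the steepest OLS slope of log-OD over a sliding
  15-point (1 h at 4-min sampling) window, ties to the earliest window.
* `lag_time()`: where the line through the first 15 log-OD points crosses
  the max-rate line. Lines with slope difference < 1e-6 h^-1 are treated
  as parallel and the lag flagged undefined (a culture already growing at
  t = 0 has no measurable lag). Mathematically the lag may precede the
  first time point; values more than 1 h before it are flagged suspicious
  rather than clamped.
* `growth_auc()`: trapezoidal integral of log-OD minus the rectangle under
  the smallest observed log-OD, so a never-growing culture scores 0.
* `carrying_capacity()`: the maximum OD observed in the window.

A sliding-window maximum is an *extreme statistic*: under measurement
noise it preferentially selects windows whose noise tilts upward, giving a
small positive bias that grows as the signal-to-noise ratio at the start of
growth falls; the 1-h window also averages over logistic curvature, a small
negative bias. At 0.002 OD noise and a 0.1-OD inoculum these cancel to
within a couple of percent on average, but individual curves can be off by
more — recovery tolerances in the test suite are therefore evaluated on
ensemble means over 100 simulated curves (rate within 5%, lag within
0.25 h, capacity within 2%), not per curve.

## 4. Competitive fitness from flow cytometry

Gating follows the standard two-stage scheme: a 99% covariance ellipse on
log10 SSC-A x log10 FSC-A (debris removal), then a 95% ellipse on FSC-H x
width fitted to the survivors (doublet removal). Ellipses use the classical
sample mean/covariance with the chi-square(2) quantile, fitted per day on
the pooled events of all samples of that day and then applied per sample —
pooling stabilizes the gates and applies identical criteria to every
sample. A robust-covariance option is deliberately absent from the default
path: with ≤10% contamination the classical ellipse at the 99% level is
already dominated by the cell cluster.

The YFP threshold is the midpoint between the two largest modes of the
log10 YFP-A histogram (256 bins, lightly smoothed so shot noise cannot
spawn fake modes; the second mode must reach 5% of the first and be
separated by a real valley). Once found it is held constant across the
experiment; a manual threshold always overrides detection, since threshold
placement was a manual step in the assays this reproduces.

Reference-only controls estimate the dim fraction `f` of the marked
reference (observed at 1-19% in practice; values above 50% are flagged as
implausible controls). The unmarked:marked ratio is then
`Total (1 - f) / P - 1`, i.e. the true reference count is `P / (1 - f)`.
The same-day control supplies `f` for a day's samples. Generations per
daily cycle come from `log2(conc_end / (conc_prev * dilution))` with one
1/1000 dilution per 24 h cycle, concentrations being gated events over
acquired volume; each replicate's own culture provides its axis. `s` is
the OLS slope of `ln(ratio)` on cumulative generations, and an evolved
strain's fitness difference is its `s` minus the mean of its two
ancestors'.

## 5. The synthetic generators — what they emulate and what they don't

`simulate_plate()` draws, per colony and day,
`cells = day0_cells * 2^(g(day) (1 + s)) * edge(layer, day) * lognormal(sigma)`
and maps cells to pixels through the inverse calibration. Defaults are the
study conditions the pipelines target: 384-position plates, days 0-4,
1.5 ancestor generations per day (~6 over the course), lognormal cell
noise `sigma = 0.05`, and a "trimmed" edge profile (layer-0 multiplier
1.15 at day 4, fading linearly to layer 4 and growing with day; "intact"
uses 2.0). Edge effects are multiplicative on cells and increase with
time, matching the reported direction of real plates. Not emulated:
pinned-inoculum variability (day-0 anchoring makes the pipeline
insensitive to it), neighbour-size dependence beyond the layer structure,
and mechanistic nutrient diffusion. Passing recovery tests therefore shows
estimator correctness under concentric spatial structure — not robustness
to arbitrary spatial fields.

`simulate_growth_curve()` produces lag / logistic-rise / saturation curves
whose *maximum ln-slope equals the requested rate* (the internal logistic
rate is inflated by `1/(1 - od0/K)`), with Gaussian OD noise on a 4-min,
24-h grid. The 0.1 default inoculum represents a back-diluted culture the
reader resolves well above its noise floor; real 1/1000 dilutions start
below the resolvable range, a regime that would require modelling the
reader floor itself.

`simulate_flow_experiment()` draws singlet-cell, debris and doublet
clusters (5% each of the latter two by default), with the strain:reference
ratio following `ratio0 * exp(s g)` at ~10 generations/day plus 5%
lognormal day-to-day jitter, a dim-reference fraction inside the observed
control band (10% default), and per-day reference-only controls.
Acquisition volumes are set so event concentrations track the culture
through its dilution cycles. Compensation/spillover and barcode-style
readouts are out of scope.

All generators are deterministic functions of their seed (`withr`-scoped,
so the global RNG state is untouched).

## 6. Statistics

Significance per strain (x condition) uses the two-sided one-sample t-test
against 0, Benjamini-Hochberg corrected *within* an assay's table, never
across assays. "Significance level 0.95" conventions are read as
alpha = 0.05. The assay's error scale is the RMSE of the `s ~ strain`
one-way ANOVA; the default denominator is total n (mean squared residual),
with the residual-df variant behind `use_df = TRUE`. Power for the
one-sample t-test is computed exactly from the noncentral t distribution
and inverted with `uniroot` to the minimum detectable fitness difference;
at n = 32 and the competitive assay's error scale (RMSE 0.0176) the 80%
power threshold falls just below a 1% fitness difference, which is the
quantitative basis for calling these assays percent-level sensitive.
Reproducibility between experiments is the Pearson correlation of strain
(x condition) mean `s`.

## 7. Problem sizes used in validation

The recovery suite runs one 384-position plate (12 strains x 32
replicates, 5 days) for colony-fitness recovery; 100 simulated growth
curves; 3-day, 7-replicate, 20,000-event competition experiments; 1e5-event
ratio oracles; and 200 simulated 24-group null tables for type-I
calibration — sizes chosen to give each check percent-level resolution
while keeping the whole suite runnable on a laptop in a few minutes.

## 8. Known limitations

* Row/column mean normalization attenuates true effects (Section 2); the
  package reports what the field's standard arithmetic computes rather
  than attempting a deconvolution.
* The generation axis treats ancestor generations as fixed once averaged;
  its sampling noise is folded into the recommended SE approximation, not
  into a formal errors-in-variables model.
* Lag estimation inherits the noise of the first 15 points; at very low
  inocula it is the least stable of the four growth parameters.
* The CSV flow-event fallback expects pre-exported channel tables; binary
  FCS containers are not parsed.
* Fitness comparisons assume the evolved strain and its ancestors share a
  plate (colony assay) or a reference and conditions (competitive assay);
  cross-plate contrasts add layout-level variance the SEs do not model.
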