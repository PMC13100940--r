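---
title: "Quantifying antibody specificity with srquant: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody specificity with srquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srquant)
```

## The problem

Commercial antibodies against membrane proteins such as the TRPV1 and TRPA1
ion channels are notoriously variable, and immunofluorescence images alone
("it looks positive") are a weak basis for calling an antibody specific.
A quantitative alternative is to image cells in which the ground truth is
known independently of the antibody — a fluorescent reporter marks the cells
that genuinely express the target, or a knockout provides a field in which
no cell does — and to ask how much brighter the antibody channel is in true
positives than in true negatives.

`srquant` implements that analysis as a tested pipeline: a synthetic-field
simulator that stands in for acquired images (no raw image data are bundled
with the package; the simulator emulates their statistical structure),
per-cell quantification on maximum projections, the specificity-ratio
statistic with nonparametric inference, a knockout log-variance check, a
Monte Carlo power/sample-size simulation, and immunogen-region percent
identity scoring against orthologue sequences.

## The specificity ratio

All quantification operates on raw 16-bit maximum projections of confocal
z-stacks, with no background subtraction or normalization. For each
reporter-positive cell $i$ in a field, the specificity ratio is

$$\mathrm{SR}_i \;=\; \frac{\bar I^{\,\mathrm{ab}}_i}
  {\frac{1}{|N|}\sum_{j \in N} \bar I^{\,\mathrm{ab}}_j},$$

where $\bar I^{\,\mathrm{ab}}_i$ is the mean antibody-channel intensity over
the cell's pixels and $N$ is the set of reporter-negative cells *in the same
field*, required to contain at least 20 cells (`min_negatives`, exposed but
defaulting to 20). Negatives are never pooled across fields, so slide-level
illumination and staining differences cancel within each ratio. SR = 1 means
the antibody stains positives and negatives equally; SR > 1 means
preferential staining. Because both numerator and denominator are raw
intensities, SR is invariant to a global rescaling of the field — but it is
*not* background-free: a constant camera offset shrinks SR toward 1, which
is one reason the simulator's default background is small relative to the
signal amplitudes (see below).

Per-cell SRs are pooled across fields of the same condition and compared
against a secondary-only control with:

* the **Mann–Whitney test**, two-sided at $\alpha = 0.05$, exact by
  enumeration when the combined sample size is at most 12 and tie-free,
  otherwise the normal approximation with midranks, tie correction and
  continuity correction;
* the **Hodges–Lehmann estimator** of the shift — the median of all
  $n_x n_y$ pairwise differences, with the even-count median defined as the
  mean of the two central order statistics — and its distribution-free
  Moses 95% confidence interval: the $K$-th and $(n_x n_y + 1 - K)$-th
  sorted pairwise differences with
  $K = \lfloor n_x n_y/2 - z_{0.975}\sqrt{n_x n_y (n_x+n_y+1)/12} \rfloor$,
  clamped to at least 1. This is the standard large-sample rank-based
  interval; no bootstrap is involved, so the endpoints are always elements
  of the pairwise-difference multiset.

No multiple-testing correction is applied across antibodies or dilutions;
that choice is recorded in the comparison metadata rather than hidden.
Shapiro–Wilk and Kolmogorov–Smirnov screens (`normality_tests()`) document
why rank-based inference is used at all — per-cell fluorescence is
right-skewed and approximately lognormal. The KS variant tests against a
normal with sample-estimated parameters and is therefore anti-conservative
(the Lilliefors caveat); the result carries an explicit
`ks_approximate = TRUE` flag.

The `-` / `+` / `++` grading used in validation summary tables is a
heuristic on top of these statistics, and `grade_comparison()` treats it as
one: `-` if the CI contains 0 or the HL shift is below `t1`, `+` between
`t1` and `t2`, `++` at or above `t2`, with closed lower bounds and defaults
`t1 = 0.5`, `t2 = 2` SR units. `t1` equals the median difference the power
analysis is designed to detect; `t2` is an arbitrary "clearly useful"
multiple. Both are configuration, not science.

## The knockout log-variance check

When a knockout control is available, SR cannot be formed (there are no
true positives), but specificity still has a signature: a specific antibody
stains a wild-type field heterogeneously — some cells bright, some at
background — while in knockout tissue every cell sits at a similar
background level. `log_variance()` captures this as the sample variance of
$\log(\bar I_i / \mathrm{median}_j \bar I_j)$ over all cells of a field.
Field-median normalization is a documented choice (the normalization used
for published versions of this metric is typically not stated); it makes
the statistic scale-invariant, and any other positive normalizer changes it
by nothing at all, since a multiplicative constant shifts every log by the
same amount. Mixed-class fields should therefore show systematically higher
log-variance than knockout-like single-class fields, and the test suite
verifies they do in at least 18 of 20 simulated field pairs.

## The synthetic-field generator

The generator is first-class, tested code, not a fixture. It emulates the
study design the statistics assume:

* **Geometry.** Cells are disks with radii uniform in `radius_range`
  (default 4–7 px) placed by rejection sampling in a `height_px x width_px`
  field (default 256 x 256) so that edges are at least `min_separation_px`
  apart (default 2 px); placement aborts with a "field too crowded" error
  after 10,000 total attempts. Coordinates are 0-based (row, col); label 0
  is background.
* **Classes.** Exactly `round(positive_fraction * n_cells)` cells are
  positive (default 0.4 x 60 = 24), assigned by shuffling a fixed-count
  vector, so tests are exact rather than binomially noisy. Roughly half of
  sensory neurons expressing the target motivates a default fraction in the
  0.4–0.5 range; 60 cells per field keeps at least 20 negatives with room
  to spare and four fields per condition give around 100 positive cells,
  the order of magnitude a validation experiment analyzes.
* **Photometry.** Per-cell amplitudes are lognormal with class-dependent
  parameters. Defaults: reporter median 3000 (positive) vs 150 (negative),
  log-sd 0.3; antibody median 6000 (positive) vs 2000 (negative), log-sd
  0.25 — a generative specificity ratio of 3, with a constant background of
  50 intensity units and Gaussian read noise of sd 50 (Poisson shot noise
  is available via `poisson_scaling` but off by default). These are
  arbitrary-unit choices pinned once: amplitudes comfortably inside the
  16-bit range, a background that is small (2.5%) relative to the negative
  amplitude so SR recovery bias stays within a few percent, and
  amplitude-to-noise of 40 for negatives, well above the ratio of 10 at
  which the recovery tests operate.
* **z-structure.** Each cell has a Gaussian intensity profile along z
  (sd `z_profile_sigma`, default 1.5 planes over 5 planes) centered on a
  focal plane drawn uniformly from the integer plane indices — so the
  maximum projection recovers the full amplitude exactly, which is what
  makes the noise-free mean-recovery invariant exact. Noise order is
  Poisson on signal plus background (if enabled), then additive Gaussian,
  then rounding and clipping to [0, 65535].
* **Determinism.** One RNG stream per field, derived from the seed; the
  caller's RNG state is saved and restored.

What the simulator deliberately does not model: optics (PSF, depth
attenuation), anisotropic cell shapes, touching cells, autofluorescence
gradients, tissue texture. Passing tests on synthetic fields therefore
demonstrate that the *measurement and inference chain* is correct and
well-calibrated — not that segmentation would succeed on real tissue, which
is why `segment_reporter()` is documented as a stand-in validated only
against synthetic truth (real studies typically outline ROIs manually).
Residual biases the simulator *does* reproduce are instructive: taking the
maximum over noisy planes inflates dim pixels slightly, and the constant
background compresses ratios toward 1, so the pooled median SR of fields
generated at ratio $k$ lands a few percent below $k$ — the recovery tests
assert agreement within 10%, not equality.

## The power simulation

The sample-size question — how many positive cells per group are needed to
detect a given median difference in SR — is answered by Monte Carlo
(`simulate_power()`, `required_n()`), with B = 2000 replicates by default.
SR-like data are modeled as lognormal. The null group has log-mean 0 (median
1, matching secondary-only controls) and log-sd 0.8; the published planning
analysis states the lognormal assumption, B, the target median difference
of 0.5 and the answer (n = 70 per group at power 0.823) but not the
lognormal parameters, so log-sd 0.8 is fixed here as the documented
reference configuration — it is the value under which the two-sided
Mann–Whitney test at $\alpha = 0.05$ reaches the reported power at exactly
that sample size, and both parameters remain configurable. The alternative
group is scaled multiplicatively by $(m_0 + 0.5)/m_0$, the only location
change that keeps both groups exactly lognormal. The grid search steps
through n = 10, 20, ..., 200 in order and returns the first size whose
estimated power reaches 0.80, along with the full curve and the Monte Carlo
standard error $\sqrt{p(1-p)/B}$ (about 0.009 near p = 0.82). Each grid
size uses the stream seeded `seed + n`, so a single-size run and the grid
run agree exactly.

```{r power, eval = FALSE}
spec <- power_spec(seed = 1)       # B = 2000, log-sd 0.8, delta = 0.5
simulate_power(spec, 70)$power     # ~0.82
required_n(spec)$n_required        # 70
```

An asymptotic cross-check used in the tests: with
$p_1 = P(X < Y) = \Phi\!\left(\ln(1.5)/(0.8\sqrt{2})\right) \approx 0.64$,
the Noether-type approximation
$\Phi\!\left((p_1 - \tfrac12)\sqrt{12 n^2/(2n+1)} - z_{\alpha/2}\right)$
gives 0.815 at n = 70, within Monte Carlo error of the simulation.

## Immunogen identity

Cross-species reactivity correlates with how conserved the immunogen region
is. `identity_table()` extracts a region by 1-based inclusive coordinates,
aligns it semi-globally to the orthologue (region global, orthologue ends
free) under BLOSUM62 with affine gap costs (open 11, extend 1), and reports
percent identity with **all alignment columns, including gaps, in the
denominator**. That convention had to be fixed once: published identity
figures for short immunogens are sometimes internally inconsistent (values
that imply a denominator of region length minus one), so results computed
here can differ from printed values by one rounding step; the output keeps
`matches` and `aligned_columns` explicit so any convention can be
recomputed. Ties between equally scoring placements are broken toward the
leftmost subject position by re-aligning against shrinking subject
prefixes, making the output deterministic.

Real orthologue sequences (e.g. UniProt entries) are user-supplied and
never downloaded; the bundled FASTA is a *synthetic* stand-in engineered so
that residues 1–100 of the "human" record match the "mouse" record in
exactly 77 of 100 aligned columns — the code path is identical to the real
use case, only the sequences are artificial.

## Numerical and degenerate-input choices

* Otsu thresholding of a constant image returns "no foreground" rather than
  an arbitrary split, both on pixels and on per-cell means.
* Connected components use 8-connectivity, labels numbered in raster order
  of each component's first pixel; components below `min_area` (default 20
  px) are dropped.
* Identical constant samples in the Mann–Whitney test return p = 1 under
  the midrank convention (U sits exactly at its null mean).
* The Moses CI index K is clamped to 1, so tiny samples widen the interval
  to the extreme pairwise differences instead of failing.
* A constant sample is an error for `normality_tests()` (both statistics
  are undefined there).
* Grading bounds are closed at the lower end: an HL shift exactly at `t1`
  grades `+`, exactly at `t2` grades `++`.

## Problem sizes used by the test suite

The suite exercises the full chain at deliberately compact sizes chosen as
the smallest that still separate signal from Monte Carlo noise: fields of
160 x 160 px with 34 cells (14 positive / 20 negative — the minimum
negative count), 10–20 seeds per property, B between 200 and 1000 for
calibration checks, and the reference B = 2000 configuration for the power
results. The end-to-end demo (`inst/extdata/demo_config.yaml`) runs two
simulated antibodies (generative ratios 3 and 1) against a secondary-only
control, four fields each.

## Known limitations

* Segmentation is threshold-based and will merge touching cells; it is a
  stand-in for manual ROIs, not a general cell segmenter.
* SR is sensitive to additive offsets by construction (raw projections, no
  background subtraction); comparisons between instruments with different
  offsets are not meaningful.
* The power simulation's log-sd is a reference value, not an estimate from
  data; power at other spreads should be recomputed with `power_spec()`.
* The log-variance metric assumes comparable cell segmentation between
  wild-type and knockout fields; systematic area differences would bias it.
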