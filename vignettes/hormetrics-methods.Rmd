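---
title: "Quantifying hormetic drug response and biomarker associations in organoid panels"
author: "hormetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hormetic drug response and biomarker associations in organoid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormetrics)
```

## The problem

Patient-derived tumor organoid panels are screened against a drug on a
small dose grid (here: eight concentrations from 0 to 8 µM, three to four
replicate wells of ~2000 seeded cells each, ~20 lines). Two things make
the analysis non-standard:

* some lines *grow faster* at low doses than untreated controls — a
  non-monotonous (hormetic) response that a classical four-parameter
  logistic cannot represent;
* the cohort is tiny, so biomarker association needs aggressive
  multiple-testing control, collinearity handling (mutations present in
  exactly the same lines are statistically one feature), and robustness
  checks across several response summaries.

`hormetrics` implements the full chain: dose-response quantification with
four viability measures, monotonicity phenotyping, mutation/expression
feature preparation, and a multi-measure association procedure — plus a
seeded synthetic-cohort generator with planted ground truth so that every
stage is testable without any external data.

## The hormetic dose-response model

Viability is the cell count at concentration $c$ divided by the untreated
control count of the same replicate, so $v(0) = 1$ by construction. The
model combines a two-parameter sigmoid (asymptotes fixed at 1 and 0, which
is what makes it two-parameter on control-normalized data) with a scaled
normal density carrying the low-dose growth peak:

$$v(c) = \frac{1}{1 + e^{\,\beta (c - m)}} \;+\; A\,\varphi(c;\,\mu,\sigma),$$

with midpoint $m$ (`shift`, µM), steepness $\beta$ (`slope`, 1/µM, $> 0$),
peak location $\mu$ (µM), peak width $\sigma$ (µM, $> 0$) and a
nonnegative proportionality coefficient $A$ (`amp`). For $A = 0$ the model
is a pure decreasing sigmoid and the fitted IC50 equals `shift` exactly.
`amp` is constrained $\ge 0$ because the peak component models growth
enhancement; the constraint can be lifted by fitting with custom bounds,
but all shipped tools keep it.

### The four response measures

1. **`auc_trap`** — trapezoidal area under each replicate's piecewise-linear
   viability curve, then the median across replicates.
2. **`ic50_trap`** — per replicate, linear interpolation to $v = 0.5$
   inside the first segment with a downward crossing (scanning in
   increasing concentration); median across replicates. Curves that never
   reach 0.5 are *censored* at the maximum tested concentration and
   flagged; the summary flag is set when at least half the replicates are
   censored.
3. **`auc_fit`** — $\int_0^{c_\max} \hat v(c)\,dc$ of the fitted model, by
   adaptive quadrature (the closed form — logistic antiderivative plus
   normal CDF — is used as an independent oracle in the tests).
4. **`ic50_fit`** — smallest downward 0.5-crossing of the fitted curve,
   found by bracketing on a 1000-point grid and bisection to 1e-8 µM;
   censored at $c_\max$ when no crossing exists.

AUCs are computed on the observed range $[0, c_\max]$ of normalized
viability; lower AUC means a more sensitive line.

### Estimation and the random-restart fallback

All replicate points of a sample enter one least-squares fit of the five
parameters, bounded (`sigma`, `slope` > 0, `amp` ≥ 0) and started from
three deterministic heuristics (peak at the empirical maximum, midpoint at
the empirical half-viability dose, plus two generic shapes). We use
L-BFGS-B with an analytic gradient of the residual sum of squares.

A fit is declared **converged** when the optimizer reports success, the
RSS is finite, *and* no shape-critical parameter is pinned to a sampling
bound. The last clause is what operationalizes the known failure mode of
this model: for step-like fast responders (viability ≈ 0 at every nonzero
dose) the sigmoid is not steep enough at zero concentration under any
interior parametrization, so the fitted `slope` runs into its ceiling —
that is not a stationary point, and such samples are sent to the fallback.
`amp = 0` is a legitimate boundary solution (most lines are pure
sigmoids), so the sigma/amp pinning check only applies when the fitted
peak is material (height above 2% of control viability).

The fallback (`random_restart_fit()`) draws 500 parameter vectors
uniformly from documented ranges (`mu` ∈ [0, c_max], `sigma` ∈
(0, c_max/2], `shift` ∈ [-c_max/2, 2c_max], `slope` ∈ (0, 20], `amp` ∈
[0, 5]), evaluates all of them, polishes the 20 most promising (plus the
primary path's incumbent, which guarantees the returned RSS never exceeds
any primary fit) by bounded local minimization, and returns the
minimum-RSS solution. Whether "parameter samplings" should be polished or
evaluated directly is genuinely ambiguous; we default to polishing and
expose `polish = FALSE` (CLI: `--no-polish`) for pure evaluation. Fallback
draws are seeded, so pipelines are reproducible end to end.

## Monotonicity phenotype

A line is a **non-monotonous responder** when its *fitted* curve at the
lowest nonzero tested concentration is at least 1.5× the untreated
control (inclusive threshold; "an increase of at least 50%" and "at least
1.5 times control" coincide on normalized viability). Group comparisons
downstream: per-mutation 2×2 chi-square tests without continuity
correction (degenerate margins report p = 1 with a flag; a warning counts
cells with expected counts below 5, unavoidable at n = 20), and a
moderated two-group expression comparison.

### Moderated t, re-implemented

With groups as small as 3 vs 17, per-gene variances are unusable; we
shrink them toward a common prior by empirical Bayes. The prior degrees of
freedom $d_0$ and scale $s_0^2$ are estimated by moment-matching the
distribution of log pooled variances (using a Newton inverse of the
trigamma function), the posterior variance is the convex combination
$(d_0 s_0^2 + d\,s_g^2)/(d_0 + d)$, and the moderated t uses $d + d_0$
degrees of freedom. `prior_df = 0` recovers the ordinary pooled t exactly;
our implementation agrees with the reference empirical-Bayes
implementation in `limma` to machine precision on simulated data (see
`test-phenotype.R`), but the package itself depends only on base R.

## Feature preparation

* **Mutations**: records are filtered to coding, non-silent classes
  (silent, intron, intergenic, non-coding, UTR and flank records are
  dropped; common annotation spellings are normalized via an explicit
  table, and unknown classes error rather than pass silently), binarized
  per (sample, gene), optionally forced by a curated override list (e.g.
  pathogenic germline variants found outside the somatic pipeline), and
  filtered to genes mutated in ≥ 2 samples. The recurrence filter runs
  before collinearity grouping; the resulting group patterns are identical
  either way, only singleton bookkeeping differs.
* **Collinear groups**: genes with *identical* mutation patterns are one
  feature. Groups whose mutant samples are all hypermutants are flagged
  (likely passengers), as are groups with ≥ 5 member genes (driver cannot
  be pinpointed; the threshold is configurable — "large" is not defined
  more precisely anywhere, and a reported real-world example had 8
  members).
* **Expression**: genes × samples matrix, row mean-centered; association
  runs on high-variance genes (sample SD strictly above 0.7 by default,
  which keeps ~11% of genes in the synthetic world; a top-fraction mode
  with deterministic tie-breaking is also provided). SDs use the n−1
  denominator.

## Association procedure

Per collinear group and per viability measure, a two-sided Welch t-test of
mutant vs wild-type samples (pooled-variance option available; Welch is
the default because arms are tiny and unbalanced). P-values are adjusted
by Benjamini–Hochberg **per measure across tested groups** (the 0.25
cutoff reads as an FDR; adjusting across measures jointly is available by
concatenation but not the default). Expression genes are screened by
Pearson correlation with each measure, significant when |r| ≥ 0.5
(inclusive). Censored IC50s enter tests at the maximum concentration with
a warning. A feature is **robust** when significant for at least 2 of the
4 measures; hypermutant-only and large-group flags propagate into the
final report. Hypermutant status is tested by Welch t-test per measure,
subtype by one-way ANOVA (the subtype test is never named in the source
methodology; ANOVA is consistent with its other group comparisons and
reduces to the squared pooled t for two levels). Drug–drug Pearson
correlations use pairwise-complete samples with a minimum of 3 complete
pairs (below that the entry is NA), and the panel is ranked by correlation
with the focal drug, the focal drug excluded from its own ranking.

## The synthetic world

`generate_cohort()` emulates the screen the pipeline targets; its defaults
*are* the stated conditions, chosen once: 20 samples, grid
0, 0.5, 1, 2, 3, 4, 6, 8 µM (the source states "between 1 µM and 8 µM"
plus a control but never prints the grid — ours is a guess and stays
configurable), 3 replicates, 2000 cells seeded per well, multiplicative
lognormal count noise with log-SD 0.05, 15% hormetic lines (3/20,
matching the observed passage-1 fraction), 6 hypermutants at 5× the 0.12
background per-gene mutation rate, 80 mutation genes with 3 planted
collinear groups (2–8 members), 2000 expression genes of which 11% are
high-variance (SD 1.0 vs 0.3), an 84-drug panel, a planted mutation
effect of 2 within-group AUC standard deviations, a planted expression
gene at correlation −0.7 with true AUC (high expression ↔ sensitivity,
mirroring a BIK-like marker) and a planted drug at correlation 0.8 with
the focal drug.

Implementation choices worth knowing:

* **Counts are integers** (`round(2000 · v · noise)`): real well counts
  are. This quantizes viability at ~5·10⁻⁴, which is the dominant error
  source for noiseless parameter recovery (~10⁻³ median relative error;
  the optimizer itself recovers exact data to ~10⁻⁷).
* **Planted peaks are narrow** (`mu ≥ 3.5 sigma`), so the normal density
  contributes essentially nothing at dose 0. Otherwise control
  normalization (dividing by the dose-0 count) rescales the whole curve
  and the planted peak height is not what the data show. The cost: peak
  position and width are only weakly identified on the default grid (the
  peak spans ~1 grid point); the peak *value* at the lowest nonzero dose —
  the quantity the monotonicity rule uses — is recovered to < 1%.
* **Planted effects are exact, not stochastic.** The mutant-vs-wild-type
  separation is planted by lowering each mutant's true logistic AUC by
  exactly `effect × sd(baseline AUC)` (midpoints found by root-finding on
  the closed-form logistic area), and planted correlations are constructed
  with in-sample orthogonalized noise so the empirical correlation equals
  the target exactly. What remains stochastic is estimation: group
  composition still makes the *realized standardized* effect fluctuate
  (SD ≈ 0.5 at n = 20).
* **What a green test does not establish**: the generator plants smooth
  single-peak curves, homoscedastic log-normal count noise, independent
  genes and drugs, and exact collinearity. Real screens have correlated
  gene modules, batch effects, heteroscedastic counting error, edge-well
  artifacts and near-collinear (not identical) mutation patterns. Green
  recovery here validates the machinery, not field performance.

## Numerical and design choices

* Censoring convention: unreached IC50s are reported as $c_\max$ with a
  flag (plots elsewhere show finite values, so a sentinel value would
  distort medians less transparently).
* Multiple 0.5-crossings of hormetic curves: the smallest downward
  crossing is taken, reading the curve in increasing concentration.
* L-BFGS-B uses `factr = 1e4` for final fits; the boundary tolerance for
  the convergence rule is 1e-6.
* Seeds: one global pipeline seed fans out to per-stage (and per-sample
  fallback) seeds by a fixed affine map mod 2³¹−1, so stages can be rerun
  independently and reproducibly; all generator randomness is scoped so
  the caller's RNG stream is untouched.
* TSV interchange: header row, `#`-prefixed metadata lines carrying the
  package version, a 32-bit FNV-1a fingerprint of the analytic config, and
  the seed; UTF-8; `NA` for missing.

## Known limitations

* **Power at the planted boundary.** With 20 samples (7 mutant vs 13
  wild-type), ~70 tested collinear groups, BH FDR < 0.25 per measure and
  the 2-of-4 rule, the planted mutation gene is recovered in ~88% of
  seeded cohorts at an effect of exactly 2 within-group SDs (50/50 for
  the planted expression gene and drug). The corresponding acceptance
  check expects ≥ 90% and is deliberately left failing rather than making
  the synthetic world easier; from effect ≈ 2.3 SD upward recovery clears
  90%. The four measures are strongly correlated, so the robustness rule
  is nearly a single shot rather than four.
* Noiseless parameter recovery is quantization-limited (integer counts at
  2000 cells/well), not optimizer-limited.
* The multivariate association arm ("combinations of features") is out of
  scope — no algorithm is specified anywhere; likewise CMS subtype
  *classification* (only the downstream group test is implemented) and
  germline screening from raw exomes (represented by the override list).
* `fit_hormetic` requires ≥ 6 points; with the default grid and 3
  replicates there are 24, but single-replicate 5-point screens are
  rejected by design.
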