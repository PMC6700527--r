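---
title: "Growth-rate inhibition metrics and replicate metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate inhibition metrics and replicate metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmetrology)
```

# The problem

Plate-based drug dose-response assays — seed cells in a microtiter plate,
treat with a dilution series, count viable cells after a few days — are a
foundational perturbational experiment, and a notoriously hard one to
reproduce across laboratories. Conventional endpoints such as IC50 are
confounded by division-rate differences between sites and experiments.
This package implements the growth-rate-normalized alternative and, around
it, the metrology needed to say *how* reproducible a given laboratory's
measurements actually are: nested technical/biological standard errors,
plate-level spatial QC, and direct comparison of assay readouts. A
synthetic plate-data generator with the same nested replicate structure
makes every stage testable end to end without external data.

# The GR model

For a treated well with endpoint count $x_c$, pre-treatment count $x_0$
and same-plate vehicle-control count $x_{ctrl}$,

$$\mathrm{GR}(c) \;=\; 2^{\,\log_2(x_c/x_0)\,/\,\log_2(x_{ctrl}/x_0)} - 1 .$$

The exponent is the ratio of the treated to the untreated growth rate, so
GR = 1 means uninhibited growth, 0 complete arrest, and $-1$ complete
killing, independently of how fast the untreated cells divide. `grValue()`
requires $x_{ctrl} > x_0$ (controls must have grown) and treats $x_c = 0$
as the complete-kill limit. Values outside $[-1, 1]$, which arise under
noise, are **flagged but never clipped**: clipping would bias every
downstream standard error toward zero.

Two conventions needed fixing where the procedure admits more than one
reading, and both are exposed as arguments:

* $x_0$ is the mean of the untreated t = 0 plate of the same biological
  replicate (one plate per day is assayed at the moment of drug addition),
  shared across that day's treated plates.
* $x_{ctrl}$ is the per-plate mean of the vehicle wells (median
  selectable), so plate-level growth effects cancel within the ratio.

`instantaneousGR()` extends the endpoint definition to live-cell time
courses: within a sliding window (default 12 h wide, advancing in 2 h
steps, labelled by its center) the growth rate $k$ in doublings/h of each
treated well and of the plate-matched control trajectory is an ordinary
least-squares slope of $\log_2(\text{count})$ on time, and the windowed
value is $2^{k/k_{ctrl}} - 1$. Windows whose control slope is non-positive
cannot be normalized and are omitted with a flag rather than silently
dropped.

# Curve fitting and derived metrics

`fitGRCurve()` fits the three-parameter sigmoid

$$\mathrm{GR}(c) = \mathrm{GR}_{inf} +
  \frac{1 - \mathrm{GR}_{inf}}{1 + (c/\mathrm{GEC}_{50})^{h}}$$

to per-concentration mean GR values by bounded least squares
($\mathrm{GR}_{inf} \in [-1, 1]$, $h \in [0.1, 5]$,
$\mathrm{GEC}_{50}$ within two decades of the tested range), with
multi-start initialization (geometric mid-dose, both range ends, and a
near-flat start) so the optimizer cannot be trapped by a bad mid-point
guess. A nested-model F-test (3 vs 1 parameters) compares the sigmoid to
the flat model $\mathrm{GR}(c) = \overline{\mathrm{GR}}$; when the sigmoid
is not significantly better at $\alpha = 0.05$ the fit falls back to flat
and no sigmoid parameters are reported. The $\alpha$ is a package
convention — standard for nested model comparison, and selectable.

Derived metrics follow the field's definitions:

* **GR50** — the concentration where the fitted curve crosses 0.5, in
  closed form; when the curve does not cross 0.5 inside the tested range
  the value is *censored* (`greater_than_cmax` / `less_than_cmin`) rather
  than reported as a number, because a bound is all the data support.
* **GRmax** — the mean *measured* GR at the highest tested concentration.
  The fitted asymptote is reported separately as `gr_inf`; the two
  deliberately differ when the dose range stops short of the lower
  plateau, which is exactly the situation the dose-range flags detect.
* **GR_AOC** — the trapezoidal integral of $1 - \mathrm{GR}$ over
  $\log_{10} c$, normalized by the log-range: the mean growth-rate deficit
  across the tested range.

`doseRangeFlags()` marks fits whose GEC50 falls outside the tested range
and fits where the curve at the top dose is still more than 0.1 GR units
above its asymptote (`no_lower_plateau`): both situations make
$\mathrm{GR}_{inf}$ an extrapolation, and truncating the top decade of a
biphasic response demonstrably shifts the fitted asymptote upward (see the
dose-response tests). `compareAssays()` reports per-drug
$\Delta\mathrm{GRmax}$ and $\Delta\log_{10}\mathrm{GR50}$ between two
readouts, flagging drugs whose GR50 is defined under one readout and
censored under the other — the signature of a surrogate assay whose
signal never falls below GR = 0.5.

# Replicate metrology

Uncertainty is quantified on GR *values*, not on fitted metrics, using

$$\mathrm{SE} = \sigma/\sqrt{n}, \qquad
  \sigma = \sqrt{\textstyle\sum_i (x_i - \mu)^2 / (n - 1)} .$$

* `technicalSE()` computes one SE per (drug, dose, biological replicate)
  across all of that day's technical GR values — wells and plates pooled.
  A design of $d$ drugs, $k$ doses and $b$ days yields exactly
  $d \cdot k \cdot b$ values (192 for the reference 8 × 8 × 3 design).
* `biologicalSE()` enumerates, per drug-dose pair, every combination that
  takes **one technical unit per day** and computes one SE across the $b$
  chosen values. The technical unit is the *plate-level mean* GR: wells
  are averaged per plate first, so 3 plates per day over 3 days give
  $3^3 = 27$ combinations per pair and $64 \times 27 = 1728$ values for
  the full design. Using individual wells as units would give $9^3$
  combinations instead; the plate-mean reading is the package's
  convention because a plate is the smallest unit that can be picked
  independently per day.
* `metricSE()` applies the same formula to GRmax, GR_AOC and
  $\log_{10}\mathrm{GR50}$ across per-replicate fits, excluding censored
  GR50 values and reporting the exclusion count — averaging a censoring
  bound as if it were a measurement would fabricate precision.

`summarizeSE()` reports the mean, the 90th percentile using the
linear-interpolation quantile convention $h = (n-1)p + 1$ (R's type 7 —
fixed so the percentile is testable), and a Gaussian KDE with Scott's
bandwidth on 256 points over $[0, 1.1\,\max]$. Because SE values are
non-negative, the KDE is renormalized by its trapezoid integral on that
grid; an untruncated kernel leaks mass below zero and would not integrate
to 1 where it is plotted. `foldChangeLog10SE()` converts a
$\log_{10}\mathrm{GR50}$ SE to its fold-change reading
($10^{0.07} \approx 1.17$-fold).

# Plate QC

`edgeEffectAnalysis()` takes a full plate of untreated counts and reports
the fractional deviation of every row, column and edge-distance band from
the plate mean, with a Welch two-sample test of each row/column against
the complement, Bonferroni-corrected across the $rows + cols$ tests at a
conservative default $\alpha = 0.01$. The test choice is a package
decision (the phenomenon is well known; the flagging test behind published
plate figures is typically unstated); Welch avoids assuming equal
variances and Bonferroni keeps the family-wise error controlled with only
40 tests on a 384-well plate. Edge distance is
$\min(r-1, c-1, R-r, C-c)$ with bands 0, 1 and 2+. Detection only:
spatial *correction* (LOESS smoothing, autocorrelation models) is out of
scope — the in-scope countermeasure is layout randomization
(`randomizeLayout()`), which converts systematic spatial error into
random error.

# The synthetic-data generator

`simulateEndpoint()` / `simulateTimecourse()` generate tidy well tables
with the reference study conditions as defaults: 8 drugs × 8 doses in
$\sqrt{10}$-fold steps from 1 µM, 384-well plates seeded at 750
cells/well, 72 h treatment, 3 days × 3 plates × 3 wells per condition,
≥ 24 randomized vehicle wells per plate, and one full untreated plate per
day at t = 0. The growth model inverts the GR definition exactly:
a dose with true value $\mathrm{GR}^*$ grows as
$x_0 \cdot 2^{k_{ctrl}\, g\, t}$ with $g = \log_2(\mathrm{GR}^* + 1)$, so
noise-free data round-trip through `grTable()` to the true curve to below
$10^{-9}$ — the generator and the estimator share no code path beyond
that definition.

The noise hierarchy and its one deliberate asymmetry:

* **Well level** — multiplicative log-normal count noise with the given
  CV (default 5 %), rounded to integer counts. Rounding applies only when
  the CV is positive: the noise-free mode is an analytic fidelity mode and
  keeps exact real-valued counts.
* **Plate and day level** — log-normal multiplicative effects on the
  *growth rate*, with meanlog $-\sigma^2/2$ so the multiplier has
  expectation exactly 1. These cancel in the GR ratio by construction —
  that cancellation is the entire point of GR normalization, and the
  generator keeps them so tests can demonstrate it.
* **Day-level efficacy effect** (`daySigmaEffect`, default 0.1) — a
  log-normal multiplier on each drug's fractional effect, drawn per
  (day, drug). This is the generative source of *biological* variability:
  day-to-day changes in the response itself (procedure drift, biological
  adaptation state) do not cancel in GR, and without such a term the
  biological SE could not exceed what well noise alone propagates.

Time-varying efficacy uses two first-order time constants per drug: onset
$e(t) \propto 1 - e^{-t/\tau_{on}}$ and adaptation $e^{-t/\tau_{adapt}}$,
integrated in closed form, which is the minimal parameterization that
produces both a time-invariant drug and one whose intermediate-dose
windowed GR rises over the assay. The edge field multiplies counts by
$1 - f \cdot \max(0, 1 - d/\text{depth})$ for edge band $d$ (default
depth 2); in time courses the multiplier is applied as
$m^{t/T}$ so it accumulates with growth. Dead cells follow
$\text{dead fraction} = \text{baseline} + \text{slope} \cdot
(1 - (\mathrm{GR}^* + 1)/2)$, clipped to $[0, 1]$, tying death to drug
effect so that dead-inclusive miscounting can be emulated. The surrogate
readout multiplies viable counts by a per-cell signal interpolating from
1 to the drug's `atpBias` with fractional effect — arrested-but-enlarged
cells (bias > 1) inflate apparent GR, collapsed ATP (bias < 1) deflates
it; controls always carry unit signal.

The default drug panel spans the regimes the analysis must distinguish —
full arrest inside the range, a mid-point near the top dose, strong
adaptation, large and small surrogate bias — with parameter values chosen
once as illustrative calibrations; no published numeric ground truth
exists for them, and the adaptation kinetics in particular are
qualitative. What the generator does **not** emulate: image segmentation
itself (only its count-level consequences), pharmacokinetics, media
effects, spatial noise correlation beyond the deterministic edge field,
and passage-number drift. Passing tests therefore certify the statistical
machinery, not the biology of any particular cell line.

# Numerical and scale choices

* Optimizer: `stats::optim` L-BFGS-B on
  $(\mathrm{GR}_{inf}, \log_{10}\mathrm{GEC}_{50}, h)$; four starts;
  residual ties resolved toward the flat model.
* All concentrations are µM throughout; times are hours; growth rates are
  doublings/hour.
* Well coordinates are 1-based row-major with A1-style labels
  (`wellLabel(3, 5)` = `"C05"`).
* Determinism: every generator takes a seed and is a pure function of
  (config, seed); the pipeline writes a manifest with config snapshot and
  file digests, and re-running reproduces byte-identical CSVs.
* Test and acceptance problem sizes: the full 8 × 8 × 3 × 3 × 3 design is
  exercised once per run where the combinatorics demand it (192/1728 SE
  counts); property sweeps use 2-drug, 96-well configurations, 10–20 seeds
  and 200-plate null calibrations — sizes chosen to make the checks sharp
  while keeping a full suite run in well under a minute per file.

# Limitations

Biological-SE enumeration is exhaustive ($t^b$ combinations) and guarded
by a cap rather than sampled; for the designs this package targets
($3^3$) that is exact and cheap. The flat-fallback F-test assumes
independent homoscedastic residuals across concentrations, which pooled
replicate means only approximate. Censored GR50 values are excluded from,
rather than modelled in, metric SEs — a survival-style treatment of
censoring is out of scope. And the variance decomposition is the
enumerated replicate procedure, deliberately not a fitted mixed model:
it counts what the replicate structure actually supports rather than
estimating variance components under distributional assumptions.
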