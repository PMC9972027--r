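---
title: "Methods: screen normalization, hit calling, dose-response and validation statistics"
author: "chorioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen normalization, hit calling, dose-response and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chorioscreen)
```

This vignette documents the statistical machinery of the package: the
models behind each pipeline stage, the parameters that matter and their
defaults, the numerical decisions, what the synthetic-data generators do
and do not emulate, and the known limitations.

# The screening problem

A single-point repurposing screen treats every compound of an
approved-drug library (1,271 compounds by default, the size of a
standard FDA-approved collection) at one concentration (10 µM, 48 h) in
each of four cell lines: three choriocarcinoma lines (JAR, JEG-3, BeWo)
and the immortalized extravillous trophoblast line HTR-8/SVneo serving
as the "normal" control. The readout is a colorimetric viability assay:
optical density proportional to metabolically active cell number. The
goal is a short list of compounds that kill the cancer lines but spare
the trophoblast line, confirmed by replicated secondary screening,
concentration-response, and in-vivo validation.

# Plate normalization

Viability of a sample well is interpolated between its plate's blank
wells (no cells) and DMSO vehicle wells (no drug):

$$v = \frac{OD - \overline{OD}_{blank}}{\overline{OD}_{DMSO} - \overline{OD}_{blank}}$$

Blanks are pooled per plate; DMSO means are taken per plate *and* cell
line, so multi-line plates normalize correctly. Requirements: at least
one blank and two DMSO wells per plate/line; a plate whose DMSO mean
does not exceed its blank mean is rejected as degenerate (the assay
failed — silently carrying it forward would poison the z-scores).
Negative viabilities are clamped to 0: optical densities below blank are
physically measurement noise. Missing OD cells are rejected rather than
imputed, for the same reason.

# Library z-scores and the selectivity rule

Percent inhibition is $100(1 - v)$. Within each cell line the entire
library is used as the null distribution — the standard single-point HTS
convention, resting on the assumption that the vast majority of library
compounds are inactive:

$$z_{c,\ell} = \frac{x_{c,\ell} - \bar{x}_{\ell}}{s_{\ell}}$$

with the sample SD ($n-1$ denominator; documented so results are exactly
reproducible). Positive $z$ means stronger inhibition.

A compound is called **selective** when

* $z > 2$ (strict) in at least `minCancerLines = 2` of the three cancer
  lines, and
* $z \le 2$ (non-strict) in the control line.

The asymmetric strict/non-strict boundary is deliberate: a compound
sitting exactly at $z = 2$ in the control line still *passes* the
control filter, while $z = 2$ in a cancer line is *not* a hit. Ordered
outputs break ties by compound id so reruns are byte-identical. No
robust-z, B-score or plate-edge correction is applied in this version;
the normalization assumes spatially unbiased plates.

**A consequence worth knowing about.** Because the z-denominator is the
SD of the whole library *including* the actives, any real (or planted)
actives inflate $s_\ell$ and attenuate every standardized effect. With
~3–4% of compounds shifted by 3.5 noise-SDs, the mixture SD is ~1.18
noise-SDs, so a planted 3.5-SD hit standardizes to $z \approx 2.9$
rather than 3.5, and the conjunction over two or more cancer lines
compounds the per-line miss probability. Recovery of planted hits at the
default design is therefore partial (roughly three quarters of planted
selective hits are recalled, as the end-to-end recovery test measures),
while the false-positive rate stays far below 1%. Screens that need
higher sensitivity should raise the planted/expected effect size, lower
the threshold, or move to a robust (median/MAD) standardization — an
extension point, not a default.

# Secondary screen and superiority

Confirmed-hit plates are normalized identically; per compound and line
the replicate mean and SEM of inhibition are reported (default
triplicate). A compound is *superior to the positive control* when its
mean inhibition, averaged without weights over the three cancer lines,
strictly exceeds the same statistic for the cisplatin wells. Whether
superiority should be averaged or required per line is genuinely open;
both are implemented (`perLine = TRUE`), averaged is the default because
a single resistant line should not veto a broadly superior compound at
this stage — the dose-response stage re-examines each line separately.

# Four-parameter logistic fitting

Dose-response curves are fitted with the declining-viability 4PL

$$v(d) = bottom + \frac{top - bottom}{1 + (d/IC_{50})^{hill}}$$

by least squares on log10-dose (`minpack.lm` Levenberg–Marquardt),
parameterized in $\log_{10} IC_{50}$ so the dose scale is handled
symmetrically and the IC50 standard error is natural on the log scale.
Constraints: $bottom \ge 0$, $top \le 1.2$ (tolerating super-control
noise), $hill \in (0, 10]$, $\log_{10} IC_{50}$ within the observed
log-dose range ±2. Initialization is multistart — the midpoint starts at
every distinct observed dose plus the grid centre, the Hill slope at
0.5/1/2, asymptotes at the extreme-dose means — and the lowest-deviance
successful fit wins. Requirements: at least four distinct positive
doses.

Failure is a *state, not an exception*: a flat curve, an optimizer
failure on every start, a non-finite standard error, or a fitted window
$top - bottom \le 0.1$ viability units (an effect too small to resolve
against assay noise) all yield `converged = FALSE`.

Two conventions deserve note. The reported IC50 is the **relative
EC50** — the curve midpoint, satisfying $v(IC_{50}) =
(bottom + top)/2$ exactly — not the absolute 50%-viability crossing;
this is the parameter convention of standard dose-response software, and
the two coincide only when $bottom = 0$ and $top = 1$. And the response
is viability, not inhibition, so `top` is the healthy asymptote.

`ic50WithCI()` gives a Wald interval on $\log_{10} IC_{50}$ with a $t$
quantile on $n - 4$ degrees of freedom, back-transformed. Monte-Carlo
checks in the test suite put coverage a little below the nominal 95%
(≈93–94% at the default design): the `bottom` asymptote frequently sits
on its boundary, which the Wald approximation ignores. Treat the
interval as a good summary of order-of-magnitude uncertainty, not an
exact frequentist guarantee.

How well is a single IC50 determined? At the default design — 8
log-spaced doses spanning 0.01–100 µM, triplicate, viability noise
SD 0.05 — the confidence intervals make the answer visible: a single
curve determines its midpoint only to roughly ±10–30%, because the Hill
slope and asymptotes trade off against the midpoint. Averaging fits over
replicate experiments tightens this quickly; precise potency comparisons
should replicate curves, not wells.

# Candidate triage

Exclusion criteria are **data, not code**: an ordered table of
`flag → reason` rules (first match wins, unmatched hits become
candidates). The shipped defaults encode two common post-screen expert
judgments — a hit whose drug class is already in clinical use for the
disease is redundant (`topoisomerase_class → class_in_clinical_use`),
and cardiac glycosides carry unacceptable cardiac risk
(`cardiac_glycoside_class → cardiac_toxicity_class`). Because the rules
are a plain data.frame, the engine transfers to any other screen's
judgments unchanged. Every hit must be annotated; a missing annotation
is an error, not a silent candidate.

# Downstream validation statistics

**qPCR.** Relative expression uses the ΔΔCt (Livak) method with
amplification efficiency fixed at 2.0: per condition
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{reference}$ (GAPDH
reference by default), $\Delta\Delta Ct = \Delta Ct_{treated} -
\Delta Ct_{control}$, fold $= 2^{-\Delta\Delta Ct}$. No
standard-curve efficiency correction is applied — appropriate when no
efficiency data exist; efficiency-corrected quantification would need
per-assay standard curves. Replicate spread propagates to a standard
error on the log2 fold change as the quadrature sum of the four
per-gene, per-condition SEMs. The construction is invariant to any
per-sample additive Ct shift applied to all genes — that is precisely
what the reference gene is for.

**Tumor volume.** The modified ellipsoid formula
$V = L \times W^2 \times 0.5$ (mm³) with the caliper pair canonicalized
first (length = larger): the formula is orientation-sensitive and field
recordings swap axes. Growth curves are compared per timepoint with the
two-sample test below; timepoints are opaque ordered labels.

**Group comparison.** The classical equal-variance Student's t-test,
two-sided, significance at $p < 0.05$ with `*`/`**`/`***` tiers; Welch's
correction is available behind a flag but is not the default because the
equal-variance form is the stated convention of this analysis style. No
multiple-testing correction is applied across timepoints or markers by
default (mirroring common practice in this literature); `adjust =
"holm"` switches it on. Identical groups give $t = 0$, $p = 1$; two
constant groups are a degeneracy error rather than an infinite
statistic.

# The synthetic-data generators

The generators exist so that every pipeline stage can be validated
against known truth. They emulate the *structure* of the screen, not any
particular instrument:

* **Library/plates** (`generateLibrary()`, `simulatePrimaryPlates()`):
  viability is simulated directly on the normalized fraction scale —
  inert compounds $\sim N(1, \sigma)$ truncated at 0 — and mapped to OD
  by the invertible affine map $OD = OD_{blank} + v\,(OD_{DMSO} -
  OD_{blank})$, which exercises the normalizer without obscuring truth.
  Planted selective hits are shifted down by `effectSizeSd × noiseSd` in
  a random subset of the cancer lines (subset size uniform on {2, 3},
  matching the "at least two cancer lines" rule's combinatorics);
  pan-toxic plants shift in all four lines and exist to prove the
  control-line filter rejects them. Plates are 96-well: column 1 DMSO,
  column 12 blanks, 80 compounds in between, one line per plate.
* **Dose-response** (`simulateDoseResponse()`): 4PL mean plus Gaussian
  noise, truncated to plausible viability; default 8 log-spaced doses
  0.01–100 µM in triplicate.
* **Tumor growth** (`simulateTumorGrowth()`): per-animal exponential
  growth with log-normal measurement noise; treatment scales the growth
  rate by $1 - effect$. Caliper pairs are emitted so the ellipsoid
  formula recovers the simulated volume exactly.
* **Ct panels** (`simulateCtPanel()`): reference gene centred
  identically in both conditions; a fold change $f$ moves the treated
  target Ct by $-\log_2 f$ cycles.

Defaults and why: `noiseSd = 0.1` viability — a 10% well CV, typical of
a colorimetric viability assay without extensive replication;
`effectSizeSd = 3.5` — comfortably above the $z > 2$ calling threshold
yet close enough that misses occur under noise, making sensitivity a
meaningful statistic rather than a tautology; 40 selective + 10
pan-toxic plants in 1,271 — a few percent actives, as in real
repurposing screens; tumor study n = 5 per arm, measurements every 2
days to day 14, growth rate 0.18/day, effect 0.6, log-noise SD 0.15 —
representative of a subcutaneous xenograft experiment of this size;
qPCR noise 0.15 cycles per well. The raw noise level and plate layout of
any particular historical screen are not published, so these defaults
are explicitly synthetic choices, fixed once, not calibrated to an
external dataset.

All generators are seeded and restore the caller's RNG state; identical
spec + seed gives byte-identical output. `simulatePrimaryPlates()`
accepts a `noiseSd` override so the noiseless limit can be exercised
while the planted shifts (sized from the `LibrarySpec`'s noise SD)
remain nonzero.

What they deliberately do **not** emulate: plate spatial/edge artifacts,
evaporation gradients, inter-plate batch drift, compound
autofluorescence or assay interference, RNA-seq counts, or image-level
IHC data (only the numeric positive fractions that segmentation software
emits are consumed). Passing recovery tests on synthetic screens
therefore demonstrates the *statistical* machinery under the stated
noise model — not robustness to the spatial and chemical artifacts of
real plates, which would require the edge-correction extensions noted
above.

# Validation design and problem sizes

The test suite validates each stage against independent oracles: an
exhaustive re-evaluation of the selectivity rule on small random
screens, a hand-coded pooled-variance t-test, closed-form 4PL identities
(midpoint, asymptotes, dose-unit equivariance), and noiseless
self-consistency (random admissible 4PL parameter draws recovered to
1e-4 relative). End-to-end studies use the full default design: 50-seed
IC50 recovery at true midpoints of 1.55/1.16/0.96 µM, 20-seed hit
recovery on 1,271-compound screens, 200-curve CI coverage, and ≥1,000
null growth-curve tests for type-I calibration (empirically ≈0.05, as it
should be, since under the null both arms share one generating law).
These sizes were chosen to make each statistic stable to well under its
decision margin while keeping the whole suite quick on a laptop.

# Known limitations

* Library-SD inflation by actives attenuates z-scores (see above); the
  mean/SD convention is kept because it is the field's default, and a
  robust variant is the natural first extension.
* Single-curve IC50 estimates at the default noise level carry ~10%
  relative uncertainty with heavier tails; per-curve errors of 20–30%
  occur at realistic rates. This is an identifiability property of the
  free 4PL at this design, not an optimizer deficiency — the multistart
  least-squares estimate is already at the information bound.
* Wald CIs on log IC50 under-cover slightly when asymptotes sit on their
  constraints; profile-likelihood intervals would be the upgrade.
* The equal-variance t-test on raw (log-normal-ish) tumor volumes is
  mildly non-normal at n = 5; calibration holds at the simulated noise
  level, but heavier-tailed measurement error would favour testing log
  volumes.
* No plate-effect modelling: the normalizer assumes controls on the same
  plate are exchangeable with sample wells.
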