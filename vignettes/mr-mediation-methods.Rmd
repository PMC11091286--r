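---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

Two-sample MR works entirely on GWAS summary statistics. For SNP $j$,
let $\hat\gamma_j \pm \sigma_{xj}$ be its estimated per-allele effect
on the exposure and $\hat\Gamma_j \pm \sigma_{yj}$ its effect on the
outcome, estimated in non-overlapping samples. If SNP $j$ is a valid
instrument — associated with the exposure, independent of confounders,
and affecting the outcome only through the exposure — then the Wald
ratio $\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal
effect $\theta$. Binary traits are handled on the log-odds scale; the
package never touches individual-level likelihoods.

The package treats $\sigma_{xj}$ as negligible when weighting (the
standard no-measurement-error approximation), so
$se(\hat\theta_j) = \sigma_{yj}/|\hat\gamma_j|$ and the
inverse-variance weight is $w_j = 1/se(\hat\theta_j)^2$.

## Estimators

- **IVW**: $\hat\beta = \sum w_j\hat\theta_j / \sum w_j$, identical to
  the weighted through-origin regression of $\hat\Gamma_j$ on
  $\hat\gamma_j$ with weights $1/\sigma_{yj}^2$. The fixed-effect SE is
  $(\sum w_j)^{-1/2}$; the default *multiplicative random-effects*
  model inflates it by $\max\{1, \sqrt{Q/(J-1)}\}$ with $Q$ Cochran's Q
  at the point estimate, so between-instrument heterogeneity widens but
  never narrows the interval. The floor at 1 means the model never
  claims less than sampling variance. Source studies rarely state which
  variance model they used; this default matches the most common
  practice for more than a handful of instruments, and `model =
  "fixed"` is available.
- **MR-Egger**: weighted least squares of $\hat\Gamma_j$ on
  $\hat\gamma_j$ *with* an intercept; the intercept absorbs directional
  pleiotropy (and testing it against zero is the pleiotropy
  diagnostic), the slope estimates $\theta$ under the InSIDE
  assumption. Instruments are re-oriented internally so all
  $\hat\gamma_j > 0$, as the estimator requires; the caller's data are
  never mutated. Inference uses $t_{J-2}$, with the residual scale
  floored at 1 as above.
- **Weighted median**: the ratios are ordered and the midpoint
  cumulative weight function $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum w$
  is interpolated linearly at $1/2$; consistent when valid instruments
  carry more than half the weight.
- **Weighted mode**: the maximizer of a weighted Gaussian kernel
  density over the ratios; consistent when the largest cluster of
  agreeing instruments is valid. The bandwidth rule is fixed and
  versioned: $h = f \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,
  J^{-1/5}$ over the ratios, with `bandwidth_factor` $f = 1$ by
  default. The maximizer is located by a 2048-point grid, bracketed
  `optimize()`, and a short Newton polish on the analytic density
  derivative, so it is reproducible to full double precision.
- **Multivariable IVW** (`mvmr_ivw()`): no-intercept weighted
  regression of outcome effects on a matrix of exposure effects,
  giving each exposure's *conditional* direct effect. An exposure
  column that is identically zero carries no information and is
  excluded from the design (its estimate reported as degenerate)
  rather than making the fit singular; genuinely collinear exposures
  are an error.

Median and mode standard errors come from a parametric bootstrap:
exposure and outcome effects are redrawn from their normal sampling
distributions and the estimator recomputed (`n_boot = 1000` by
default). Seeds are mandatory arguments everywhere randomness enters —
there is no hidden global-RNG default — and the bootstrap restores the
caller's RNG state. The 95% interval multiplier is fixed at 1.959964
across all methods for cross-method consistency.

## Instrument selection

Selection runs significance filtering (strictly below
$5\times10^{-8}$ by default), greedy LD clumping, blocklist exclusion,
then F screening, each recording before/after counts in provenance.

The clumping rule prunes any SNP lying within 10 Mb of an
already-accepted, more significant SNP on the same chromosome whose
pairwise $r^2$ is at or above 0.001 — the strict conventional setting,
read as "independent means $r^2 < 0.001$ within 10 Mb". No LD
reference panel is bundled: LD comes from a user-supplied pairwise
table or matrix (`read_ld_table()`), or, when absent, proximity alone
prunes (distance-only clumping). P-value ties break by rsID so results
are deterministic.

Two F-statistic formulas are offered because source descriptions vary:
`ratio`, $F_j = (\hat\gamma_j/\sigma_{xj})^2$, needs only the printed
effect and SE; `r2_based` works from the explained variance
$R^2_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\hat\gamma_j^2$ as
$F_j = R^2_j (n-k-1) / (k(1-\sum R^2))$ and needs the sample size and
allele frequencies. The default is `ratio` since it is computable from
any summary-statistics file; both label the report with the formula
used, and neither is claimed to reproduce any particular published F
value.

## Harmonization

Exposure and outcome records are joined by rsID (the instrument tables
this package mirrors are keyed by rsID; positions, 1-based throughout,
are carried for interval operations). Outcome alleles listed in the
reverse order have their beta negated and frequency complemented;
non-palindromic mismatches are retried after strand complementation
(switchable off). Palindromic SNPs (A/T, C/G) carry no strand
information, so orientation is inferred from allele frequency: the
pair is kept only when both studies' frequencies fall on the same side
of 0.5 **and** both minor-allele frequencies are below
`palindrome_eaf_limit` (default 0.42). Requiring *both* sides below
the limit is this package's unambiguity rule — a deliberately
conservative reading, since a palindromic SNP near 0.5 on either side
cannot be oriented reliably. Dropped SNPs stay in the output table
with their disposition (`dropped_palindromic`,
`dropped_incompatible`), so every instrument is auditable, but carry
no effect values downstream.

Harmonization is idempotent, and re-coding an input's effect allele
(swap alleles, negate beta, complement frequency) leaves every
downstream estimate unchanged to machine precision — both properties
are asserted in the test suite.

# Sensitivity diagnostics

**Cochran's Q** at an estimate $\hat\beta$ is
$\sum_j w_j(\hat\theta_j - \hat\beta)^2$ on $\chi^2_{J-1}$; at the
fixed-effect IVW estimate it equals the weighted regression residual
sum of squares (asserted numerically in the tests).

**MR-PRESSO** compares the observed
$\mathrm{RSS} = \sum_j (\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2$
— with $\hat\beta_{(-j)}$ the fixed-effect IVW excluding SNP $j$ — to
a parametric null: each simulation redraws exposure effects about
their observed values and outcome effects about the leave-one-out
predictions, with the observed SEs. The global p-value uses the
add-one Monte-Carlo estimator $(1 + \#\{\mathrm{sim} \ge
\mathrm{obs}\})/(n_{\mathrm{sim}}+1)$, which can never be exactly
zero; per-SNP residual terms are tested the same way and
Bonferroni-adjusted (configurable) at `outlier_alpha = 0.05`. When
outliers are flagged, the outlier-removed IVW estimate is reported
together with a descriptive percent change from the uncorrected
estimate — no distortion p-value is attached, since a single percent
change is the honest summary at these instrument counts. Defaults
($n_{\mathrm{sim}} = 1000$, Bonferroni, $\alpha = 0.05$) follow common
use of the method; results are reproducible bit-for-bit from
`(set, n_sim, seed)`.

**Leave-one-out** re-estimates with each SNP omitted and marks an
omission *influential* when the re-estimate leaves the full-set 95%
interval or flips sign. For outlier hunting the comparison interval
should be the fixed-effect one (`leave_one_out(set, model =
"fixed")`): an outlier inflates the multiplicative random-effects
scale of the full-set fit and can thereby mask its own influence.

**Reverse MR** reruns the identical pipeline with the roles exchanged.
A former outcome without genome-wide-significant instruments yields a
structured `"no-instruments"` result rather than an error — the honest
statement that no reverse claim can be evaluated.

# Two-step mediation

With $\hat\beta_a \pm s_a$ the exposure→mediator effect (IVW on the
exposure's instruments) and $\hat\beta_b \pm s_b$ the
mediator→outcome effect (by default conditional on the exposure via
multivariable IVW on the mediator's own instruments, since that is the
appropriate second-step estimand; univariable is available for
comparison):

$$\mathrm{IE} = \hat\beta_a\hat\beta_b,\qquad
  \mathrm{DE} = \mathrm{TE} - \mathrm{IE},\qquad
  \mathrm{prop} = \mathrm{IE}/\mathrm{TE},$$

with the Sobel delta-method SE
$\sqrt{\hat\beta_b^2 s_a^2 + \hat\beta_a^2 s_b^2}$ (the second-order
$s_a^2 s_b^2$ term is a configuration toggle, off by default, since
first-order is the conventional reported form) and
$se(\mathrm{prop}) = \sqrt{se(\mathrm{IE})^2/\mathrm{TE}^2 +
\mathrm{IE}^2\,se(\mathrm{TE})^2/\mathrm{TE}^4}$, treating IE and TE
as independent. That zero-covariance assumption reflects the
two-sample design — the step estimates come from separate GWAS — and
is stated here rather than hidden. The identity
$\mathrm{IE} + \mathrm{DE} = \mathrm{TE}$ holds exactly (it defines
DE), and every emitted result is checked for it. A zero total effect
makes the proportion undefined (flagged, not an error); a proportion
outside $[0,1]$ is reported with an `inconsistent-mediation` flag,
because suppressing such rows would bias any screen built on them.

`mediation_screen()` runs this for a panel of candidate mediators and
passes a candidate when the step-one, step-two and indirect-effect
p-values are all below 0.05. No multiplicity correction is applied
across candidates by default — mirroring how such screens are
conventionally reported — but `adjust` accepts any `p.adjust` method.
In step two the exposure's effects at the mediator's instruments are
themselves harmonized to the instrument set's allele coding before
entering the multivariable design; SNPs absent from the exposure GWAS
enter with a zero exposure effect, and an all-zero exposure column
falls back to the univariable estimate by construction.

# The synthetic generator

`simulate_pair()` emulates the statistical structure of the study
datasets the package is designed around, and its defaults *are* those
conditions: 11 instruments; exposure GWAS $n = 154{,}780$ (the
instrument discovery study for the pregnancy cholestasis phenotype);
outcome GWAS $n = 484{,}598$ (the cardiovascular outcome panel);
mediator GWAS $n = 115{,}082$ (the lipid panel); true causal log-OR
$\theta = 0.004$; and SNP–exposure effects
$\gamma_j \sim N(0, 0.65^2)$, matching the spread of the published
instrument effects (0.24–1.96 in absolute value). Allele frequencies
are uniform on $(0.05, 0.95)$; observed effects are drawn from
$N(\mathrm{truth}, se^2)$ with the single-SNP GWAS standard error
$se = 1/\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})\,n}$ for a
unit-variance trait, applied on the log-odds scale for binary traits
— the estimators consume only summary statistics, so this normal
sampling model is the right level of fidelity. Emitted p-values are
floored at the smallest normalized double so they survive a text
round trip.

Design choices worth stating:

- **No LD between instruments** — the generator emulates the
  *post-clumping* state. A block-correlation mode is not needed for
  any estimator test; clumping is tested against explicit r² matrices
  instead.
- **Harmonization stress is label-only.** A configurable fraction of
  records is emitted with swapped alleles, and palindromic allele
  pairs are assigned only to SNPs whose MAF is already unambiguous, so
  the stressed and unstressed generations share identical sampled
  numbers and harmonized estimates agree to 1e-12 — a strong
  round-trip test.
- **Pleiotropy** (`balanced` or `directional`) adds offsets
  $\alpha_j$ to a stated fraction of instruments; the InSIDE-violating
  case is available to *demonstrate* estimator bias, not to correct
  it.
- `simulate_mediation()` gives the mediator its own disjoint
  instruments $\delta_k$ with effects $\beta_b\delta_k$ on the
  outcome, while exposure instruments act with slope
  $\beta_a\gamma_j$ on the mediator and
  $(\mathrm{direct} + \beta_a\beta_b)\gamma_j$ on the outcome, so the
  implied total effect is recoverable by construction.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: LD between instruments and proxy
lookup, winner's curse in instrument discovery, sample overlap between
GWAS, population stratification, and case-control ascertainment
effects beyond the log-odds approximation. Conclusions about those
belong to the source studies, not to this package's test suite.

# Numerical choices

- P-values from z-scores are computed on the log scale
  (`pval_from_effect()`), so values far below 1e-300 remain
  representable; a `log10` mode covers the rest of the range.
- Monte-Carlo p-values use the add-one estimator (never zero).
- Clumping and weighted-median ties are broken deterministically
  (rsID order; midpoint cumulative weights).
- Stage seeds derive from the master seed by a fixed affine scheme
  (`split_seed()`), so any stage can be re-run in isolation; all
  derived seeds stay below $2^{31}-1$.
- Display formatting is half-even to 3 decimals, with scientific
  notation below 0.001, matching the conventional table style
  (`2.952E-04`).

# Problem sizes in the test suite

The suite exercises calibration at sizes chosen to give stable
empirical rates while remaining desk-scale: 50 instruments at GWAS
$n = 10^5$ over 200 seeds for IVW bias (observed mean bias below
0.01), type-I error (within [0.03, 0.08] at the 5% level) and interval
coverage; 500 replicates for Egger intercept null calibration
(rejection at or below 8%); 30 instruments with a planted 10-SE
outlier for the MR-PRESSO and leave-one-out checks; and $10^6$-draw
Monte-Carlo oracles for the delta-method SEs. Estimator point
estimates are checked against independent brute-force oracles
(explicit normal equations, cumulative-weight interpolation, dense
grid search plus derivative root) to 1e-10 on small hand-set
instances.

# Interface note

The package's surface is its R functions — `run_study()` over a
`study_config()` for the orchestrated pipeline, and the per-stage
functions for interactive work. All file outputs are plain TSV/JSON.
A shell wrapper would add nothing over
`Rscript -e 'mrmediate::run_study(...)'`, so none is shipped.

# Known limitations

- LD is consumed, never computed: no reference panels, no proxy SNPs.
- No MR-RAPS, contamination mixture, radial MR, or Steiger filtering.
- Mediation is single-mediator per decomposition; joint multi-mediator
  models are out of scope.
- The `r2_based` F formula is one published convention among several;
  when comparing to a specific study, confirm which formula it used.
- Reverse MR inherits all forward assumptions; a `"no-instruments"`
  reverse result is absence of evidence, not evidence of absence.
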