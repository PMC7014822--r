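---
title: "Benchmark-dose models and point-of-departure estimators in tgxpod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose models and point-of-departure estimators in tgxpod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgxpod)
```

tgxpod implements the dose-response inference stack used to set a point of
departure (POD) for a short-term rodent toxicogenomics study: benchmark-dose
(BMD) modeling of continuous apical endpoints with a sex-by-time covariate,
per-gene transcriptomic BMD modeling with a filter cascade and a battery of
POD aggregation strategies, and a DEG-count estimator (D1/D1*) that asks at
what dose fewer than one gene is expected to pass a K-fold differential
expression threshold. This vignette records the models, their assumptions,
and the numerical and design choices behind the implementation.

## Apical benchmark-dose model

`fit_bmd()` fits the two continuous model families used throughout European
regulatory BMD practice, written as a background level `a` times a relative
response `f(x)` with `f(0) = 1`:

* exponential family: `f(x) = 1 ± γ(1 − e^{−b x^d})`, with the unbounded
  reduced forms `e^{±bx}` and `e^{±b x^d}` nested below it;
* Hill family: `f(x) = 1 ± γ x^d / (b^d + x^d)`.

Here `γ = |c − 1|` is the fold-range between background and plateau, `b` the
potency, and `d ≥ 1` the shape (the lower bound is the usual constraint that
avoids infinite slope at dose zero; the upper bound defaults to 4).
Responses are treated as lognormal: the likelihood is normal on log
responses with a constant log-scale variance per variance stratum. Summary
input (n, mean, SD per group) is converted to log-scale sufficient
statistics through the exact lognormal moment relations, so a fit from group
summaries reproduces the fit from the individual animals that generated
them up to the second-order accuracy of that conversion (tested at ≤0.5%).

Within a family the sub-model (E2/E3/E4/E5, or H4/H5) is chosen by lowest
AIC with ties going to fewer parameters. This sub-model set is our choice:
the field's convention names only the two families, and the nested set
mirrors common PROAST defaults.

The BMD at benchmark response (BMR) `q` solves `|f(BMD) − 1| = q`; all
sub-models invert in closed form. The default BMR is 10% relative change,
the conventional choice for these endpoints.

**Covariate structure.** A combined sex-by-duration label ("study") can sit
on the background (`a`), the residual variance, and/or the potency (`b`).
The default is background plus variance; potency is allowed to vary with
the covariate only when doing so improves AIC by more than 2. When it does,
each covariate level has its own BMD and the reported POD takes the
extremes (lowest BMDL, highest BMDU) across levels and families, matching
the lowest-of-families reporting rule.

**Confidence bounds.** BMDL and BMDU are profile-likelihood bounds: the
model is reparameterised so the BMD is an explicit parameter (substituting
`b` by its closed-form expression in the BMD), and each bound is the
extreme BMD whose profiled deviance stays within `χ²₁(0.90) ≈ 2.706` — a
two-sided 90% interval, i.e. one-sided 95% per bound, the standard
BMDL/BMDU convention. The profile is scanned geometrically outward from the
MLE and the crossing refined by root-finding; the inner re-optimisation
warm-starts from the previous profile solution. A bound that runs past
50× the highest tested dose is reported unbounded and flagged, as is a BMD
above the tested range. The profile machinery is validated against a dense
two-parameter grid enumeration (background and variance profiled
analytically) at a 1% tolerance.

**Exclusion gates.** Series-level gates are explicit, never silent:
`bartlett_gate()` flags a series with heterogeneous within-group variances
(p ≤ 0.05), and `grubbs_test()` flags at most one outlying animal
(two-sided, single pass). When only printed group summaries are available,
`outlier_adjust_summary()` removes a known outlying value from an
(n, mean, SD) summary by exact moment algebra. `apical_pod()` wires these
together for the bundled study tables: the female day-8 Ki67 series is
excluded, the flagged male day-29 animal (37.5% labeling index) is removed
from its group summary, and both families are fit at BMR 10%.

**SD versus SE.** The bundled tables store the printed `mean ± dispersion`
values verbatim with a configurable interpretation flag. The default reads
them as SDs: the male day-29 top-dose entry (10.31 ± 13.35 with a stated
maximum individual value of 37.5%) is arithmetically impossible as an SE of
n = 6, while it is exactly consistent with an SD that includes the outlier.
Both interpretations remain selectable because the source tables never say.

## Per-gene transcriptomic BMD

`gene_bmd()` models each gene's log2 expression against dose with six
candidate mean functions — linear, quadratic, cubic, power
(`β₀ + β₁x^δ`, `δ ≥ 1`), Hill (`β₀ + v x^h/(k^h + x^h)`), and exponential
(`α e^{βx}`) — by least squares with constant normal error. Genes must
first pass a raw-count prefilter: a strictly positive count in every
replicate at every dose, with no fallback to log values.

Model selection is hierarchical: within the nested polynomial chain the
simplest model not rejected by a nested F-test (α = 0.05) is retained; the
chain winner then competes with power, Hill and exponential on lowest AIC.
A Hill winner whose half-maximal dose falls below one third of the lowest
positive dose is flagged and demoted — such fits place all their action
below the observed dose range. Exact ties go to fewer parameters, then a
fixed model-name order. These rules follow the BMDExpress2 convention; the
original study's selection procedure lives in an unpublished report, so the
convention is documented here as an interpretation.

The gene-level BMR is 1.349 residual standard deviations — the offset
equivalent, under a normal response, to a 10% tail shift relative to
control. σ is the model residual SD (not the control-group sample SD),
configurable. The BMD solves `|y(x) − y(0)| = 1.349σ̂` in closed form where
the model admits one; polynomial BMDs take the smallest positive real root.
Profile bounds reuse the reparameterised-deviance approach with the
benchmark offset held at the best fit's `1.349σ̂` while mean parameters are
re-profiled and the variance is concentrated analytically — the common
treatment of σ in this BMR definition, which keeps the profile
one-dimensional in the BMD.

Four filter rules — goodness-of-fit p > 0.1 (lack-of-fit F against the
saturated group-means model), BMDU/BMDL < 40, BMD within the tested range,
and observed max |fold change| ≥ 1.5 from the companion DE table — form a
pure conjunction, so the cascade is order-independent; each rule's verdict
is recorded per gene. Fold changes are observed, not modeled: the source
convention is ambiguous, and the observed choice keeps the filter
independent of the fitted curve. Profile bounds are computed for genes
that pass the other three rules; a gene already excluded fails regardless
of its interval width.

## POD aggregation

`fisher_enrichment()` scores gene sets by the one-tailed hypergeometric
over-representation p-value of the surviving genes against a universe that
defaults to the prefiltered gene list (the set of genes that could have
survived). p-values are uncorrected by default, matching the study's stated
practice; a BH option exists but is off. A set is reported when p ≤ 0.1 and
at least 10 surviving genes overlap it.

`aggregate_pod()` implements the nine text-attested aggregation strategies
(all-gene median; 20 lowest-BMD genes; 20 most induced, most repressed, or
largest-|FC| genes; per-pathway medians; the 20 most sensitive pathways;
the single most sensitive pathway; pathways common to all datasets, with
the per-dataset medians averaged arithmetically). The registry is a simple
switch, so further variants are one-line additions. Selection ties break
by FDR then gene id. `concordance_report()` classifies each estimate's
(BMDL, BMDU) interval against the apical interval as below, spanning, or
above, with closed-interval endpoints.

## The DEG-count estimator (D1/D1*)

For each fold-change threshold K, the number of genes with |FC| ≥ K and
FDR ≤ 0.05 at each positive dose is fit with the fixed-plateau Hill curve
`Count = C / (1 + (d50/dose)^n)`, `C = 1000`, by iteratively reweighted
least squares with Poisson inverse-variance weights `w = 1/max(μ̂, 1e−6)`.
The control dose is excluded: the model is undefined at dose 0 and the DEG
count there is identically 0. The plateau is exposed as a parameter — the
value 1000 plausibly reflects this study's DEG plateau rather than a
universal constant.

The inner weighted fit is a damped Gauss-Newton step on (log d50, log n),
vectorised so that thousands of bootstrap refits run as matrix operations.
The outer weight iteration runs to a relative parameter change below 1e−8
(at most 100 iterations); after the first ten iterations the weight update
is relaxed by half, which preserves the fixed point while suppressing the
two-cycles plain IRLS falls into when a count overshoots the fixed plateau.
Curves whose counts sit at or above the plateau at every dose are rejected
as unidentifiable, and a fit that still fails to settle is reported
non-converged rather than returning a bogus estimate.

D1, the dose at which a single gene is predicted differentially expressed,
inverts the fitted curve in closed form: `D1 = d50 (C − 1)^{−1/n}`. Its
lower one-tailed 95% bound D1* is a parametric bootstrap: counts are drawn
Poisson about the fitted curve, each replicate is refit with the weights
frozen at the inverse of the original fitted responses (the documented
estimator; a full-IRLS-per-replicate option exists for sensitivity
analysis), inverted to D1, and the 5th percentile of the sorted sample is
D1*. Non-convergent replicates are resampled up to a doubling of the draw
budget so the percentile sample size stays fixed; more than 5% failures is
a hard error. The default 10,000 replicates run in well under a second.

## Synthetic data: what it emulates and what it does not

`study_design()` defaults to the emulated study: doses 0, 300, 500, 750,
1000, 1500 mg/kg/day, six animals or replicates per group.
`simulate_apical_series()` draws individual responses as curve mean times
multiplicative lognormal noise with unit mean; the default CV of 25% is a
typical within-group spread for endpoints like a labeling index. The
analytic BMD of every generating curve is attached, and on noise-free data
the fitted BMD reproduces it to ≤0.1%.

`simulate_expression_study()` places a configurable fraction of genes
(default 10%, a plausible responsive fraction for a hepatotoxicant at
these doses) on monotone Hill-shaped curves on the log2 scale. Each
responsive gene draws a true BMD (log-uniform over 100–1200 mg/kg/day) and
a top-dose |log2FC| (uniform over 0.8–3); the curve is calibrated so the
change equals the drawn fold change exactly at the top dose and exactly
1.349 × the generating noise SD (default 0.25 log2 units) at the drawn
BMD, so both recorded truths are precisely the quantities the pipeline
estimates. The minimum Hill exponent is 2, raised per gene when the drawn
pair needs a steeper curve. `make_deg_table()` closes the loop with a
Welch t-test on log2 values and BH correction within dose — a deliberately
simple stand-in that is not, and does not emulate, count-based
differential-expression inference.

The generator therefore does not model: sequencing depth, count overdispersion
beyond the optional Poisson layer, correlation between genes, batch or
library-size effects, or non-monotone responses. Passing the closed-loop
tests shows the estimators recover the truth under the stated noise model;
it does not certify behaviour under real RNA-seq artefacts.

## Problem sizes and numerical settings

The test suite exercises: parameter recovery and one-sided 95% BMDL
coverage over 50 simulated studies at the study design with 25% CV;
gene-level recovery on 2,000 genes (10% responsive) plus 20 smaller-scale
replicate studies; D1* coverage over 200 outer replicates at 1,000
bootstrap draws; FDR control over 100 null simulations; and goodness-of-fit
uniformity over 200 seeds. Optimiser settings: multi-start bounded
quasi-Newton (`nlminb`) over log-transformed parameters with a log-spaced
potency grid; 1-D concentrated searches use `optimize()` with tolerances
tightened to ~1e−7 of the parameter scale (the default tolerance is far too
coarse for rate parameters of order 1e−3); profile crossings are refined to
~2e−4 relative. All randomness flows from explicit integer seeds.

## Known limitations

* The apical likelihood treats printed summary dispersions as exact
  sufficient statistics under the lognormal moment conversion; with very
  large CVs the conversion's second-order error grows.
* Profile bounds assume a locally unimodal profile; a profile irregular at
  the MLE is reported as missing bounds, not guessed.
* The gene-level polynomial profile substitutes one root of the benchmark
  equation; for non-monotone cubic fits the profiled bound can refer to a
  different crossing than the reported BMD. Monotone generators make this
  rare, and such fits seldom survive the filter cascade.
* Plain IRLS on DEG counts far above the fixed plateau can cycle; the fit
  then reports non-convergence. Choosing a plateau nearer the observed
  top-dose count avoids the regime.
* The D1* bootstrap follows the documented frozen-weight refit; it is not a
  full accounting of weight-estimation uncertainty (the IRLS-per-replicate
  option quantifies the difference).
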