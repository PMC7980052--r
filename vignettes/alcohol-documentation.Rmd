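---
title: "Methods: phenotyping alcohol documentation in primary-care EMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping alcohol documentation in primary-care EMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcodoc)
```

## The problem

Primary-care EMRs record lifestyle risk factors — alcohol among them — as
semi-structured free text in a dedicated risk-factor table. Whether a
patient has *any* alcohol entry is itself an outcome of clinical behaviour:
providers decide whom to ask. Studying that documentation gap requires
three steps, each implemented here as a tested module:

1. **Phenotyping**: map each free-text entry to a consumption category
   anchored in the Canadian low-risk drinking guidelines.
2. **Cohort construction**: eligibility filtering and covariate
   derivation, one analysis-ready row per patient.
3. **Modelling**: provider-clustered marginal logistic models of (a)
   having any alcohol documentation and (b) being at heightened risk of
   alcohol-related problems (heavy or past drinker), reported as odds
   ratios with 95% confidence intervals.

Because sentinel-network EMR extracts cannot be redistributed, the package
also ships a synthetic multi-table generator with known ground truth; all
properties of the pipeline are established against it.

## The classifier

Six labels partition the documented patients: `NONE`, `LIGHT`, `MODERATE`,
`HEAVY`, `PAST`, `UNKNOWN`. Consumption bands follow the guideline
anchoring: light is under 3 drinks a week, moderate 3–15 inclusive at both
ends, heavy strictly more than 15. The boundary semantics matter only at 3
(the printed definitions "\<3" and "3–15" force 3 into moderate) and at 15
(moderate); both are asserted in the test suite.

Decision logic, in precedence order:

1. **Past-use phrases** dominate everything: a note such as "past heavy
   use" classifies as `PAST`, because former drinkers form a distinct risk
   group regardless of historical quantities. The dictionary is seeded with
   the four canonical phrases (*Alcoholics Anonymous*, *recovering*,
   *recovered*, *past*) plus close variants, and lives in a plain-text
   file (`inst/extdata/rules/past.txt`) so a site-specific list can be
   dropped in without code changes.
2. **Quantities.** A small grammar parses
   `<number> [unit] (per|a|/) (week|day|month)`, ranges (midpoint), number
   words up to twenty, and `weekly`/`daily`/`monthly` adverbs. Daily
   quantities are multiplied by 7, monthly by 7/30. A parsed weekly
   quantity of zero is a denial; positive quantities fall into the bands
   above.
3. **Denial phrases** (`non-drinker`, `denies alcohol`, ...) give `NONE`.
4. Everything else — family history, unquantified or social mentions,
   empty text — is `UNKNOWN`.

Negation uses a sentence window: a quantity that shares a sentence with a
denial phrase is voided ("denies alcohol, maybe 10 per week" is a denial),
while quantities in other sentences survive ("denies alcohol. partner
reports 10 drinks per week" is a quantity). There is no dependency
parsing; the sentence window is the entire negation model, and qualifier
constructs like "no more than 2/wk" survive because the denial
dictionary holds full phrases, not the bare token "no".

Patients with several notes are resolved to one label by the
`most-recent` policy: the latest note inside the study window wins, and
exact date ties go to the heavier-risk label (severity order
`UNKNOWN < NONE < LIGHT < MODERATE < HEAVY < PAST`). The source analysis
reports one category per patient without stating its resolution rule;
recency is the choice made here because the models describe current
status, and a `heaviest` policy is available for sensitivity analysis.

The guideline's sex-specific weekly limits (15 male / 10 female) are *not*
used for banding by default — the published category definitions are
sex-agnostic — but `default_rules(sex_specific_bands = TRUE)` exposes the
alternative.

## The synthetic extract: a stated world

The generator emits the five relational tables the analysis touches
(patients, providers, encounters, condition flags, risk-factor text) plus
a truth table. Its defaults are fixed once, from the published cohort's
margins, and are not tuning knobs:

| quantity | default | basis |
|---|---|---|
| P(documented) | 0.406 | published marginal documentation rate |
| category mix | 20.3/41.4/28.9/2.8/1.6/4.9% | published category table with the unclassified share 13,992/284,268 |
| male | 0.429 | pooled sex counts |
| urban | 0.845 | pooled residency counts |
| patient age | N(50.7, 17.6) truncated at 18 | published mean; SD set so the documented/undocumented means (51.9/49.9, SD ~17–18) are plausible |
| provider age | N(49.6, 11.1) | published provider mean/SD |
| family physician | 0.994 | published provider-type share |
| comorbidities | pooled prevalences (e.g. hypertension 0.238, depression 0.184) | published descriptive table |
| visits/patient-year | NB(mean 4.9, size 0.84) | published visit means 4.8/5.0 with SD ~5.8 |

Structure: covariates are drawn independently; documentation is a logistic
model in the derived binary covariates (with provider-level covariates
shared within cluster); conditional on documentation, an entry is
unclassifiable with the fixed `UNKNOWN` probability, and otherwise
heightened risk is a second logistic model (age entering continuously,
centered), with the specific category then drawn proportionally within the
risk and non-risk groups. Intercepts are calibrated numerically
(`uniroot` on the realized linear predictor) so the marginal rates equal
their targets whatever the effect maps say. Effect defaults are the
published adjusted odds ratios of the two models.

Deliberate modelling consequences:

- **Clustering is covariate-induced.** Outcomes are conditionally
  independent given covariates; within-provider correlation arises only
  through shared provider covariates. This keeps the marginal GEE models
  exactly well-specified, so the published effects are recoverable — a
  provider random intercept would attenuate marginal odds ratios relative
  to the conditional ones and make "recovery" ill-defined. The GEE engine
  itself is exercised against positively correlated clusters in its own
  unit tests.
- **Every patient has at least one encounter** (a zero-visit patient gets
  one forced visit) because the cohort definition conditions on an
  encounter; the generator emits the conditioned population directly.
- **Birth dates are anchored** at the patient's last in-window encounter
  so the cohort builder's derived age equals the drawn age exactly.
- `text_noise_rate` defaults to 0: the unclassifiable share of real
  documentation is already represented by the `UNKNOWN` mixture component,
  which the classifier reproduces from family-history/social templates.
  Raising the noise rate garbles rendered notes *without* changing truth
  labels, for robustness experiments only.
- Note templates are an invention (the field's real phrasing distribution
  is unpublished); they cover structured shorthand (`etoh 3/wk`), prose,
  ranges, daily forms and number words, and every clean template must
  round-trip through the classifier — enforced by test, not assumed.

What a green round-trip test establishes is therefore *internal*
consistency: the classifier inverts the generator's rendering exactly on
clean text. It says nothing about recall on real clinical notes, whose
spelling variation, abbreviations and narrative structure the templates do
not emulate.

## Cohort construction

Eligibility: age ≥ 18 with at least one encounter in the half-open window
`[2015-01-01, 2018-01-01)` — half-open because the source phrase "between
January 1, 2015 and January 1, 2018" is ambiguous at the right endpoint
and a half-open window makes the three years exact calendar years. Age is
computed at the last in-window encounter (the source never anchors age).

Derived covariates: urban means a census-area population of at least
100,000 (inclusive); the visit split takes each patient's median of
per-calendar-year encounter counts (years with no visits count as zero)
and cuts at more than 3; age is dichotomized at the cohort's observed mean
by default, with the published cuts (50.7 patient / 49.6 provider)
available as arguments. Patients whose only documentation is
unclassifiable count as documented (they *have* a record) but are excluded
from the risk-model denominator; `unknown_counts_as_documented = FALSE`
flips the first half of that rule. Missing covariates (e.g. a missing
census population) drop listwise per model, with the dropped count kept on
the fit.

One naming note: the source text alternates between "osteoarthritis" (its
covariate section) and "osteoporosis" (its model tables) for the same
flag. The package models a single bone/joint condition flag named
`osteoarthritis` throughout; the discrepancy is surfaced here rather than
resolved.

## The clustered models

No GEE implementation is available in the dependency budget, so the
estimator is implemented in the package: Liang–Zeger estimating equations
with logit link, independence or exchangeable working correlation
(moment estimator on standardized Pearson residuals, re-estimated each
iteration), Fisher-scoring updates initialized at the ordinary logistic
fit, and a robust sandwich covariance from cluster-summed scores. The
exchangeable cluster inverse uses the closed form for
$((1-\alpha)I + \alpha J)^{-1}$, so cost is linear in cluster size.
Correctness is pinned by oracle tests: with singleton clusters the
coefficients equal `glm()`'s to $10^{-6}$; the independence sandwich
equals a hand-built cluster-robust estimator to $10^{-8}$; with truly
uncorrelated clusters the exchangeable and independence fits agree to
$10^{-2}$; and across replicates the 95% CIs cover a Monte-Carlo-derived
marginal truth at the nominal rate.

Model 1 (documentation, full cohort) uses the published term list: patient
sex, dichotomized age, rural, the visit split, depression, diabetes,
hypertension, the bone/joint flag, provider sex, dichotomized provider
age. Model 2 (heightened risk, classified patients only) drops the
provider terms and enters age continuously per year. "Unadjusted" columns
are single-term clustered fits, matching the published tables' layout; the
crude cross-product odds ratio (with Woolf CI and Haldane–Anscombe
correction for zero cells) is kept as an independent oracle, not as the
reported estimator. The published unadjusted male CI ("1.06–1.81") is
internally inconsistent with its point estimate and is treated as a
misprint; no agreement with it is forced.

Working correlation defaults to exchangeable (the source says only
"generalized estimating equations"); robust standard errors are always
reported. p-values are Wald, with no multiple-testing correction, matching
the source's reporting; the report footer says so.

## Numerical choices

- **Rounding** follows the printed tables: half-up (never half-to-even),
  one decimal for percents, two for odds ratios (`round_half_up()`).
- **Date handling** uses a vectorized integer ISO-8601 parser (encounter
  tables run to millions of rows; `as.Date` costs seconds per million).
  Malformed dates become `NA`, are excluded with a warning, and are
  counted.
- **Convergence**: coefficient-update sup-norm below $10^{-10}$, at most
  50 iterations, with the update trace carried in the error on failure.
  $\alpha$ is clamped to $[0, 0.95]$; all-singleton layouts force
  $\alpha = 0$.
- **Degenerate inputs** are refused loudly: constant outcomes, a single
  cluster, empty extracts, probability vectors off the simplex.
- **Reproducibility**: one global seed fans out to per-stage seeds through
  a fixed affine map (`derive_seed()`), so any stage can be rerun in
  isolation; two runs with the same configuration are byte-identical.

## Limitations

- The keyword dictionaries are seeded from the four published past-use
  phrases and category names only; the full published keyword appendix is
  not available. The dictionaries are plain text precisely so it can be
  dropped in.
- Template-rendered text is far cleaner than clinical free text;
  round-trip accuracy of 100% is a property of the stated world, not a
  claim about real charts.
- The real cohort's adjusted estimates are not reproducible at desk scale
  (the clinical data are not public); parameter-recovery simulations at
  the published effect sizes are the substitute, and exact-number checks
  are limited to arithmetic on the published tables themselves.
- Comorbidity flags are consumed as given; the validated case definitions
  that produce them are out of scope, as are real postal-code-to-CMA
  lookups and any screening-instrument scoring.
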