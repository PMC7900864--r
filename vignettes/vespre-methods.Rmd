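---
title: "Methods: a synthetic EHR-embedded sepsis biorepository pipeline"
author: "vespre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic EHR-embedded sepsis biorepository pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vespre)
```

## What the package models

Prospective sepsis cohorts are expensive to run the traditional way: manual
screening, consent, dedicated research blood draws. An alternative
infrastructure embeds the whole funnel in the electronic health record: a
digital alert flags emergency-department (ED) patients meeting sepsis-3
criteria within six hours of arrival, research staff collect *remnant*
specimens (leftover clinical blood and urine before discard), and a
de-identified clinical-plus-biologic repository accrues at a small marginal
cost. This package re-creates that pipeline at desk scale on fully synthetic
data, so that every stage — alert, funnel, biorepository, cost accounting,
and the proof-of-concept analytics — is testable against known ground truth
without any patient data.

## The digital alert

An encounter is flagged when all six criteria hold within the screening
window (half-open, `[0, 360)` minutes from ED arrival — "within six hours of
presentation"):

1. location in the enrolling ED;
2. age 18 years or older;
3. at least one blood-culture order in window;
4. at least one antibiotic administration in window;
5. at least one of six *modified SOFA elements*: PaO2/FiO2 < 400 mm Hg,
   Glasgow Coma Scale < 15, mean arterial pressure (MAP) < 70 mm Hg or any
   vasopressor administered, total bilirubin > 1.2 mg/dL, platelets
   < 150 x 10^3/uL, creatinine > 1.2 mg/dL;
6. hemoglobin, plasma lactate and sodium results obtained (this guarantees
   the tube types needed downstream exist).

Criteria 3 + 4 are the usual sepsis-3 suspected-infection proxy; criterion 5
is a binary single-organ-dysfunction screen. All inequalities are strict
exactly as stated: platelets of 150 do not trigger, 149 do.

Conventions the source description leaves open, fixed here once:

* **Worst-in-window.** Each element is evaluated on the worst value observed
  in the window (minimum for P/F, GCS, MAP, platelets; maximum for bilirubin
  and creatinine), not the first value. An element with no measurement of
  its kind is false, never missing.
* **Cumulative conjunction.** The six criteria may be satisfied at different
  times; the flag fires if all are satisfied by the end of the window, and
  the flag time is the earliest minute at which all six have evidence.
* **MAP.** Directly charted MAP events take precedence; otherwise MAP is
  derived as `(systolic + 2 * diastolic) / 3` from same-timestamp pairs.
* **P/F.** Requires a measured PaO2 plus FiO2 information: a charted FiO2,
  or 0.21 imputed from an oxygen-device event charted as room air. No other
  imputation. The worst case is taken as min PaO2 over max FiO2.
* **Vasopressors/antibiotics** are recognized by configurable code lists
  (`vasopressorCodes()`, `antibioticCodes()`).

### Full-SOFA adjudication

`adjudicateFullSofa()` stands in for manual chart adjudication: it scores
the conventional six-organ SOFA grid (0–4 per organ, shipped as a plain
table in `inst/extdata/sofa_grid.csv`) on worst-in-window values, scoring 0
for organs without data. Two deliberate simplifications: cardiovascular
sub-scores 3–4 require vasopressor dose rates the simulator does not model,
so any vasopressor administration floors at 2; respiratory sub-scores 3–4
normally require ventilatory support, which is likewise not modeled, so the
P/F thresholds alone are used. Both are conservative for the property the
package checks: every triggered modified element implies its organ sub-score
is at least 1, hence adjudicated SOFA is always at least the number of
triggered elements, and every flagged encounter has SOFA >= 1. The fraction
of flagged encounters with SOFA >= 2 (the sepsis-3 organ-dysfunction bar) is
reported by the screening output but is data-dependent and deliberately not
asserted.

## The enrollment funnel

Flagged encounters are partitioned per calendar day (local midnight of the
simulated arrival datetime, UTC): the first four flags by flag time are
screened, the remainder are recorded as eligible-but-not-screened. Ties
break by ascending encounter id, so the partition is deterministic.

Screened encounters pass a three-rule exclusion cascade, applied in the
stated order with the first failing rule recorded: (1) no specimen collected
inside the window; (2) insufficient remnant volume — some required tube type
has in-window specimens but none meeting its minimum; (3) required tube
types absent — a required type has no in-window specimen at all while every
present type meets its minimum. "Minimum required tube types" is not defined
in the source description; here it is at least one heparin (> 550 uL), one
EDTA (>= 450 uL) and one sodium-fluoride (>= 225 uL) specimen — the three
blood minima the screening protocol lists — and it is configurable
(`requiredTubeRules()`). Urine never affects enrollment. Reasons are
mutually exclusive by construction even though the source reports
overlapping percentages without a precedence rule.

Enrolled encounters receive sequential zero-padded study ids; the
study-id-to-identifier crosswalk is returned separately from the
de-identified export (no patient id, no absolute datetimes), and
re-identification through the crosswalk is exact. Funnel reports enforce
conservation at every level (flagged = screened + capped; screened =
enrolled + excluded; reasons sum to excluded) — the one printed funnel
inconsistency in the source (an excluded count off by three from its own
margins) is deliberately not reproduced. Percentages of at least 1% print to
the nearest integer, smaller ones to one decimal, matching the reporting
convention of the figures being recomputed (64%, 0.4%, and so on).

## The biorepository

A remnant specimen is eligible when its tube type is known, it is collected
from the clinical laboratory within 48 hours (2880 minutes) of acquisition
and after clinical testing completes, and its volume meets the tube-type
minimum (strict > for heparin; >= for EDTA, sodium fluoride, urine at
125 uL). The citrate minimum is unstated in the protocol; the package
defaults to the EDTA-like 450 uL and documents it as a package choice.
Eligibility is monotone in volume and collection delay. Aliquot accounting
fixes a 125 uL aliquot for the total-aliquot counter (no aliquoting rule is
stated), and the "two or more aliquots" availability statistics count
eligible *specimens* per tube type, over the enrolled denominator, with
integer-rounded percentages.

## The cost model

Currency is held as integer cents; totals are exact cent sums and
per-patient values are cent totals divided by the patient count, rounded
half-up to whole cents. The printed per-patient figures in the source mix
conventions (some match round-half-up, some are truncations), so the package
standardizes on round-half-up: with the shipped line items it reproduces the
totals ($39 417.50; $244 917.50; $99 073.46) and the per-patient values
$22.12, $1.77 and $238.48, and prints $14.49 and $125.89 one cent above the
two source figures that were truncated rather than rounded ($14.48,
$125.88). The hypothetical
coordinator-led design is composed of its five printed components, which sum
exactly to its printed total; the prehospital comparison cohort prints only
a total, carried as a single laboratory-category line item, so for that
design only ordering and ratio claims are meaningful.

## Cohort analytics

* **Summaries** are mean (SD) or median [IQR] per a variable configuration,
  binary outcomes as count (integer percent), computed on non-missing
  values. (The source's text says "median (SD)" for age where its table says
  mean (SD); age is treated as mean (SD).)
* **Missingness filter**: variables are retained when their missing fraction
  is strictly below the threshold (default 25%).
* **Log-fold matrix**: entries are `log2(value / marker median)`. The marker
  median is the lower-order-statistic (type-1) median so that the median
  patient maps to 0 *exactly* for any sample size — the interpolating median
  would break that identity for even n. Log base 2 is chosen because the
  displayed range of +/-4 is plausible for these analytes on that scale and
  it is the field convention; values are stored unclipped with a display
  clip at +/-4. Missing cells stay missing (white in the heat map);
  non-positive concentrations are an error.
* **Factor screen**: eigen-decomposition of the correlation matrix,
  retaining eigenvalues strictly greater than 1 (Kaiser rule). Raw tables
  use pairwise-complete correlations — matching an analysis that filters on
  missingness rather than imputing — and unrotated loadings are eigenvectors
  scaled by sqrt(eigenvalue). Rotation is out of scope: only the retained
  count and qualitative loadings matter downstream.
* **OPTICS**: canonical semantics — core distance is the distance to the
  minPts-th nearest neighbor with the point itself counted first (undefined
  beyond eps); reachability of o from p is max(core(p), d(p, o)); processing
  uses a min-priority structure over tentative reachability, seeded and
  tie-broken at the smallest index, so the ordering is fully deterministic
  and testable against an exhaustive O(n^2) reference. Defaults minPts = 5,
  eps = Inf; coordinates are z-scored first (constant columns are only
  centered). The raw-coordinate behavior is available with
  `standardize = FALSE`.
* **Smoothness diagnostic**: the score is the mean absolute successive
  difference of the finite reachability values normalized by their
  interquartile range; a constant profile scores 0 by convention (the ratio
  is otherwise 0/0). At or above the threshold (default 0.5, a documented
  heuristic — no numeric rule is given in the source) the recommendation is
  hierarchical clustering (jagged profile, clear cluster structure), below
  it partitioning methods (smooth profile).

## The synthetic generator

The generator emulates a single-center adult ED population with the
enrolled-cohort marginals: age ~ normal(59, 17) truncated to [18, 105] years
(a configurable fraction of under-18 negative controls is generated
separately), 56% male, Elixhauser comorbidity count ~ normal(4.0, 2.3)
truncated at 0, and 27 clinical event codes drawn from mean/SD or
median/IQR-derived log-normal marginals (`clinicalMarginals()`). Sepsis
prevalence among adult encounters defaults to 8%, the ratio of flagged to
total ED encounters in the setting being emulated. True-sepsis encounters
draw from the septic marginals and are guaranteed one blood-culture order,
one antibiotic administration and one qualifying organ-dysfunction value in
window; non-septic encounters draw from reference-range marginals with
smaller event rates. Criterion-level truth is computed by running the alert
logic on the emitted events, so labels are consistent with the stream by
construction, while the latent `true_sepsis` label stays independent of
alert completeness (e.g. a septic encounter can be missed for want of a
sodium result).

Missingness is applied per variable, completely at random, because only
marginal missingness is reported for the emulated setting; per-variable
rates are package configuration (not source values), set so that 23 of 29
variables fall below 25% missing — the rarely-ordered tests (bands, CRP,
ESR, arterial gases, albumin, INR) sit above the threshold. Specimen counts
per tube type are Poisson (about 1.5–2 expected per blood tube), volumes
are truncated normals whose defaults put roughly a quarter of individual
blood specimens below their minimum, so that about a quarter of
otherwise-eligible patients fail the volume rule. Arrivals spread over
`n / 70` study days so the daily cap of four genuinely binds at realistic
flag rates. Everything is a pure function of the configuration and seed;
the caller's RNG state is untouched.

What the generator does **not** emulate: disease trajectories over time
(each variable is measured once or twice, not as a time series),
pharmacology, inter-variable physiological coupling (variables are
independent unless the explicit block-factor generator
`generateFactorCohort()` is used), site effects, or informative
missingness. Passing tests therefore demonstrate the pipeline's logic —
conservation, monotonicity, threshold handling, score coherence — not
clinical realism of any particular rate.

`generateFactorCohort()` produces the known-answer input for the factor
screen: n observations of p standardized variables on k orthogonal latent
factors over disjoint near-equal blocks, `x = loading * F + sqrt(1 -
loading^2) * e`, so primary loadings of 0.7 leave unique variance 0.51. At
the nested-sample geometry (n = 549, p = 23, k = 5) the five block
eigenvalues sit near 2.5–3 and the noise eigenvalues near 0.5, so the
Kaiser screen recovers k with large margin.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at 10 000 encounters (a few seconds)
and check OPTICS against the exhaustive reference at n <= 25, factor-count
recovery over k = 2..8 with 20 replicates each at n = 549, and Monte-Carlo
marginal recovery at n = 5000–10 000 — sizes chosen so the whole suite stays
interactive while estimates are well inside their sampling tolerances.
Numerical conventions worth restating: half-open windows everywhere; strict
inequalities exactly as printed; integer cents for currency with half-up
rounding; type-1 medians for log-fold references; eigenvalue sums checked to
1e-8; and deterministic tie-breaks (encounter id for the cap, smallest index
for OPTICS).

## A worked run

```{r example}
cfg <- generatorConfig(nEncounters = 2000, seed = 1)
coh <- generateCohort(cfg)
s <- screenCohort(coh)
res <- enrollCohort(s, specimensTable(coh))
res$report

br <- biorepositoryReport(specimensTable(coh), res$crosswalk)
br$ge2_any

panel <- generateBiomarkerPanel(cfg, crosswalkTable(res$crosswalk)$study_id)
lf <- logfoldMatrix(panel)
lf

compareDesigns(vespreCostDesigns())

x <- generateFactorCohort(n = 549, k = 5, p = 23, loading = 0.7, seed = 1)
kaiserFactorScreen(x)
```

## Known limitations

The alert's sensitivity/specificity against the latent truth depends
entirely on configured rates and is reported, never asserted. The cost
fixtures are specific to the emulated study and not generalizable. The
smoothness threshold is a heuristic; profiles near 0.5 should be inspected,
not trusted to the recommendation. Remnant-specimen chemistry (analyte
stability after freezing) is out of scope, as are consent workflows, live
EHR integration, sequencing-based analyses and downstream consensus
phenotype assignment.
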