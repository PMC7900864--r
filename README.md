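# vespre

Simulation and analytics for an EHR-embedded sepsis biorepository pipeline.

## The problem

Traditional prospective sepsis cohorts screen manually, consent patients,
and draw dedicated research blood — slow, expensive, and blind to most
eligible patients in a time-sensitive disease. An alternative embeds the
whole study in the electronic health record: a digital alert flags
emergency-department patients meeting sepsis-3 criteria within six hours of
arrival, staff collect *remnant* specimens (leftover clinical blood and
urine before discard), and a de-identified clinical-plus-biologic
repository accrues at a fraction of a coordinator-led study's cost.

`vespre` rebuilds that infrastructure as a desk-scale, fully synthetic
pipeline for methodologists and trial designers: a seeded ED event-stream
simulator with known ground truth feeds the digital alert, the enrollment
funnel, the biorepository accounting, a comparative cost model, and the
proof-of-concept analytics, so every stage is testable without any patient
data.

## The core machinery

* **Digital alert** — an encounter is flagged iff all six criteria hold in
  the half-open window `[0, 360)` minutes from arrival: ED location;
  age ≥ 18; blood cultures; antibiotics; ≥ 1 of six *modified SOFA
  elements* (PaO2/FiO2 < 400 mm Hg, GCS < 15, MAP < 70 mm Hg or
  vasopressors, bilirubin > 1.2 mg/dL, platelets < 150 ×10³/µL, creatinine
  > 1.2 mg/dL, all strict, worst-in-window); and hemoglobin + lactate +
  sodium obtained. A full-SOFA oracle (standard 0–4-per-organ grid) backs
  the coherence guarantee `SOFA ≥ #elements triggered`, so every flagged
  encounter has SOFA ≥ 1.
* **Funnel** — daily cap of 4 screened per calendar day, then the ordered
  exclusion cascade (specimen window → insufficient volume → tube types
  absent: ≥ 1 heparin > 550 µL, EDTA ≥ 450 µL, sodium fluoride ≥ 225 µL),
  then sequential study ids with a separately held crosswalk. Conservation
  holds at every level, on every run.
* **Biorepository** — remnant eligibility (tube minima, 48-h collection
  window, after testing complete) and per-patient ≥ 2-aliquot availability
  over the enrolled denominator.
* **Cost model** — integer-cent line items per study design; totals,
  half-up-rounded per-patient values, category stratification, ratios.
* **Analytics** — missingness filter (strict < 25%); log2 fold-change
  biomarker matrices vs the cohort median (display clip ± 4); the Kaiser
  screen (count of correlation-matrix eigenvalues > 1); OPTICS reachability
  profiles with a smooth-vs-jagged score recommending partitioning vs
  hierarchical clustering.

## Worked example

```r
library(vespre)

cfg <- generatorConfig(nEncounters = 2000, seed = 1)
coh <- generateCohort(cfg)            # encounters, events, specimens, truth
s   <- screenCohort(coh)              # six criteria + adjudicated SOFA
res <- enrollCohort(s, specimensTable(coh))
res$report
#> FunnelReport
#>   flagged: 118
#>     eligible & screened: 97 | not screened (cap): 21
#>     enrolled: 43 | excluded: 54 (window 0, volume 21, tubes 33)
#>   percentages:
#>     eligible_screened_of_flagged: 82% (97/118)
#>     enrolled_of_eligible_screened: 44% (43/97)
#>     excluded_of_eligible_screened: 56% (54/97)
```

Of 2000 synthetic ED encounters, 118 trip the six-criterion alert; the
daily cap of 4 defers 21; of the 97 screened, 21 fail remnant-volume minima
and 33 lack a required tube type, leaving 43 enrolled with study ids
`VESPRE-0001`… and an exact crosswalk. Downstream:

```r
panel <- generateBiomarkerPanel(cfg, crosswalkTable(res$crosswalk)$study_id)
logfoldMatrix(panel)
#> LogFoldMatrix: 43 patients x 17 markers (display clip +/-4)
#>   stored log2 fold range: [-5.37, 3.47]; 55 missing cells

compareDesigns(vespreCostDesigns())
#> CostReport
#>                           design n_patients     total per_patient ratio_to_cheapest
#>                           VESPRE       1027  39417.50       38.38          1.000000
#>               prehospital_cohort        787  99073.46      125.89          3.280094
#>  hypothetical_coordinator_cohort       1027 244917.50      238.48          6.213653

kaiserFactorScreen(generateFactorCohort(n = 549, k = 5, p = 23,
                                        loading = 0.7, seed = 1))
#> FactorScreenResult: 5 of 23 eigenvalues > 1
#>   top eigenvalues: 3.35, 3.06, 2.84, 2.61, 2.21, 0.67
```

The EHR-embedded design totals $39 417.50 — about a sixth of the
hypothetical coordinator-led design covering the same activities — and the
five-block latent-factor cohort is recovered exactly by the
eigenvalue-greater-than-one screen.

A thin command-line front end (`inst/scripts/vespre`) exposes the same
stages as `simulate` / `screen` / `enroll` / `biorepo` / `cost` /
`analyze` subcommands. The methods vignette
(`vignettes/vespre-methods.Rmd`) documents every modeling convention and
default.

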