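# patientday

**patientday** builds standardized *patient-facility-day* datasets from raw
multi-hospital EHR extracts. It is aimed at health-services and critical-care
researchers who need daily-granularity inpatient data — physiology, organ
dysfunction, sepsis phenotypes, outcomes — assembled consistently across many
facilities with heterogeneous local coding, in the style of nationwide
clinical data warehouses (where inpatient data arrive as *specialty transfer*
records rather than ready-made hospitalizations).

## What it computes

The core data model is a nesting of intervals reconstructed from the
specialty-transfer table:

* **specialty stay** — a contiguous period under one treating specialty at
  one facility (the atomic record);
* **bedded stay** — one or more consecutive same-specialty stay records at
  one facility;
* **single-site hospitalization (SSH)** — a maximal run of consecutive
  *acute* specialty stays at a single facility (the primary analysis unit);
* **acute hospitalization** — SSHs chained across facilities when the next
  admission falls within the transfer gap (default 1 calendar day);
* **episode of care** — the same chaining over bedded stays of any
  specialty (so nursing-home tails extend the episode).

Every SSH is expanded to one row per patient, facility and calendar date
(both admission and discharge dates included; a same-day inter-facility
transfer yields one row per facility), with an ICU flag for any day the
patient spent time in an ICU. Onto that grid the package joins:

* daily **high/low values for 16 laboratory tests and 6 vital signs**,
  matched by LOINC code *or* curated local-name substring (with topography
  filters), converted to canonical units, and plausibility-filtered;
* daily **drug indicators** from free-text medication-administration
  records (case-insensitive token search, with records containing
  "research"/"study" vetoed entirely), plus antibiotic class and route
  grouping;
* daily **SOFA component scores** (coagulation, liver, cardiovascular,
  renal) from the worst same-day values — e.g. coagulation 0–4 by platelet
  low (<150/<100/<50/<20 ×10³/µL), cardiovascular from MAP < 70 mmHg and an
  extended vasopressor list — with **organ failure** defined as a component
  score of 3 or 4, and missing inputs kept missing (never imputed to 0);
* two sepsis phenotypes per hospitalization: **Angus** (claims-based:
  concurrent infection + organ-dysfunction codes, or an explicit severe
  sepsis/septic shock code, with GEM-based ICD-9→ICD-10 list conversion)
  and the **CDC Adult Sepsis Event** (EHR-based: blood culture with a
  sustained systemic-antibiotic run anchored within ±2 days, plus concurrent
  organ dysfunction);
* hospitalization-level **mechanical ventilation** from procedure codes
  (day-level detection is deliberately unsupported);
* outcomes: in-hospital mortality, 30-day mortality from admission, and
  30-day readmission among live discharges, plus severity-score
  *components* (age, admission diagnosis category, 30 comorbidity flags,
  11 admission labs — no composite score).

A fully deterministic **synthetic CDW generator** produces all the raw
tables with known ground truth (true SSH boundaries, sepsis flags, daily
SOFA), so the entire pipeline is testable end to end without access to any
protected data.

## Worked example

The canonical two-facility trajectory — ICU admission at Battle Creek,
same-day transfer to the Ann Arbor ICU on day 3, ICU-to-ward move on day 7,
ward-to-nursing-home on day 10:

```r
library(patientday)
out <- run_pipeline(generate_worked_example())
out$ssh[, .(ssh_id, facility_id, admit_date, discharge_date)]
#>     ssh_id    facility_id admit_date discharge_date
#> 1: S000002 F-BATTLE-CREEK 2014-03-01     2014-03-03
#> 2: S000001    F-ANN-ARBOR 2014-03-03     2014-03-10
```

Two SSHs, and `nrow(out$bedded) == 4`, `nrow(out$hospitalizations) == 1`,
`nrow(out$episodes) == 1`. The transfer day produces one row per facility
(day 3 for Battle Creek is day 1 for Ann Arbor), and the day-7 ICU-to-ward
move stays a single row flagged as an ICU day because part of it was spent
in the ICU.

A synthetic cohort through the full pipeline:

```r
cfg  <- cohort_config(n_patients = 300, sepsis_prevalence = 0.048, seed = 42)
tabs <- generate_cohort(cfg)
res  <- run_pipeline(tabs)
#> SSHs: 355 | patient-facility-days: 2018 | CDC-ASE sepsis: 16 | Angus: 16
#> median LOS: 4 | spot check (n = 50): 0 disagreements
```

16 of ~340 hospitalizations (≈4.7%) meet both sepsis definitions,
recovering the configured 4.8% prevalence; `spot_check_sample(res, tabs,
n = 50, seed = 7)` recomputes every sampled day's extremes and drug
indicators directly from the raw records and reports field-level agreement.

## Command line

```sh
Rscript inst/cli/patientday simulate --n-patients 200 --seed 1 --out raw/
Rscript inst/cli/patientday build --in raw/ --out built/
Rscript inst/cli/patientday audit --in raw/ --n 50 --seed 7
Rscript inst/cli/patientday example --out demo/
```

## Configuration

All clinical content is editable configuration under `inst/extdata/`:
specialty classes, lab/vital definitions (LOINC sets, synonyms,
topographies, units, plausible ranges), the drug lexicon, SOFA cutoffs,
sepsis code lists, ASE parameters, comorbidity and diagnosis-category
groupers, and a *synthetic* GEM-style ICD crosswalk stand-in
(`gem_synthetic.csv`). Shipped values are clinically standard seeds, not
transcriptions of any site's lists; see the methods vignette
(`vignettes/patient-facility-day-methods.Rmd`) for every default and its
rationale.
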