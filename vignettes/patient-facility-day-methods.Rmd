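---
title: "Building patient-facility-day data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building patient-facility-day data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patientday)
library(data.table)
```

## The problem

Multi-hospital EHR warehouses store inpatient care as *specialty transfer*
records — one row per contiguous period under a treating specialty at a
facility — not as hospitalizations. Laboratory tests are named and coded
differently at every site, LOINC penetration is incomplete, and drug names
are hand-typed free text. This package reconstructs an analysis-ready
dataset at the **patient-facility-day** grain from five such raw tables,
and ships a synthetic generator so every step is testable without access to
protected clinical data.

## Episode construction

**Contiguity.** Two stays chain when the successor's admission date is at
most `gap_days` (default 1) after the running latest discharge date of the
chain. The 1-day tolerance absorbs midnight-crossing transfer paperwork; it
is exposed as configuration because the literature this rule descends from
does not pin the tolerance. The sequential gap-join is provably equivalent
to the transitive closure of pairwise interval contiguity, and the test
suite checks that equivalence against an independent boolean-matrix closure
oracle on a thousand random instances.

**Bedded stays.** A bedded stay is a maximal contiguous run of
*same-specialty* records at one facility. Pure facility-level merging would
fuse an ICU-to-ward-to-nursing-home sequence into one bedded stay; the
published worked example enumerates those as three distinct bedded stays,
so a change of treating specialty starts a new bedded stay while
consecutive records under the same specialty merge ("composed of one or
more specialty stays"). Episodes of care then chain bedded stays of any
specialty with the same gap rule.

**SSHs and acute hospitalizations.** Non-acute stays (nursing home,
domiciliary, rehabilitation — per the editable specialty code-list) are
removed *before* grouping, so an acute run interrupted by a non-acute stay
splits into two single-site hospitalizations. SSHs of one patient chain
into acute hospitalizations when the next admission is within the transfer
gap, normally an inter-facility transfer.

**Degenerate inputs.** Overlapping stays at one facility are resolved by
truncating the earlier stay at the later admission (preserving the
partition invariant) and logged. A missing discharge at the end of
observation keeps the SSH but flags it censored; censored SSHs are excluded
from length-of-stay and readmission denominators. Both admission and
discharge dates generate day rows (closed interval): a same-day
admit/discharge is one patient-facility-day. Calendar dates are taken from
recorded datetimes with no time-zone normalization (single-system
assumption).

## Laboratory and vital-sign harmonization

A record matches a standard test when its LOINC is in the test's LOINC set
*or* its local name contains one of the curated synonym patterns
(case-insensitive fixed substring — deliberately not fuzzy matching, so
every match is auditable), and its topography is allowed. Records matching
two tests go to a conflict report and are excluded; records matched by name
despite a blank LOINC are counted separately, since they are exactly the
tests LOINC-only extraction would miss. Unit conversion is linear per an
explicit table; unknown units flag the record unconvertible rather than
guessing. Values outside per-test plausible ranges are removed and reported
per facility and test, mirroring the clinician-review loop over value
distributions. Vitals are matched only on the vital-type field, never free
text. Mean arterial pressure is taken directly when recorded and otherwise
derived as (2×diastolic + systolic)/3 from cuff readings paired on the same
timestamp.

The shipped definitions (16 labs, 6 vitals) are the implementer's
clinically standard seeds — LOINC sets from the LOINC standard, ranges wide
enough to exclude only physiologic impossibilities — because the original
site-specific lists are not public. They are configuration, not code, and
are expected to be re-curated per deployment.

## Medications

Drug identification is case-insensitive token search across all name
fields, with and without appended dosage text. Any record containing an
exclusion token ("research", "study") anywhere in any name field is vetoed
entirely — veto dominates every match, erring toward excluding trial drugs.
One wrinkle of plain substring search: "norepinephrine" contains
"epinephrine", so the lexicon supports per-drug negative tokens
(epinephrine is suppressed when the norepinephrine token is present).
Antibiotics carry a class and a route group (systemic-IV, systemic-oral,
non-systemic); unknown routes classify as non-systemic with a warning — the
conservative choice for the sepsis infection arm. Daily indicators are an
idempotent OR over the calendar day. Dose-quantity parsing is out of scope.

## SOFA components

Four of six components (coagulation, liver, cardiovascular, renal) are
scored 0–4 from the *worst* same-day values: platelet low, bilirubin high,
creatinine high, MAP low. Cutoffs are the standard SOFA tiers, held in
configuration. The respiratory component is excluded because day-level
mechanical ventilation cannot be distinguished reliably from these data
(ventilation is detected from procedure codes at the hospitalization level
only, and a day-level query is an explicit unsupported-operation error);
the CNS component is excluded because coma-score recording in sedated
patients is too variable. Renal scoring uses creatinine only — urine output
is not among the abstracted measures.

The cardiovascular component uses an extended vasopressor list
(norepinephrine, epinephrine, dopamine, dobutamine, vasopressin,
phenylephrine, milrinone). The canonical SOFA tiers 2–4 depend on infusion
*dose rates*, which barcode-administration text does not reliably carry and
dose parsing is a non-goal; the package therefore assigns a configurable
dose-free tier per agent (`cv_tier`): dobutamine alone → 2, any other
vasopressor → 3, combined as `max(MAP tier, agent tier)`. This can
under-score a day that would be 4 by dose criteria; it never under-scores
below 2 when any pressor is given. A day with no platelet (bilirubin,
creatinine, MAP/pressor) data has a *missing* component, never 0 —
missingness honesty is asserted by tests.

## Sepsis phenotypes

**Angus (claims-based).** True when a hospitalization carries at least one
infection code and at least one acute organ-dysfunction code, or any
explicit severe-sepsis/septic-shock code. "Concurrent" is interpreted as
same-SSH (an open question in the source; the SSH is the primary analysis
unit). The ICD-9 lists convert to ICD-10 by union of GEM forward images and
backward pre-images, de-duplicated, sorted, then filtered by a
manual-review exclusion list. The shipped crosswalk
(`gem_synthetic.csv`) is a small **synthetic** stand-in sufficient for
testing the mechanism; real analyses supply the CMS tables.

**CDC Adult Sepsis Event (EHR-based).** Presumed infection: a blood culture
drawn during the SSH whose first systemic antibiotic day falls within ±2
days, with the antibiotic run lasting ≥4 consecutive days or until
discharge/death if earlier. Organ dysfunction within ±2 days of the culture
day: vasopressor initiation, mechanical ventilation, or configured
abnormal-lab criteria (lactate ≥ 2.0 mmol/L; platelets < 100 ×10³/µL with
≥50% decline from the in-stay maximum; creatinine ≥ 2× the in-stay minimum;
bilirubin ≥ 2.0 mg/dL and ≥ 2× the in-stay minimum). Window width, QAD
minimum and all thresholds are configuration (`ase_criteria.json`), seeded
from the surveillance toolkit values. Baselines are computed within the SSH
(community baselines are unavailable in an inpatient extract), which makes
the criteria slightly conservative for patients admitted already deranged.
A shift of all events by a constant number of days leaves the flag
unchanged (tested property).

## Severity-score components

The package emits components only — age, admission diagnosis category via a
configurable prefix grouper, 30 comorbidity flags via configurable code
sets, and 11 admission-day laboratory values — and refuses to compute a
composite predicted mortality, because the fitted coefficients of the
reference model are not public. The comorbidity and diagnosis-category
seeds are **provisional** (Elixhauser-style prefixes; admission-day high
value for the labs) and labelled as such.

## The synthetic generator: what it emulates, and what a green test proves

`generate_cohort()` emits the five raw tables plus a death-date table and
ground truth (true SSH boundaries, per-hospitalization sepsis, true daily
SOFA computed by an independent inline scorer). Defaults are the stated
world of the published system: log-normal stay durations rounded to whole
days with median 4 (IQR target 2–6), minimum 1; in-hospital mortality 1.7%
and 30-day mortality 4.4% per hospitalization; 30-day readmission 15.3%;
sepsis prevalence 4.8%; ICU segments sized to put roughly 14% of
patient-days in an ICU. Inter-facility transfer frequency is not published;
`transfer_prob = 0.05` was chosen once as a plausible rate and is not
tuned. Identifiers are opaque (`P000123`, `F042`). Sepsis-positive
hospitalizations always contain a blood culture, a ≥4-day (or
until-discharge) systemic antibiotic run, a vasopressor start within the
window, a lactate rise, and explicit + infection discharge codes, so both
phenotype definitions have full ground-truth support; sepsis-negative
hospitalizations carry no blood cultures and only benign codes.

`inject_messiness()` degrades only the *coding*: blanking LOINCs (the
name-path capture must recover them), swapping facility-local test-name
synonyms (all within the curated pattern lists), case-perturbing and
dosage-suffixing drug names, and inserting "research"/"study" decoys.
Ground truth is never altered.

What a green test therefore establishes: the pipeline exactly recovers
hospitalization structure, daily SOFA and both sepsis phenotypes from
clean-but-realistically-shaped raw tables, and is robust to the specific
messiness modes above. What it does not establish: robustness to
unmodelled real-world pathologies — synonym lists that miss real local
names, units absent from the conversion tables, contradictory transfer
records, disease-progression dynamics. The generator makes no claim of
statistical realism for value trajectories beyond plausible ranges.

## Numerical and interface choices

* Deterministic throughout: generator output is byte-identical for a fixed
  config+seed; pipeline output is byte-identical for fixed inputs.
* Phenotype recovery is evaluated at the acute-hospitalization level (a
  transferred sepsis hospitalization is positive if any member SSH is
  flagged): blood cultures localize to one facility, so the SSH at the
  other facility is legitimately negative while the hospitalization is
  positive.
* Configuration is JSON/CSV rather than YAML: the deployment environment
  guarantees a JSON parser and no YAML parser, and the mappings are
  isomorphic.
* Delimited outputs use fixed column order, ISO-8601 datetimes and UTF-8;
  the manifest records per-stage row counts and rejection counts so
  conservation (input = matched + rejected + orphaned) is machine-checkable.
* Ties and edge cases: a record matched by both LOINC and name counts as a
  LOINC match; same-timestamp direct MAP suppresses derivation; unknown
  specialty codes classify per a configured default with a warning.

## Known limitations

Observation status, emergency-department visits and non-VA community care
are out of scope. Angus code lists, comorbidity sets and the 11 admission
labs are representative seeds, not validated transcriptions. Day-level
ventilation, dose-aware cardiovascular SOFA, and composite severity scores
are deliberately refused rather than approximated.
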