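---
title: "Methods: the maternal cardiovascular risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the maternal cardiovascular risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcvrisk)
```

## The problem and the model

Maternal cardiovascular complications (preeclampsia, eclampsia, peripartum
cardiomyopathy, stroke, myocardial infarction, heart failure, pulmonary
embolism) are often preceded by signs already present in routine prenatal
records. `matcvrisk` replays a patient's encounters in chronological order
and evaluates, at each encounter, a deterministic catalog of established
risk factors. The rule core is intentionally simple and fully auditable:

* **Static risks** (demographics and prepregnancy history) are evaluated
  once per patient and are active at every encounter.
* **Variable risks** (symptoms, physical findings, vital-sign threshold
  exceedances) count only at encounters where they are recorded. There is
  no carry-forward by default: the engine sees what a provider would have
  seen in the encounter's record. A carry-forward window can be configured
  but is off by default.
* An encounter's profile is **red flag** when a single severe factor is
  present — dyspnea, orthopnea, or a red-flag threshold exceedance — or
  when **4 or more distinct** risk factors are active simultaneously;
  **standard** when at least one factor is active; none otherwise.

All numeric thresholds are inclusive as printed in the source catalog
(heart rate ≥ 110 / ≥ 120 bpm, systolic blood pressure ≥ 140 / ≥ 160 mm Hg,
respiratory rate ≥ 24 / ≥ 30 per minute, oxygen saturation ≤ 96 / ≤ 94 %,
BMI ≥ 35, age ≥ 40). Two interpretation choices were genuinely open and are
configurable:

* whether static findings count toward the 4-or-more rule — they do here,
  because the rule is stated over *total* risk factors;
* tachypnea can arrive both as a coded symptom and via the respiratory-rate
  threshold; the two are distinct factor ids and the count rule uses
  distinct ids, so a single physiological fact is never double-counted
  within one route, while symptom-coded and measured routes remain
  distinguishable.

The age ≥ 40 factor is retained in the catalog even though the extraction
stage filters encounters to ages 18–35: the catalog stays faithful to the
clinical criteria, and the factor simply never fires on study-like data.

### Individual baselines

In its intended prospective use the engine first establishes per-patient
baselines and evaluates deviations from them. For retrospective data with
thin histories this is unreliable, so baseline mode is **disabled by
default** and the study configuration evaluates raw catalog thresholds;
patients whose data fall outside medically accepted ranges are flagged and
excluded from any calibration set rather than silently modelled. When
baseline mode is enabled, the baseline per quantity is the median of the
first `k = 3` observations, and numeric thresholds shift by
`baseline − norm midpoint` for conforming patients. The median-of-first-k
construction and the shift are this package's interpretation (no formula is
fixed by the source description), which is why both `k` and the norm ranges
are plain arguments. The shipped norm ranges are conventional adult
reference intervals and deliberately labelled non-authoritative.

## What the synthetic generator emulates

No deposited dataset exists for this problem — the source records are
protected hospital data — so the generator is a first-class, tested module
that emulates the *statistical structure* the pipeline must survive:

* a visit-centric relational layout in which events tie to encounters and
  encounters to persons, with the clinical-events table using one shared
  **character** result-value field for every variable plus a unit field;
* identifiable fields (synthesized names, zips from a synthetic urbanicity
  pool, full calendar dates) and free-text comment events that deliberately
  embed names and dates, so de-identification is exercised for real;
* weights emitted in pounds or kilograms with equal probability, to
  exercise unit normalization;
* historical-upload visits registered in the year 1900 and
  communication-only visits (portal messages, phone calls) carrying no
  clinical events — both carry a pregnancy-supervision code so that they
  reach the exclusion filters and their removal can be verified against the
  injected ground truth, rather than disappearing earlier for an unrelated
  reason;
* planted risk: static-risk prevalences and a rising systolic-blood-pressure
  trajectory that crosses the standard threshold at a known encounter and,
  for a subset, the red-flag threshold at a later one, followed by a
  target-condition diagnosis after a Poisson-distributed lag snapped to an
  actual encounter day.

Ground truth records the days *realized* in the emitted values (not merely
the planted intent), so the invariant "replaying the trajectory against the
catalog reproduces the recorded crossing days" holds at any noise level;
with the default small noise the crossing encounter is unambiguous, and
with `noise_sd = 0` recovery is exact by construction. Ground-truth
red-flag status also accounts for the 4-or-more route: a patient carrying
three static risks reaches the red-flag level at their first variable
finding.

### Generator defaults

Where the source cohort overview states a composition, the defaults follow
it: delivered-on-first-visit 46 %, single-visit 35 % (both as marginal
fractions of all patients, drawn from one uniform so the two categories are
exclusive and both marginals hold), red-flag 5.3 %, prepregnancy BMI ≥ 35
at 8.64 %, African American race at 25.28 %, substance use at 10.7 %, twin
births 1.45 %, triplet births 0.03 %, stillbirths 0.78 %. The remaining
static-history prevalences (diabetes 3 %, hypertension 5 %, heart disease
2 %, chemotherapy 0.5 %, labor/delivery complications 4 %) are plausible
obstetric values chosen once; the planted variable-trajectory fraction
(16 %) was chosen so that the *expected* fraction of patients with at least
one risk finding, under independence with the static prevalences, is
≈ 55.8 %, matching the reported composition. Visit days are drawn uniformly
within a 280-day gestation window ending at the delivery date (the source
is silent on spacing); ages are drawn so patients remain inside 18–35 at
every encounter, which keeps the age filter load-free on default synthetic
data — age-boundary behavior is tested with hand-built fixtures instead.

What the generator does **not** emulate: physiologic correlation between
quantities, realistic between-visit autocorrelation beyond the planted
trajectory, coding variability across sites, or free-text clinical notes
(excluded from scope altogether). Passing tests therefore demonstrate the
pipeline's mechanics — filtering, anonymization, normalization, replay,
recovery — not clinical performance on real records.

## Extraction, de-identification, harmonization: numerical choices

* **Ages** are completed years (birthday semantics, not division by
  365.25), and the 18–35 bounds are inclusive at both ends; the source
  states the range without boundary semantics, so inclusivity is documented
  as a choice. Visits of patients with a missing date of birth go to a
  review list, never silently dropped.
* **"Registration dates starting in 1900"** is interpreted as registration
  year ∈ {1900}, configurable.
* **Index visit** is the earliest encounter *surviving extraction* — using
  the earliest raw visit would let a 1900 artifact corrupt every offset.
  Day offsets are integer calendar-day differences; clock times are kept
  verbatim in a separate field for within-day sequencing; offsets may be
  negative for records imported from before the index visit. The date of
  birth is replaced by age at index in completed years.
* **Pseudonyms** are the first 16 hex characters of HMAC-SHA256(salt, id),
  with hard-error collision detection; the construction (and the
  truncation length) is this package's choice, since the source states only
  that ids were hashed. The master key (salt + forward/inverse maps) allows
  exact backtracking for revalidation and can only be written to a
  directory distinct from the analysis export; key emission is off by
  default.
* **Unit normalization** converts pounds with the exact factor 0.45359237
  and rounds to 0.01 kg; canonical units pass through; unknown units are
  flagged and the flagged observations are excluded from risk evaluation.
  Round-tripping lb → kg → lb is accurate to < 0.02 lb.
* **Duplicates** (identical person, visit, label, value, day, time)
  collapse to one row, mirroring a warehouse's cleaned extracts.
* **Categorization rules** are ordered plain data (first match wins);
  unmatched records go to a review queue so categorization is total. The
  delivered rule set covers the generator's vocabulary and is expected to
  be site-edited; the data catalog is rebuilt from the final tables on
  every assembly, so it can never go stale. Its last-updated marker is a
  content marker (row count), keeping repeated runs byte-identical.
* The prenatal (Z34/O09) and delivery (10D0/10E0) code prefixes are
  editable placeholders: the source defers to an external delivery
  definition and prints no code lists.
* The final schema keeps person *and* visit ids on every table except
  FamilyHX and Race, which are person-grain; the Person table carries the
  index-visit id as its visit reference. Field-level schema beyond the
  stated columns is implementation-defined (the source's schema figure is
  not printed in text form).

## Lead-time evaluation

The delta for a patient is `reference − onset` in days: positive when the
engine's earliest standard-level onset precedes the first recorded
target-condition diagnosis. Which onset level anchors the delta is
configurable (`level = "red_flag"` restricts to red-flag onsets), since the
source does not fix it; the default is the earliest standard-or-higher
onset. Patients who delivered at their index encounter (no retrospective
data) or had a single included encounter (no trend) are excluded, with
delivered-first taking precedence so the reasons partition the cohort
exactly. "Intervention" reference events beyond diagnoses are supported as
configurable marker codes appended to the target list; none are planted by
default. Patients with an engine onset but no reference event are retained
under a `detected_never_diagnosed` status — on real data these are the
interesting mixture of false positives and missed diagnoses; on synthetic
data they are static-risk carriers without a planted condition.

Because static-risk carriers are at standard risk from day 0, their deltas
measure time from the *first encounter* to diagnosis; deltas anchored
purely on the planted trajectory can be obtained by restricting to
patients without static risks, and the acceptance machinery checks both
onsets and deltas against ground truth patient by patient.

## Reporting

Percentages are formatted as `100·count/denominator`, rounded half-up to
two decimals with trailing zeros trimmed. This rule reproduces 15 of the 17
percentage cells in the published cohort-overview table from their printed
count pairs; the remaining two printed cells (45.83 for 14855/32409, whose
exact value is 45.836, and 1.45 for 545/37457, exactly 1.455) are not
consistent with *any* single rounding rule that also produces the cells
requiring rounding (35.44, 97.62), so the package follows the arithmetic
where the table is self-consistent. Births are counted from delivery-
outcome codes; plurality rows count delivery events while the total counts
infants, so the mutually exclusive rows sum to at most the total.

## Problem sizes and determinism

The test suite and the acceptance script exercise a 500-patient noise-free
cohort (the size at which binomial checks on the planted fractions are
meaningful at three standard deviations) plus smaller cohorts of 20–120
patients for determinism and interface checks; the full 500-patient
pipeline runs in seconds. Every stochastic step flows from the single
configured seed through `withr::with_seed` (artifact injection uses a fixed
offset of the same seed so it is deterministic yet independent of the
generation stream), and repeated runs with one seed produce byte-identical
CSV trees, which the acceptance checks verify by file hash.

## Known limitations

* The rule core is the deterministic, auditable specification of the
  screening behavior; no learned weighting, training loop, or proprietary
  scoring is included, and the package does not predict *which* condition a
  patient will develop — it emits risk levels.
* Code matching is exact-prefix against configured lists; there is no
  ontology traversal.
* De-identification here is a faithful engineering implementation
  (generalization, offsets, keyed pseudonyms, free-text stripping) and is
  verified by scanning its own exports, but it carries no formal
  k-anonymity or differential-privacy guarantee.
* Synthetic trajectories use a single vital-sign route (systolic blood
  pressure) for planted variable risk; the engine evaluates all catalog
  factors, and the presence/symptom routes are covered by unit tests rather
  than by the generator's planted cohort.
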