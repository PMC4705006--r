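---
title: "Rule-based HABSI surveillance: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based HABSI surveillance: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habsi)
```

## The surveillance problem

A health care-associated bloodstream infection (HABSI) is a bloodstream
infection whose onset is attributable to hospital care rather than to the
community. Hospital-wide surveillance of HABSI feeds quality indicators,
outbreak detection and intervention targeting, but manual surveillance by
infection control personnel is slow and reviewer-dependent. `habsi`
implements an automated alternative: a deterministic rule engine over
discrete EMR data streams — admissions and ward transfers, blood and
non-blood culture results, vital signs, device intervals, antimicrobial
orders — that detects candidate infections, removes duplicate signals, and
classifies each event.

Two data-representation decisions shape everything downstream:

* **Specimen log-in time as onset proxy.** Bedside collection times are
  rarely recorded reliably, so the laboratory receipt (log-in) timestamp
  stands in for collection time and infection onset. This is faithful to
  practice and introduces a known artifact: a delayed specimen transport
  can push a community-onset culture past the 48-hour mark.
* **Minute-resolution, timezone-naive timestamps.** Every rule operates
  at hour scale, so all timestamps are truncated to one implicit-timezone
  minute grid at ingest.

## The detection and classification model

**Episode linkage.** Re-admission within `readmit_gap_days` (default 2,
inclusive, measured on calendar dates — administrative linkage is
date-based) of a discharge links the stays into one hospitalization
episode, transitively. The hospital-acquired clock runs from the *first*
admission of the merged episode: a patient re-admitted one day after
discharge who grows a pathogen two hours into the re-admission is a
healthcare-associated case, which an unlinked system would miss. Whether
the original hospital system restarted the 48-hour clock at re-admission
is not documented anywhere we could check; restarting it would contradict
the purpose of linkage (re-admissions within two days are considered the
same hospitalization), so the clock does not restart.

**Hospital-acquired rule.** A blood specimen is healthcare-associated iff
`login_ts − episode_start ≥ 48 h`, inclusive at the boundary ("48 hours
or more").

**Sign screening.** Fever is any temperature strictly above `fever_c`
(default 38.0 °C): a reading of exactly 38.0 is *not* fever. This strict
inequality is a faithful, deliberately imperfect operationalization — an
antipyretic-suppressed or blunted febrile response produces a miss, which
is precisely the dominant false-negative mode of fielded systems of this
kind. Hypothermia is strictly below 36.0 °C. Tachycardia and tachypnea
use age-banded thresholds (adults: HR > 90/min, RR > 20/min, the SIRS
conventions; infants ≤ 365 days: HR > 180, RR > 60) because neonatal
vital signs would otherwise flag constantly. Free-text signs (chills,
apnea) are out of scope: the engine sees only discrete data.

**Organism confirmation.** Report revisions replace the organism set and
are applied only when dated within `recall_days` (default 7) of the final
report; later corrections are ignored. This models a polling integration
that stops re-reading laboratory results after a fixed "recall day", and
is kept deliberately because it reproduces a documented false-positive
mechanism (a pathogen report corrected to a contaminant after the recall
day stays a pathogen in the engine's view). A recognized (non-commensal)
pathogen confirms on a single draw. A common skin commensal confirms only
with corroboration: the same organism in at least two separate draws
whose log-ins are ≤ `commensal_window_days` (default 2) calendar days
apart — mirroring the routine paired blood sets drawn 45–60 minutes
apart — plus at least one sign flag within ± 24 h of the first draw of
the pair. The commensal list is configuration, not code: coagulase-
negative staphylococci, *Micrococcus*, *Corynebacterium* (non-
diphtheriae), *Bacillus* (non-anthracis), *Cutibacterium*/
*Propionibacterium*, viridans-group streptococci and *Aerococcus* by
default, NHSN-style; sites with their own list substitute it wholesale.

**Clinical sepsis (CSEP).** Culture-negative sepsis is detected from
signs plus treatment: a sign ≥ 48 h into the episode, a new antimicrobial
order starting within `csep_abx_window_hours` (48) after the sign, no
confirmed positive blood culture within ± 48 h, and no positive
(non-commensal, non-catheter-tip) site culture within ± 7 days. The
engine emits at most one sepsis candidate per episode, at the earliest
qualifying sign: without organisms there is no principled way to separate
repeated sepsis signals inside one hospitalization, and the deduplication
stage has no organism overlap to work with. The antimicrobial-treatment
requirement is the NHSN-style reading; it is configurable because some
programs screen on signs alone.

**Deduplication.** Candidates of the same pathway whose onsets lie within
`polymicrobial_hours` (48) merge into one polymicrobial event with the
union organism set. A later candidate sharing an organism with an event
and within `persistent_days` (14) of the *event onset* is absorbed as
persistent BSI; the window is anchored at the event onset and is not
extended by absorbed repeats (repeat-infection-timeframe semantics).
Setting either window to 0 disables that merge — the natural limit
reading, and the one that keeps "one event per candidate" exact even for
tied onsets. The chronological replay is iterated to a fixed point: a
merged union set can newly overlap an earlier event inside the persistent
window, and a single pass would leave that duplicate standing. Iteration
only ever merges further, so candidate conservation
(Σ `n_candidates` = candidates in) holds at every step and the output is
stable under re-merging.

**Classification.** Precedence is total and deterministic:
CSEP > SEC > PRIM_CRBSI > PRIM_CLABSI > PRIM_OTHER. Secondary BSI (SEC)
requires a matching non-commensal isolate (genus + species string
equality after normalization; antibiogram concordance is not modeled)
from a non-blood, non-catheter-tip specimen within ± `secondary_window_days`
(7) of onset. Catheter-tip specimens are excluded from the SEC match by
design: the tip is catheter evidence, not an infection site, and since
SEC outranks CRBSI, counting it would make every tip-concordant
catheter infection classify as secondary. CRBSI requires a central line
overlapping `[onset − 48 h, onset]` *and* a concordant tip culture within
± 7 days (differential time-to-positivity is not in the data model);
CLABSI is the line overlap without tip evidence. SEC-before-CRBSI is the
conservative branch order where both match, since secondary attribution
removes the event from the central-line quality metric only when another
site genuinely explains it.

The polymicrobial, persistent, secondary-window and line-lookback
defaults (48 h / 14 d / ± 7 d / 48 h) are NHSN-era conventions; all are
config fields and all are surfaced in the pipeline's funnel report, so a
site can audit exactly what each knob did to its counts.

## What the synthetic cohort emulates

`generate_cohort()` exists so that every rule has a labeled exercise
without any protected data. It plants, per patient, at most one HABSI
case drawn at `habsi_rate_per_1000_patients` (default 14.7/1000; the
companion patient-day rate in a generated month comes out near 2 per
1000 patient-days) with subtype mix CRBSI .25 / CLABSI .20 / OTHER .30 /
SEC .15 / CSEP .10, each constructed to satisfy the rules exactly: paired
draws 50 minutes apart, fever bracketing onset, devices covering the
association window, concordant tip or site cultures, antimicrobial
orders inside the treatment window. Planted negatives exercise each
boundary: community-onset BSIs (positive draws < 48 h after admission),
uncorroborated single-draw commensal contaminants, persistent repeat
draws 4–10 days after a case's onset (which must be absorbed, not
recounted), linked re-admissions, and laboratory reports revised to
contaminants either inside or after the recall window. Twenty departments
with skewed volumes support by-place correlation analyses, and a gamma
model of reviewer confirmation delay (mean 14.58, SD 4.64 days) supports
the delay statistics.

Two error modes are deliberately one-sided, so each reporting failure
breaks exactly one side of the confusion matrix:

* `revision_after_recall_prob` plants post-recall contaminant corrections
  on non-case patients → false positives only;
* `commensal_single_draw_prob` withholds the corroborating second draw of
  commensal-organism cases → false negatives only. For this to stay
  one-sided the generator starts antimicrobials 60 h after onset in
  commensal cases, outside the clinical-sepsis treatment window —
  otherwise the sepsis pathway would quietly rescue the missed case.

The generator splits the field's "single blood draw" statistic in two:
`single_draw_prob` (default 0.0123, the observed fraction of single-draw
specimens) applies to pathogen cases, where one draw still confirms and
nothing is lost; the error-mode knob above (default 0) is the separate
dial for corroboration failure. Folding both into one knob would make
default-condition recovery seed-dependent, which would defeat the point
of a rules-by-construction generator.

Realism is explicitly *not* the goal — rule coverage is. Organism
frequencies are a fixed categorical draw over eight common pathogens and
six commensals; vitals are uniform noise inside (or outside) the flag
bands; there is no transmission structure, no seasonality, no
antibiogram, and contaminants never co-occur with a planted case in the
same patient. Perfect recovery on these cohorts therefore demonstrates
that the engine implements its own rules exactly — not that it would
agree this well with human reviewers on real data, where blunted fevers,
free-text-only signs and messy specimen logistics live.

```{r example}
co <- generate_cohort(cohort_config(n_patients = 1000, seed = 7))
res <- run_pipeline(co$bundle)
res
cm <- patient_level_confusion(res$events, co$truth, co$truth$patient_id)
compute_metrics(cm)
```

## Evaluation statistics

Evaluation is patient-level: a patient counts once, detected iff at least
one event. Proportion intervals are Clopper–Pearson exact (the method
behind published intervals of this kind is typically unstated; exact
intervals are the defensible default at these extreme proportions, and we
make no claim of matching any particular published interval). Cohen's
kappa uses the standard p₀/pₑ form with the large-sample standard error
`sqrt(p₀(1−p₀)/(N(1−pₑ)²))`. Display values are rounded half away from
zero to 2 decimals, the convention of surveillance reports; full
precision is retained alongside. Zero-denominator metrics are flagged
undefined rather than returned as NaN.

Confirmation delay is `date(confirmation) − date(first positive log-in)`
in whole days, grouped by the month of confirmation; the period mean is
the unweighted mean of monthly means (a turnaround-time convention that
weights a slow low-volume month equally), and the period SD is the SD of
the monthly means. Incidence is `1000 × events / denominator` for both
patients and patient-days, pooled and per stratum with a min–max range.
Monthly reports assign events to months by onset for counts and
incidence, but by confirmation month for delay — each statistic follows
its own definition.

## Numerical and degenerate-input choices

* Timestamps are compared on POSIXct seconds after minute truncation;
  date arithmetic (linkage gaps, commensal windows, patient-days, delay)
  is calendar-date arithmetic, immune to time-of-day.
* Ties in deduplication are broken by onset, then source-specimen label,
  making the pipeline invariant to input row order.
* Empty inputs flow through: an empty bundle yields zero events and an
  all-zero funnel; absent vitals yield all-false sign flags; an empty
  event set yields a header-only line list.
* Ingest never silently drops a row: accepted + rejected = input, with a
  per-row diagnostic on the rejected side. Implausible vital values
  (temperature outside 30–45 °C, HR outside 0–350, RR outside 0–150) are
  blanked with a warning rather than rejected wholesale.
* Overlapping stays for one patient and confirmation before onset are
  fatal data errors, not warnings: both indicate broken upstream joins.

## Problem sizes in the test suite

The suite's cohort runs use 10,000 patients over a 31-day month for the
recovery check (the scale at which the binomial case-count band around
147 is meaningful), 4,000 for each error-mode check, and 1,500 for the
byte-identical determinism check; smaller property tests run at dozens of
records against brute-force oracles (transitive-closure linkage, date
enumeration, closed-form kappa and Pearson r).

## Known limitations

* No free-text or NLP symptom extraction; antipyretic-adjusted fever
  inference is explicitly out of scope, so fever-criterion misses are a
  designed-in behavior, not a bug.
* Ward-level attribution of events (place of onset) is not modeled.
* CRBSI evidence is tip-concordance only; differential time-to-positivity
  would need draw-level result times the data model does not carry.
* The commensal corroboration and clinical-sepsis criteria are
  NHSN-style reconstructions; sites with institution-specific rule sheets
  should encode them through the configuration rather than assume these
  defaults match local policy.
* Reviewer confirmation (`confirmation_ts`) is an input, not a model: the
  package measures confirmation delay but does not simulate reviewer
  behavior beyond a gamma delay.
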