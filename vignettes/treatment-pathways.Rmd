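---
title: "Methods: claims-based treatment pathways in outpatient psychotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based treatment pathways in outpatient psychotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptpaths)
library(dplyr)
```

## The problem

Statutory health-insurance claims record *that* care was billed, not
why or how it felt: ambulatory care arrives as quarter-based treatment
cases with ICD-10-GM diagnoses and qualifiers, and psychotherapeutic
work appears as fee-schedule service codes on dates. Out of this,
`ptpaths` reconstructs the treatment trajectory of people with an
incident depression diagnosis — who entered psychotherapeutic care,
along which sequence of services, how long each stage took, and how
long they waited between the first contact with a psychotherapist and
the first actual therapy session — and compares two periods (before
and after a structural reform of outpatient psychotherapy that added a
consultation service and an application-free acute treatment).

Because claims data of this kind cannot be redistributed, the package
treats a synthetic claims generator as a first-class module: every
pipeline stage is specified, tested and demonstrated against generated
bundles with known ground truth.

## Cohort selection

A person enters the cohort when all of the following hold:

* **index diagnosis**: a qualifying depression code (any F32.x or
  F33.x, plus F34.1 and F38.1) in a treatment case of the index
  quarter. The diagnosis qualifier must match the sector — a confirmed
  ("gesichert") diagnosis only counts on ambulatory cases, a primary
  discharge diagnosis only on inpatient cases. This pairing is how the
  two qualifiers are used in German claims; it is a package decision
  and configurable via `selection_ruleset()`.
* **washout**: no qualifying diagnosis in any case of the four full
  calendar quarters before the index quarter. We read the 12-month
  lead-in as calendar quarters rather than 365 days because ambulatory
  diagnoses are only datable to the case's quarter.
* **age**: 21–90 at window start. Claims carry only the birth year, so
  age is `index year − birth year`; the bound is applied to that
  integer.
* **confirmation**: a second qualifying diagnosis in a case of a
  *different* calendar quarter whose start date lies inside the
  observation window. The window is 365 days from the first day of the
  index case, half-open `[start, start + 365)`. All intervals in the
  package are half-open in whole days — one convention everywhere
  prevents off-by-one drift between modules.
* **enrollment** (optional, on by default): continuous enrollment from
  washout start through window end. The source study's full protocol
  holds further criteria that are not public; this is the standard
  minimal surrogate and can be switched off.

Excluded persons are logged with the *first* failed criterion in the
fixed order index-diagnosis → washout → age → confirmation →
enrollment. The order is a package decision (the source material does
not state one); fixing and documenting it makes attrition tables
reproducible. `check_cohort()` re-verifies every returned member
against the raw tables with an independent per-person loop.

### Severity and the index case

Severity is read off the ICD code: mild (F32.0/.8/.9, F33.0/.8/.9,
F34.1, F38.1), moderate (F32.1, F33.1), severe (F32.2, F33.2), very
severe (F32.3, F33.3); F33.4 (in remission) gets no grade. When
several cases or diagnoses compete, the hierarchy is:

1. within a case, the worst diagnosis becomes the index diagnosis;
2. among concurrent cases, ambulatory beats inpatient;
3. then cases from psychotherapy/psychiatry-adjacent specialty groups
   (51, 53, 58, 59, 60, 61, 68) beat other specialties.

Ties that survive all three rules are broken by the lexicographically
smallest case id, and the event is flagged in the `tie_break` column —
the tie-break is a package decision, not an attributed one. "Concurrent"
is operationalised as sharing the earliest start date among the index
quarter's qualifying cases.

Comorbidity flags (alcohol, drugs, psychoses) are prefix matches over
all confirmed/discharge diagnoses in cases overlapping the window. The
defaults (F10; F11–F16, F18, F19; F20, F22–F25, F28, F29) follow the
Elixhauser-style mental-health blocks and are configurable; the
general-practice specialty set used for the diagnosis-site table
defaults to codes 01–03.

## Services, sessions and the 91-day rule

Service records are mapped through a code map (`ebm_code` → category,
unit minutes). Consultation and acute treatment are billed in
25-minute units, everything else in 50-minute units; all counts are
normalised to 50-minute session equivalents,
`sessions = unit_count × unit_minutes / 50`, and kept as exact
fractions — stage summaries report fractional means. Same-day rows of
one category are merged before any counting, because billing can split
one sitting into several rows. Unknown codes are ignored (claims
contain the entire fee schedule) but counted.

The **first contact** is the earliest consultation or probatory event
in the window; a same-day tie resolves to the consultation and is
flagged. **Therapy services** are guideline therapy (short- or
long-term, individual or group) plus acute treatment.

The **gap rule**: within one service type, if more than 91 days pass
between a service and the next same-type service, the later part of
that type's series is discarded. 91 days exactly is kept. Two
decisions are worth making explicit:

* the rule binds *same-type* services only, so it is applied per
  category over the whole window before segmentation, not across
  pathway stages;
* individual and group arms of short-/long-term therapy count as one
  type for the rule (and for pathway matching), mirroring how the
  stages are reported as "KZT (Einzel und Gruppe)".

`truncate_gaps()` is idempotent, which the suite checks on random
series.

## Pathways

A pathway is an exact ordered sequence of merged categories. The
pre-reform catalogue is Probatorik→KZT (1.1), Probatorik→LZT (1.2) and
Probatorik only (1.3); post-reform adds the consultation-led variants
(2.1/2.2, with the leading consultation optional — implemented as two
explicit variants sharing one id), Sprechstunde→Akutbehandlung (2.3),
Sprechstunde→Probatorik (2.4) and Sprechstunde only (2.5). Matching is
exact and exhaustive: a member matches a pathway only if their *full*
segment sequence equals it; interleaved sequences (a category
revisited after another category intervened) and sequences outside the
catalogue are reported as unmatched, never force-classified. A
catalogue with two identical sequences is refused at construction.

Per stage, the package reports session counts and durations (days
between first and last same-type service; a single service has
duration 0), the mean transition gap from the previous stage, and the
cumulative mean timeline (sum of mean durations and mean gaps of
stages 1..k). Where one pathway id covers two variants, stages are
reported per variant so positions line up. The stage-level "treatment
frequency" is mean duration divided by mean sessions (not sessions−1);
this is the reading that reproduces the published frequency figures
from the published stage means.

## Intervals

The interval population is members with both a first contact and at
least one therapy service whose first therapy is not before the
contact. Members whose only therapy precedes their first contact are
excluded and counted — post-reform, acute treatment can legitimately
start without a prior contact service, and a negative waiting time is
not meaningful in a time-to-treatment table. Whether the original
analysis dropped or zeroed such cases is not stated anywhere we can
check; exclusion-with-count is our documented choice. Summaries report
n, mean, SD (n−1), median (even n: mean of the central pair), min and
max, stratified by severity or therapy type on request; the
therapy-type rows use the gap to the first service *of that type*.

## Statistics

Group comparisons use the Mann–Whitney U test throughout, matching the
descriptive stance of the analysis the package implements: U from rank
sums with midranks, and a two-sided p-value from

* the exact null distribution of U when `n_x · n_y ≤ 400` and there
  are no ties, and
* the normal approximation with tie-corrected variance and continuity
  correction otherwise.

The exact/approximate switch and the continuity correction are package
decisions validated in the suite: a brute-force enumeration over all
group labellings reproduces the exact branch, and the approximation
stays within 0.02 of the exact p for tie-free samples of 15 per group.
Categorical variables are rank-tested on their integer coding, as is
customary for ordinal claims-table comparisons. Effect sizes follow
the scale of the variable: signed φ for binary (first row = first
period, first column = reference category), Cramér's V for nominal, η
for metric; `|φ| = V` on any 2×2 table is a tested invariant.
Significance is read at p ≤ 0.05 and **no multiple-testing correction
is applied** — the tables are descriptive, and readers comparing many
rows should keep that in mind.

## The synthetic generator

`generate_bundle()` draws, per person: demographics (sex, urbanicity,
age from a clamped normal), an index case in the index quarter with
one qualifying diagnosis whose grade follows the configured severity
mix, a confirmation case one or two quarters later, optional planted
comorbidity diagnoses, and a service sequence realising a pathway
drawn from the configured full-cohort pathway mix. Contaminated
persons violate exactly one criterion (washout diagnosis, missing
confirmation, or age) so that recovered exclusion reasons can be
compared to ground truth one-to-one.

Waiting times are discretised gamma draws (shape 2.8 by default):
right-skewed, median below mean, matching the qualitative shape of
observed claim gaps. Within-stage spacings are capped at 91 days so
generated ground truth stays well-defined under the gap rule, and a
rare person whose cumulative timeline would overflow the 365-day
window is shrunk proportionally (shrinking preserves the 91-day
bound). Consultation and acute sittings are emitted as two 25-minute
units, all others as one 50-minute unit, so one sitting is one session
equivalent everywhere.

The defaults are the study conditions: index quarters Q1 2016 / Q1
2018, the observed severity mixes (65.6/25.2/7.5/1.0/0.7% pre), the
published per-pathway shares among service users with the published
no-service mass (82.5% pre, 77.2% post), and planted overall mean
contact-to-therapy gaps of 72.5 days (pre) and 89.4 days (post). Two
deliberate modelling choices:

* The published post-reform per-pathway shares sum to 82.1% of service
  users while the published coverage count implies 77.1%; the
  generator follows the per-pathway shares and gives the residual
  17.9% to the unmatched mass. The discrepancy is in the source
  figures, not resolvable here.
* The published *overall* mean gaps (72.5/89.4 d) and the published
  *per-pathway* pre-therapy spans (e.g. 63.1 d for the short-term
  therapy pathway) are mutually inconsistent under the published
  pathway mix, because the overall table also contains
  sequence-unmatched members. The generator plants the overall means —
  the recovery targets — as the expected contact-to-therapy gap of
  every therapy pathway, computed per variant by assigning the
  final transition into therapy the mean that makes the stage
  expectations sum to the target. Per-pathway spans are therefore not
  separately planted.

What the generator does **not** emulate: correlated comorbidity
structure, costs, seasonal or regional patterns, the post-reform drop
in unspecific diagnoses, conversion pathways from short- to long-term
therapy beyond the window, or dropout mid-pathway. Passing the
recovery suite therefore shows that the pipeline's logic is faithful
under the stated data-generating assumptions — it does not validate
those assumptions against real claims.

## Numerical and interface choices

* Report arithmetic uses round-half-up at one decimal (two where
  needed), with an epsilon guard against binary representation error;
  raw counts are always kept next to percentages.
* Degenerate inputs yield marked `NA`s with warnings (zero-margin
  tables, constant metric variables, zero denominators), never silent
  `NaN`s.
* Bundles are exchanged as four UTF-8 CSV tables with ISO-8601 dates;
  `read_bundle()` ∘ `write_bundle()` is the identity on valid bundles
  and referential integrity is enforced on both paths.
* The package's interface is its functions: `run_pipeline()`
  orchestrates both periods end to end and `write_report()` emits
  every table as CSV, which together serve the role a shell entry
  point would.

## Problem sizes

The test suite exercises the pipeline at 1,500–5,000 persons per
period for behavioural tests and 20,000 per period for parameter
recovery; the acceptance script uses 20,000 per period. At that size
every recovered share sits within three standard errors of its planted
value and the exact-recovery rates (exclusion reasons, pathway labels)
are 100%, which is the package's chosen operating point for routine
verification; nothing in the pipeline is size-limited, and the
generator scales linearly.

```{r recovery-demo}
cfg <- scenario_config("pre", n_persons = 2000, seed = 7)
bundle <- generate_bundle(cfg)
sel <- select_cohort(bundle, c(cfg$index_year, cfg$index_quarter))
events <- truncate_gaps(map_services(sel$cohort, bundle))
assignments <- match_pathway(compress_to_segments(events),
                             pathway_catalogue("pre"))
gt <- ground_truth(cfg, bundle)
inner_join(assignments, gt, by = "person_id") |>
  summarise(pathway_recovery = mean(pathway_id == pathway))
```

## Limitations

Ambulatory diagnoses are only datable to the case period, so time from
*diagnosis* to first contact is out of reach by construction — the
package measures from the first contact service onward. The one-year
window undercounts long pathways (especially long-term therapy reached
via short-term therapy). Severity is the coded severity of the billing
diagnosis, not a clinical assessment. And all empirical statements in
this vignette and the README are statements about synthetic data
generated under the configured conditions.
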