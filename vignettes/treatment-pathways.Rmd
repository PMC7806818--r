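---
title: "Reconstructing myeloma treatment pathways from claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing myeloma treatment pathways from claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpathways)
```

`mmpathways` reconstructs the treatment journey of newly diagnosed
multiple-myeloma (MM) patients from administrative claims and estimates an
empirical Markov disease-progression model over treatment lines. This
vignette explains the procedures, the parameters that matter, the design
choices made where the methodology was genuinely open, and what the
bundled synthetic-data tests do and do not establish about real data.

## The cohort

The unit of analysis is a patient newly diagnosed with MM, identified by
the earliest claim coded ICD-9-CM 203, 203.0 or 203.0x — any claim
position, any setting. That date is the **index date**; it anchors
everything else. Inclusion requires age ≥ 18 at index (completed years,
floored), continuous enrollment for the 12 months before index
(operationalized as 365 days; configurable via `lookback_months`), at
least one further MM-coded claim strictly after index, and at least one
dispensing of an MM drug on or after index ("treated"). Exclusions: any
non-MM primary-cancer claim (ICD-9 140–208 except 203.0x) before index —
one claim suffices by default, `prior_cancer_min_claims` raises the bar —
and any plasma-cell-leukemia (203.1x) or other-immunoproliferative
(203.8x) code within 2 months of the first MM claim, operationalized as
61 days (`pcl_window_days`) because calendar-month arithmetic is
ambiguous.

Every excluded patient is logged with *all* triggered rules, the first in
the documented rule order flagged as primary, so the selection flow-chart
can be audited; selection is order-independent and partitions the input.
Follow-up runs from index to the earliest of death, dis-enrollment and
the administrative censor date (2017-12-31 by default). Diagnoses from
2012-06-01 onward fall in the post-bortezomib era (the date bortezomib
entered first-line reimbursement in the emulated system); earlier
diagnoses are pre-era. ASCT is a journey annotation — the first transplant
procedure on/after index — never a line boundary.

## Lines of therapy

Dispensings are the atoms: each covers
`[dispense_date, dispense_date + days_supply - 1]`. Line 1 starts at the
first dispensing on/after index. A line ends at the earliest of

* **(a) gap** — ≥ `gap_days` (60) consecutive days with no coverage from
  any drug of the line; the line's end date is its last covered day. A
  59-day gap keeps the line alive; a 60-day gap ends it.
* **(b) late addition** — a dispensing of a drug outside the line's set
  more than `addition_window_days` (90) days after line start; the line
  ends the day before and that dispensing opens the next line. Day 90
  itself still joins the line.
* **(c) death**, **(d) end of data.**

Drugs first dispensed within the 90-day window join the line's regimen;
re-dispensing an in-line drug never opens a line. The gap is measured in
uncovered days rather than between dispense dates — the standard claims
convention when a days supply is recorded — with `gap_basis =
"dispense_date"` available for sensitivity analysis. Three decisions the
rules as stated leave open, and how they are resolved here:

* **Same-day semantics at a switch.** All dispensings of one day form one
  event. If any of them triggers rule (b), the whole day belongs to the
  new line, so carried-over drugs dispensed on the switch day join the new
  regimen (switch semantics), while drugs merely *covered* past the switch
  do not.
* **Terminal ties.** When death, gap completion and data end could all
  close the final line, precedence is death, then gap, then data end — a
  death during the 60-day run-out is attributed to the line it follows.
* **Steroid-only intervals.** A steroid first dispensed > 90 days into a
  chemo line is, by rule (b), a new line of class SA. Whether such
  intervals are really maintenance is unresolvable from claims alone; the
  rules are applied as written.

Classification ignores steroids unless nothing else is present: NA =
novel agent(s) (bortezomib, thalidomide, lenalidomide) without
chemotherapy, CCNA = both, CA = chemotherapy only, SA = steroids only.
Named regimens follow the first-line taxonomy (melphalan triples checked
before the generic bortezomib + thalidomide rows, single-chemo "-based"
labels, two/three-chemo combinations, steroid); lenalidomide-only novel
lines — typical in later lines, where it is reimbursed after first-line
failure — are labelled "Lenalidomide-based" rather than collapsed into
"Other". The steroid dictionary (dexamethasone, prednisolone by default)
is a repo decision: no coding standard enumerates steroids, and
`mm_drug_dictionary(extra_steroids=)` extends it.

## The disease-progression model

Journey states are line-indexed: L1, L2, L3, with DEATH and CONTINUE
absorbing ("continue" = still on the current line at study end). Lines
beyond the third fold into L3 occupancy. A patient whose last line ended
by gap and who was then censored alive counts as CONTINUE — the published
figures carry no "untreated" state, and adding one would change every
denominator.

The model is the embedded discrete multinomial: p(dest | src) =
count(src → dest) / occupancy(src), per stratum. No rate matrix is
fitted and no smoothing applied — the quantities of interest are branch
percentages and median start-to-start gaps, and the maximum-likelihood
fractions are exactly those. Durations use a fixed 30.4375 days/month.
`estimate_transitions()` returns a classed fit with `print`, `summary`,
`coef`, `simulate` and `plot` methods; `to_sankey()` exports a
(state, depth) node graph whose links carry counts and branch
percentages, and which satisfies inflow = outflow at every non-absorbing
node by construction (verified by `check_flow_conservation()`).

## The Charlson/Deyo index

The 17 Deyo condition groups ship as a plain-text prefix table
(`extdata/deyo_icd9.csv`) so auditors can amend code sets without touching
code. Each group counts once; complicated diabetes silences uncomplicated
diabetes, moderate/severe liver disease silences mild, metastatic disease
silences other malignancy. The malignancy and metastatic groups are
**excluded from the score by default**: every patient in this cohort
carries a 200–208 code, which would add a constant 2 to everyone;
cohort-table CCI means of 0.6–1.9 are consistent with that choice. Set
`include_malignancy = TRUE` to restore them. The window is the 365 days
before (exclusive of) index. The four MM-associated comorbidity flags use
a window through the index date ("at diagnosis") and require ≥ 3
outpatient claims on distinct dates — repeat same-day claim lines are one
visit — or ≥ 1 inpatient claim.

## The synthetic generator

`sim_config()` encodes the study conditions the generator emulates, with
defaults calibrated to the published cohort structure: era mix 1862/4092
post, ASCT probability 0.11 pre / 0.15 post, per-stratum age
distributions (e.g. mean 57.0, SD 7.7 for post-era transplant
recipients), first-line class mixes (post-era non-transplanted:
863/466/44/209 over 1582), and per-stratum ground-truth transition
matrices echoing the published branch structure. The published post-era
transplant first-line branches (58.7% moved, 3.3% died, 36.0% continued)
sum to 98% after rounding; the continue branch is normalized to 0.380 so
rows are stochastic. Where no printed value exists (pre-era branch rows,
L3 rows, death sojourns), plausible values in the reported ranges were
fixed once and documented in the config defaults. Inter-line sojourns are
lognormal on start-to-start days (medians 11.6 and 6.8 months, σ = 0.5,
clamped at 105 days so every sojourn is realizable).

Realization is deliberately unambiguous: dispensings every 28 days with
28-day supply (continuous within-line coverage), inter-line gaps planted
at 75 days (safely past the 60-day rule), regimen switches only after day
90, and one RNG stream per patient derived from (seed, index) so growing
`n` never perturbs earlier patients. Under these conditions the pipeline
recovers every realized journey and line boundary exactly, which is what
the round-trip tests assert; the 60/90-day boundary cases are exercised
by dedicated fixtures instead. Exclusion violations are planted
disjointly, one rule per corrupted patient, and recorded in the truth.
Truth records the *realized* journey after censoring at 2017-12-31;
recovery tests place index dates in 2007 so truncation is negligible and
the realized matrix equals the intended one.

What passing these tests shows: the algorithms implement the stated rules
exactly and recover known structure at the stated sample sizes. What they
do not show: robustness to the mess of real claims — inpatient cycle
gaps without days supply, overlapping early refills, transfers and
re-enrollment, coding drift — none of which the generator emulates. The
generator is a correctness harness, not a realism benchmark; no cost
fields, provider networks or staging information are produced.

## Problem sizes and numerical choices

Test and verification runs use 1000 randomized dispensing histories
against a literal day-by-day oracle, 5000 patients for transition
recovery (3 binomial SEs ≈ ±0.021), 2000 for sojourn-median recovery
(±0.5 months), 500 for exclusion accounting and 500 random profiles for
the Charlson oracle — sizes at which the binomial/lognormal sampling
error is well inside the asserted tolerances. Transition rows sum to 1 to
within 1e-9 (they are exact ratios); percentages are reported to one
decimal; all dates are day-granular ISO-8601; malformed input rows are
rejected with reasons, never silently dropped; rendered tables mask every
non-zero count below 3 (token `"<3"`, configurable) including the
percentage of a masked cell.

## Known limitations

Single-payer, single-registry semantics: one enrollment spell per
patient, at most one death record. ICD-10, Elixhauser, dose/intensity
analysis, and survival-curve estimation are out of scope. The Markov
estimates are purely empirical; with thin strata, branch probabilities
are noisy and the small-cell mask will hide much of the table —
stratify coarsely when n is small.
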