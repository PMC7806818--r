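# mmpathways

Treatment-pathway reconstruction and disease-progression modelling for
multiple myeloma (MM) from patient-level administrative claims.

Real-world evidence studies of MM often have nothing but claims to work
with: dated diagnosis codes, drug dispensings with a days supply, procedure
claims, a death registry. `mmpathways` turns those five flat tables into
the analysis objects such studies report:

- **Cohort selection** — newly diagnosed MM patients (ICD-9 203/203.0x),
  aged ≥ 18, with 12 months of pre-index enrollment, a confirmatory MM
  visit and at least one MM-drug dispensing; exclusion of prior primary
  cancers and of plasma-cell leukemia / other immunoproliferative codes
  within 2 months of diagnosis. Every exclusion is logged with its rule.
- **Lines of therapy (LOT)** — built from dispensings: a line ends at a
  ≥ 60-day gap in coverage of the line's drugs, at a regimen addition more
  than 90 days after line start, at death, or at end of data; drugs added
  within 90 days join the line. Lines are classified (NA / CCNA / CA / SA)
  and named (e.g. "Bortezomib + Thalidomide", "Melphalan-based").
- **Charlson/Deyo comorbidity index** from ICD-9-CM claims in the
  12 months before index, plus the four MM-associated comorbidity flags
  (anemia, renal failure, pneumonia, bone fracture) under the
  ≥ 3-outpatient-visits-or-≥ 1-hospitalization rule.
- **Disease-progression model (DPM)** — an empirical Markov model over
  journey states L1 → L2 → L3 with absorbing DEATH and CONTINUE:
  p(dest | src) = transitions(src → dest) / occupancy(src), stratified by
  era × transplant status × first-line class, with inter-line sojourn
  summaries (months = days / 30.4375) and Sankey graph export.
- **Privacy-suppressed reporting** — demographics and regimen tables in
  which every non-zero count below 3 is masked.
- **Synthetic claims generator** — emulates the structure of a national
  claims database (monthly-granular enrollment, ICD-9 codes, dispensings,
  ASCT procedures, death records) from a ground-truth Markov journey
  model, so the whole pipeline is testable without restricted registry
  access. The truth (journeys, line boundaries, planted exclusion
  violations) is serialized next to the bundle.

## Worked example

```r
library(mmpathways)

sim <- simulate_bundle(sim_config(n_patients = 200, seed = 42))
sel <- apply_selection(sim$bundle)
lines <- cohort_lines(sim$bundle, sel$cohort)
journeys <- cohort_journeys(lines, sel$cohort)
fit <- estimate_transitions(journeys, strata = c("period", "asct"))
fit
```

```
Markov disease-progression model (200 journeys, stratified by period x asct)

stratum: post_bortezomib/FALSE
     L2    L3 DEATH CONTINUE
L1 0.46 0.000 0.368    0.172
L2 0.00 0.475 0.400    0.125
L3 0.00 0.000 0.632    0.368
...
```

Each row is a journey state and each column the empirical probability of
the next state: of the simulated post-era non-transplanted patients, 46%
moved from first to second line, 36.8% died on first line, and 17.2% were
still on first-line treatment at study end. `summary(fit)` adds the
inter-line duration table; `coef(fit)` returns the per-stratum transition
matrices; `simulate(fit, nsim)` draws journeys from the fitted model;
`plot(fit)` renders the Sankey band diagram, and `to_sankey()` /
`write_sankey_json()` export the graph for external renderers.

`run_pipeline(out_dir, simulate = sim_config(...))` (or with
`input = "dir/"` holding the five CSVs) executes every stage and writes
`cohort.csv`, `exclusions.csv`, `comorbidity.csv`, `lines.csv`,
`transitions.csv`, `durations.csv`, `sankey*.json`, suppressed
`table1_*.csv` / `table2.csv`, and a deterministic `run.log`. A thin
command-line wrapper lives at `inst/scripts/mmpathways.R`.

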