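# eqaplan

Medical laboratories accredited under ISO 15189 must take part in
inter-laboratory comparisons — external quality assessment (EQA, also
called proficiency testing) schemes — but the standard does not say *how
often*. For human-genetics laboratories diagnosing rare diseases this is a
real planning problem: hundreds of low-volume tests, dozens of schemes
with overlapping scopes (technique, genotyping, clinical interpretation),
and a budget that rules out participating in everything every year.

`eqaplan` turns a concrete set of national participation rules into an
executable toolkit:

* **Error-rate model.** The annual test volume itself can serve as a
  performance indicator. With `k` errors observed in `n` analyses and a
  noninformative Beta prior on the error rate `p`, the posterior is
  `Beta(k + a₀, n − k + a₀)` (uniform prior `a₀ = 1`, Jeffreys
  `a₀ = ½`). For zero errors under the uniform prior, the one-sided
  upper credible bound is `1 − (1 − level)^(1/(n+1))`; solving
  `bound(n) = 1%` at the 95% level gives `n* = ln(0.05)/ln(0.99) − 1 ≈
  297.07`, i.e. **297 tests/year** (nearest-integer rounding; a strict
  ceiling mode gives 298). A lab running at least that volume error-free
  can claim its error rate lies between 0% and 1% with 95% credibility.
* **Participation rules.** Every technique/platform must be assessed
  annually (virtual schemes count); a technique validated for more than 3
  years with ≥ 297 tests/year and no recent method change drops to
  triennial, documented in the QMS. Genotyping + interpretation of each
  clinical indication must be covered at least once per rolling 3-year
  window. A genotyping or critical interpretation error forces
  participation the following year; clerical/analytical errors require
  documented CAPA.
* **Planner + auditor.** `build_plan()` selects a fee-minimal compliant
  schedule per year (exact subset enumeration up to 12 candidate schemes,
  greedy weighted set cover above); `audit_compliance()` independently
  re-derives the rules and verdicts any plan or history.
* **Budgeting.** Exact integer-cent cost sums, scenario comparison
  (`compare_scenarios()`), per-center budget shares.
* **Synthetic fixtures.** `generate_inventory()` and friends emulate a
  90-scheme / 72-indication national inventory (scope mix 65 TGI / 21 TG /
  1 GI / 1 T / 1 G / 1 I, 15 indications with 2–3 providers) so everything
  is testable offline.

## Worked example

Using the small inventory, center profile and participation history
shipped under `inst/extdata/` (a lab running sequencing, MLPA, fragment
analysis and karyotyping, with a genotyping error scored in 2023):

```r
library(eqaplan)
inv  <- read_inventory(system.file("extdata", "schemes.csv", package = "eqaplan"))
ctr  <- read_center(system.file("extdata", "center.yaml", package = "eqaplan"))
hist <- read_history(system.file("extdata", "history.csv", package = "eqaplan"))

minn <- min_volume_for_threshold(0.01)   # 297
p <- build_plan(ctr, inv, hist, 2024:2026, minn)
print(p)
#> EQA participation plan for C1, 2024-2026 (minn = 297)
#>   2024: EQA-002, EQA-006, EQA-007
#>   2025: EQA-006, EQA-008
#>   2026: EQA-008
#>   triennial exemptions: sequencing

print(annual_cost(p, inv))
#>   2024: €1,650
#>   2025: €1,250
#>   2026: €850
#>   mean: €1,250/year

any_overdue(audit_compliance(ctr, inv, hist, p, 2024:2026, minn))
#> [1] FALSE
```

Reading the plan: the 2023 genotyping error on the cystic-fibrosis scheme
forces coverage of that indication in 2024 (`EQA-002`, the cheaper of the
two providers); sequencing is triennially exempt (validated since 2015,
450 tests/year ≥ 297, no method change) so no dedicated sequencing scheme
is bought after its obligations are met; karyotyping had a 2022 method
change, so it stays annual (`EQA-006`) until the 3-year clock clears. The
independent auditor confirms the plan leaves nothing overdue.

The same pipeline is available from the command line (installed as
`exec/eqaplan`):

```sh
eqaplan minn --threshold 0.01
eqaplan meta-ci --n 7 --mean 0.89 --sd 0.82
eqaplan plan --inventory schemes.csv --center center.yaml \
        --history history.csv --years 2024:2026 --out out/
eqaplan audit --inventory schemes.csv --center center.yaml \
        --history history.csv --plan out/plan.csv --window 2024:2026
eqaplan budget --plan out/plan.csv --inventory schemes.csv \
        --scenario-cost full=117400 --scenario-cost hist=82000
eqaplan simulate --seed 1 --out fixtures/
```

`eqaplan audit` exits nonzero when any requirement is overdue.

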