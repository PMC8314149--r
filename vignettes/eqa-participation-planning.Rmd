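---
title: "Planning EQA participation: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning EQA participation: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqaplan)
```

## The problem

Human-genetics laboratories diagnosing rare diseases run many assays at
low annual volumes. Accreditation (ISO 15189) demands participation in
external quality assessment (EQA) schemes, but annual participation in
every relevant scheme is neither feasible nor economically defensible.
`eqaplan` implements a rule set that rationalizes participation frequency
while keeping quality claims auditable, together with the statistical
model that justifies its volume threshold.

## The error-rate model

Treat a laboratory's analyses in a year as `n` Bernoulli trials with
unknown error probability `p`, of which `k` erred. Under a noninformative
Beta prior the posterior is conjugate:

* uniform prior `Beta(1, 1)`: posterior `Beta(k + 1, n − k + 1)`;
* Jeffreys prior `Beta(½, ½)`: posterior `Beta(k + ½, n − k + ½)`.

The quality claim is one-sided: "with 95% credibility the error rate is
below θ". For `k = 0` under the uniform prior the posterior CDF is
`1 − (1 − p)^(n+1)`, so the upper bound has the closed form
`1 − (1 − level)^(1/(n+1))`; the generic path uses `qbeta()` and must
agree with the closed form to 1e−9 (a property the test suite checks for
all `n ≤ 10,000`).

`min_volume_for_threshold()` inverts the bound in a continuous `n`
(Brent's method on the smooth, strictly decreasing bound function,
bracketed at `[k, 10^8]`, tolerance 1e−9) and rounds.

```{r}
min_volume_for_threshold(0.01)
```

### Parameters and conventions that matter

* **Threshold θ = 1%**, the working error-rate ceiling for genetic tests
  (chosen in light of provider-wide analytical error rates around 1.4%
  and literature rates between roughly 0% and 4%).
* **Level 0.95, one-sided upper.** Two-sided intervals use the
  `1 − (1−level)/2` quantile and give materially larger volumes; they are
  exposed but not the default.
* **Prior: uniform.** The continuous solution at θ = 1% is
  `ln(0.05)/ln(0.99) − 1 ≈ 297.07`; Jeffreys gives a much smaller volume
  (the test suite pins it against an independent CDF bisection) and is an
  option, not the default.
* **Rounding: nearest integer.** The published threshold of 297
  tests/year equals the nearest integer to 297.07; a strict reading
  ("bound ≤ θ for the integer volume") would give 298, available as
  `rounding = "ceiling"`. This is a deliberate, documented convention:
  the quantile convention of the original analysis is not recoverable,
  and only nearest-integer rounding reproduces the published figure.
* **`k = 1`** expresses the "(n−1)/n correct" scenario; there is no
  separate code path.

`t_confidence_interval()` covers the companion meta-summary use case:
a literature row reporting a mean error-rate percentage, its SD and the
number of investigated scenarios yields `mean ± t₀.₉₇₅,ₙ₋₁ · sd/√n`.
Bounds are reported at two decimals, as such tables print them; some
published rows are computed from unrounded means/SDs and therefore
differ in the second decimal from what their printed inputs give — the
tests assert only rows that reproduce from printed inputs.

## Participation rules

`derive_requirements()` emits, for a given plan year:

* one **technique-coverage** requirement per technique the center runs —
  annual, unless the *triennial exemption* applies: validated more than 3
  years before January 1 of the plan year (strict), annual volume at
  least the model's minimum (297 by default), and no method change within
  3 years. The exemption must be documented in the QMS; an undocumented
  one is planned as triennial but flagged by the auditor.
* one triennial **genotyping/interpretation** requirement per clinical
  indication in the center's scope.

`apply_performance_rules()` adds one-shot escalations: a genotyping or
critical interpretation error in year Y forces participation in a scheme
covering that indication in year Y+1. Clerical/analytical errors change
no frequency but must carry documented CAPA.

Matching semantics (`satisfies_requirement()`): any scheme listing a
technique covers it, including virtual/dry schemes (mock cases, images,
VCF files); genotyping/interpretation is discharged by a same-indication
scheme assessing genotyping *or* interpretation — an interpretation-only
virtual scheme counts, a technique-only scheme does not.

### Design choices where the rules were open

* **Rolling windows.** "At least every 3 years" is read as: at least one
  participation in every window of 3 consecutive calendar years, seeded
  by the history (coverage in year `c` makes the next obligation due in
  `c + 3`). Some countries align such rules to fixed accreditation
  cycles instead; rolling windows are stricter, history-seedable and
  need no cycle anchor.
* **Never-covered obligations** are due in the first plan year
  (conservative), while the auditor flags them as overdue only once a
  full 3-year window has elapsed without coverage.
* **"Significant volume change"** defaults to ±50% year-over-year
  (configurable); no published figure exists.
* **Escalations require a genotyping/interpretation-capable scheme** for
  the affected indication; a technique-only scheme does not discharge
  them.
* **Interpretation-only schemes discharge the whole
  genotyping/interpretation requirement**, following the rule's explicit
  allowance for virtual clinical-case schemes.
* **Infeasibility is an error**, not silent omission: if no scheme can
  satisfy a requirement, planning aborts naming the subject — the rule
  set presumes accredited schemes exist for a center's scope.

## The planner and its optimality claim

Per year, the due requirements form a weighted set-cover instance over
the schemes offered that year. With ≤ 12 candidates the planner
enumerates all subsets (exact); otherwise it runs the classic greedy
cover (best coverage-per-euro, then redundancy pruning). Ties break by
fee, then scope breadth (TGI > TG > others), then scheme id, with
round-robin rotation among exactly interchangeable schemes anchored on
the year index — plans are deterministic, byte-identical across runs.

Joint optimization over a multi-year horizon would require enumerating
`2^(m·years)` assignments; the planner is instead *myopically* optimal:
triennial obligations are deferred to their deadline year, and each
year's selection is cost-minimal for that year's due set. The test
suite's brute-force oracle verifies exactly this property — for every
year, substituting any cheaper subset of schemes (full enumeration) and
re-running the **independent auditor** breaks compliance — and verifies
that greedy never beats the exact optimizer.

`audit_compliance()` shares the rule definitions but none of the
selection machinery: it re-derives requirements per year, checks recorded
participations (history and/or plan) against the annual and rolling-window
rules, and emits per-subject findings: `met`, `due_this_year` (the
obligation matures exactly in the still-open final year), `overdue`,
`exempt_documented` (satisfied under a triennial exemption, with a flag
when the QMS documentation is missing) and `capa_missing`.

## Budgeting

All fees are integer euro cents; sums are exact and locale-independent.
`compare_scenarios()` reports `100·(a − b)/a` rounded half-up to integer
percent — comparing a historical €82,000 with a guideline-plan €70,600
gives 14%. `per_center_budget()` rounds an equal split to a configurable
step (default €100): €70,600 over 8 centers gives €8,800/center. (A
published per-center estimate of ~€9,000 rests on unrounded commercial
prices and is not exactly recoverable from the printed aggregates, so it
is not asserted.)

## What the synthetic generator emulates — and what it does not

`generate_inventory()` reproduces the *structure* of a national scheme
inventory: 90 schemes over 72 rare-disease indications; scope mix
65 TGI / 21 TG / 1 GI / 1 T / 1 G / 1 I; 15 indications duplicated across
2–3 providers (12 doubles, 3 triples — the split is forced by the
counts); fees uniform €500–€2,500 (no per-scheme fees are published, so
fees are synthetic by necessity); a fixed 7-term technique vocabulary
assigned 1–3 per indication; interpretation-only schemes virtual, others
wet with probability 0.85. Centers draw about half of the eligible
indications, log-normal volumes (median 150 tests/year, σ_log = 1 —
typical for rare-disease assays where most volumes are well below the
297 threshold), validation dates 0–10 years back, a 20% chance of a
method change, 90% exemption documentation. Histories participate in
each in-scope scheme with probability 0.7 and score errors at 1% (the
threshold itself; the ~1.4% provider figure is a plausible alternative),
split uniformly over the four error categories.

Not emulated: real scheme names/providers/fees, historical participation
counts, correlation between a center's volumes and its indication mix,
scheme entry/exit over years (offered-year restrictions are supported but
off by default). A green test therefore establishes that the *rules and
algorithms* behave as specified on structurally realistic inputs — not
that any real inventory is reproduced.

Generators are deterministic per seed with independent streams
(inventory/center/history take separate seeds), and centers only draw
indications for which a genotyping/interpretation-capable scheme exists,
keeping every generated instance plannable.

## Numerical choices and degenerate inputs

* Quantile inversion: `uniroot` at tolerance 1e−9 on a bracket grown
  geometrically from `n = 10`; infeasible thresholds (bound never
  reaching θ below `n = 10^8`) error out.
* `n = k = 0` returns the prior itself; a threshold already met by the
  prior returns `n = k`.
* Money: integer cents end-to-end; half-up rounding for means, percents
  and budget steps (base R's banker's rounding would make €8,825 → €8,850
  at a €50 step irreproducible).
* Indication keys compare case-insensitively after whitespace
  normalization; technique ids are exact tokens.
* The exhaustive optimizer refuses more than 14 candidates (2^14 subsets)
  rather than silently degrading.

## Known limitations

Ring tests (small ad-hoc inter-laboratory comparisons) are out of scope,
as are provider catalog retrieval, sample logistics, multi-center pooled
participation and any hierarchical modeling across laboratories. The
planner's optimality is per-year conditional (see above), not global over
the horizon; a cheaper plan that covers a triennial obligation early to
exploit a scheme bought for other reasons can exist in principle — the
planner does exploit such coverage when it happens, but does not search
for it.
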