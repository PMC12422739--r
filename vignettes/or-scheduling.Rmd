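---
title: "Weekly operating-room scheduling: model, solvers and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weekly operating-room scheduling: model, solvers and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsched)
```

## The scheduling problem

`orsched` schedules elective total knee and hip arthroplasty (TKA/THA) for
one planning week on a discrete block grid. The resources describe a
high-volume arthroplasty service: 5 operating rooms open every workday of a
5-day horizon, 11 surgeons, a 540-minute regular day (08:00–17:00), up to
120 further minutes of penalized overtime per room-day, and 30 minutes of
turnover cleaning between consecutive cases in a room. Durations are
rounded up to whole blocks of 10 or 15 minutes, the two granularities a
booking office would realistically use.

Each waitlisted case carries a pre-assigned surgeon; surgeons are available
every day except 0–2 weekly off-days. Cases may be left on the waitlist —
the pool deliberately exceeds one week's capacity — except high-priority
cases, which must be scheduled. The planning objective, in minutes,

$$\text{objective} \;=\; \lambda \cdot \text{overtime} \;+\;
  \text{underutilization}, \qquad \lambda = 2,$$

sums over all room-days; overtime is activity past 17:00 (penalized double
because after-hours staffing costs roughly twice regular time),
underutilization is regular time covered by neither surgery nor cleaning.
All rooms are open every day, so a room-day that receives no surgeon counts
as fully idle.

Three formulations grade surgeon–room flexibility:

* **Any** — any case may go to any room at any time; rooms are never
  double-booked (with a cleaning block between cases) and a surgeon is
  never in two rooms at once, but a surgeon's day may hop across rooms.
* **Split** — additionally at most 2 surgeons per room-day and at most 1
  room per surgeon per day.
* **MSSP** — exactly one surgeon per room-day. Room-days are first
  dedicated to surgeons by a max-min fair allocation; the week then
  decomposes into one multiple-subset-sum packing problem per surgeon,
  which is what makes this formulation both clinically standard and
  computationally easy.

Because the feasible sets nest, optimal planned objectives always satisfy
$\text{Any} \le \text{Split} \le \text{MSSP}$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_rooms` × `horizon_days` | 5 × 5 | room-days per week |
| `n_surgeons` | 11 | surgeons sharing the rooms |
| `block_minutes` | 10 | grid quantum (10 or 15 min) |
| `regular_day_minutes` | 540 | regular day, 08:00–17:00 |
| `max_overtime_minutes` | 120 | penalized overtime horizon per room-day |
| `cleaning_minutes` | 30 | turnover between consecutive cases |
| `lambda_overtime` | 2 | cost of an overtime minute in idle-minutes |
| `waitlist_size` | 500 | weekly case pool (≈ 4 weeks of demand) |
| `p_high` | 0.05 | fraction of mandatory high-priority cases |

The regular day is a design choice: the institutional constraint fixes only
the 17:00 overtime boundary, so the package uses a 9-hour day and makes it
configurable. The overtime horizon must be finite for a finite grid; 120
minutes is generous for joint replacement and also configurable.

## Synthetic waitlists and predictors

True durations are lognormal per procedure — the standard operating-room
assumption for right-skewed operative times — with defaults
$\ln \text{DOS}_{TKA} \sim N(\ln 90, 0.30^2)$ and
$\ln \text{DOS}_{THA} \sim N(\ln 95, 0.32^2)$ (means ≈ 94 and 100 minutes).
The TKA share of the mix, 0.606, follows the relative volumes of the two
procedures in the large surgical registry this setting emulates. Surgeons
are assigned uniformly at random (registry data carry no surgeon identity).

Three predictors fill `predicted_dos`:

* **hindsight** — the truth; the perfect-information bound;
* **mean** — every case booked at its procedure's mean DOS, mimicking
  standard booking practice;
* **noisy oracle** — truth plus additive zero-mean Gaussian noise in
  minutes (floored at 15), standing in for a patient-level ML model. It is
  defined entirely by its operating point: `calibrate_sigma(a, 30)` returns
  the noise SD such that a fraction `a` of predictions falls within 30
  minutes of the truth, and the defaults pin TKA to 78.1% and THA to 75.4%
  — the published test accuracies of registry-trained DOS models. That
  inversion is exact: $\sigma = 30 / \Phi^{-1}((1+a)/2)$, ≈ 24.4 and 25.9
  minutes.

What the generator does **not** emulate: patient-level covariates (the
noise is exchangeable across cases), any systematic bias between predicted
and realized durations, secular drift between a training and deployment
period, and surgeon-specific speed. These omissions matter for
interpretation; see *Regimes and limitations*.

## Solvers

* **MSSP** is solved exactly. For each surgeon, a dynamic program over the
  joint virtual occupancy of their allocated room-days (a case of $w$
  blocks occupies $w + g$ with $g$ the cleaning blocks; a non-empty bin
  forgives one trailing $g$) enumerates all reachable occupancy vectors and
  picks the cost-minimal one, with deterministic backtracking. Mandatory
  cases are processed without a skip transition, so infeasibility of the
  high-priority demand is detected, not approximated. Surgeons hold at
  most 3 room-days under the default resources; with more, bins are solved
  exactly three at a time and the result is flagged "best found".
* **Small Any/Split instances** (≤ ~10 cases on a toy grid) are solved by
  depth-first branch-and-bound over case placements with an admissible
  bound (committed overtime plus idle that the remaining volume cannot
  cover). Any's leaves are timetabled exactly by enumerating execution
  orders through serial schedule generation — optimal for this regular
  objective, since left-shifted schedules dominate. The test suite checks
  these engines case-by-case against an independent exhaustive oracle.
* **Large Any/Split instances** use construction plus first-improvement
  relocation/swap local search. Split starts from the exact MSSP solution;
  Any considers three candidates — the Split solution improved in the Any
  neighbourhood, a surgeon-agnostic exact-fill packing (per-bin subset-sum
  DP), and a time-aware construction that fills rooms on the time axis and
  only starts a case when its surgeon is free (gap-free by construction) —
  timetables each with a family of deterministic greedy priority rules, and
  returns the cheapest, falling back to the Split solution if none beats
  it. Ties prefer the surgeon-agnostic candidates, because the unrestricted
  formulation's true optima are indifferent to surgeon identity and a
  generic solver would return such mixed solutions. The warm-start
  fallback makes the planned nesting $\text{Any} \le \text{Split} \le
  \text{MSSP}$ hold on every instance, not just in expectation.

Everything is deterministic given the configuration seed: fixed scan
orders, lexicographic tie-breaks, and a canonical (day, room, start, case)
ordering of the output. `solver_gap` is reported as 0 on exact paths and
unknown on heuristic paths.

## Realization semantics

Realization replays a plan against true durations on the same block grid —
rooms are booked by the block, so a case occupies its true duration rounded
up. Within a room-day, cases keep their planned order; each starts at the
later of the room being ready (previous end + cleaning) and its surgeon
being free anywhere in the hospital, the channel through which a surgeon
who runs long in room $r$ cascades delay into room $r'$. Under the default
`compress` policy cases may pull forward when room and surgeon are free
early; `hold` additionally forbids starting before the planned time
(sensitivity analysis — booking offices differ on early starts). Nothing is
cancelled: once assigned, a surgeon performs their case.

Per room-day, realized overtime is the last surgery end past the regular
day and realized idle is the regular time covered by neither surgery nor
between-case cleaning; mid-day surgeon-wait gaps and end-of-day slack are
deliberately the same kind of idle (one definition, conserved exactly:
surgery + cleaning + idle = 540 in every room-day). With oracle predictions
realization reproduces the plan minute for minute, which is why perfect
hindsight weeks measure exactly 0 overtime and 0 idle.

## The paired simulation

`run_simulation()` runs the weekly experiment: per week one waitlist and
one availability pattern are drawn and shared by all predictor arms and all
formulations under comparison (the paired design), each arm is planned,
realized and measured, and the weekly series feed mean (SD) summaries,
two-stage-vs-mean win rates, paired Wilcoxon signed-rank tests (exact for
≤ 25 untied pairs, tie-corrected normal approximation otherwise), and
unpaired t / ANOVA comparisons across formulations and schedule
parameters. Waitlists are redrawn independently each week with no
carry-over of unscheduled cases, and the MSSP allocation is redrawn from
each week's availability. All randomness flows from one master seed
through named streams (`derive_seed(master, week, stream)`), so any week of
any arm can be replayed in isolation; the run manifest records every
derived seed.

Problem sizes used in the package's own validation: exact-oracle sweeps on
2-room/1-day toys of 4–6 cases; nesting and formulation comparisons on
100-case weeks at 15-minute blocks; paired two-stage-vs-mean experiments on
500-case weeks over 50 weeks; conservation checks over a 104-week run.

## Regimes and limitations

Two findings from the package's own experiments deserve emphasis, because
they delimit what the synthetic defaults can and cannot show.

First, the two-stage advantage over mean booking is governed by the ratio
of *population heterogeneity* to *prediction noise*. The calibrated noisy
predictor has ≈ 24–26 minutes of error SD by construction; under the
default lognormal spread (`sdlog` 0.30–0.32, population SD ≈ 29–32 min) the
per-procedure mean booking is itself accurate to within 30 minutes about
73% of the time — nearly as good as the predictor — and additionally enjoys
protective slack from ceiling-to-block rounding of the mean. In this regime
the paired experiment measures win rates far below those reported on real
registry data, where patient-level variability dominates model error. When
heterogeneity is widened (`sdlog` 0.45), the per-case predictor wins the
majority of paired weeks, as the test suite demonstrates. Users studying
predict-then-optimize gains should therefore treat the duration spread as
the critical sensitivity parameter.

Second, with an *unbiased* predictor the realized penalty of the
unrestricted Any formulation is modest: under `compress`, early starts
offset late ones, and the surgeon-mixing cascade adds variance more than
mean. Registry-based studies in which predictive bookings systematically
understate realized room time sit in a push-only regime where the cascade
compounds; an unbiased stand-in cannot reach that regime without inventing
a bias that published accuracies do not quantify. The constructed-example
cascade tests (underestimated cross-room chains never realize better than
same-room chains) verify the mechanism itself.

Other known limitations: no recovery-bed, ward or staffing constraints; no
emergency arrivals, cancellations or intra-day re-optimization; no
carry-over waitlist dynamics; availability can leave a day with fewer
available surgeons than rooms, in which case an MSSP room-day is
necessarily idle (no surgeon may hold two rooms on one day); and heuristic
Any/Split solutions on large instances are best-found, not certified
optimal — only their nesting relation is guaranteed.
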