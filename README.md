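# orsched — predict-then-optimize elective operating-room scheduling

`orsched` builds and stress-tests weekly operating-room schedules for
high-volume elective joint replacement (total knee and hip arthroplasty,
TKA/THA). It is aimed at operations-research and health-systems analysts who
want to study **two-stage scheduling** — first predict each patient's
duration of surgery (DOS), then optimize the week's schedule on those
predictions — and to measure what actually happens when the plan meets the
true durations.

## The model

A planning week is a block-discretized grid: `n_rooms × horizon_days`
room-days, each with `R` regular minutes (default 540, 08:00–17:00) plus a
penalized overtime horizon (default 120 min), durations rounded **up** to
10- or 15-minute blocks, and 30 minutes of turnover cleaning between
consecutive cases in a room. Scheduling selects cases from a waitlist
(high-priority cases are mandatory, the rest optional) to minimize

```
objective = λ · overtime + underutilization        (λ = 2 by default)
```

summed over all room-days, where overtime is activity past the regular day
and underutilization is regular time covered by neither surgery nor
cleaning. Three integer-programming formulations differ in surgeon-room
flexibility:

| formulation | constraint set |
|---|---|
| **Any**   | any surgery, any room, any time; rooms never double-booked; a surgeon never operates in two rooms at once |
| **Split** | as Any, plus ≤ 2 surgeons per room-day and ≤ 1 room per surgeon-day |
| **MSSP**  | one surgeon per room-day (max-min fair room allocation); the week decomposes into per-surgeon multiple subset sum problems |

Solvers: MSSP is solved **exactly** by dynamic programming over each
surgeon's joint room-day occupancy; small Any/Split instances are solved
exactly by branch-and-bound (with exact timetabling of surgeon-across-room
interleavings); large Any/Split instances use construction heuristics plus
local search, warm-started from the next more constrained formulation so
that planned objectives always satisfy `Any ≤ Split ≤ MSSP`.

A **realization engine** replays any planned schedule against the true
durations: cases run in planned order, each starting when its room is clean
*and its surgeon is free across all rooms* — so a surgeon who runs long in
one room cascades delay into another. Predictors provided: a hindsight
oracle, per-procedure mean booking (the institutional standard), and a
calibrated noisy stand-in for a patient-level ML model, pinned to a target
accuracy-within-30-minutes via `calibrate_sigma()`.

## Worked example

```r
library(orsched)

cfg   <- schedule_config()        # 5 rooms, 11 surgeons, 5 days, 10-min blocks
model <- duration_model()         # lognormal TKA/THA durations, calibrated noise
waitlist     <- generate_waitlist(500, model, n_surgeons = cfg$n_surgeons,
                                  p_high = 0.05, seed = 2024)
availability <- sample_availability(cfg, seed = 2024)

booked  <- predict_noisy_oracle(waitlist, model$noise_sigma,
                                floor = model$floor_minutes, seed = 2024)
buffer_accuracy(booked, 30)
#> [1] 0.794

planned <- solve_schedule(build_mssp(booked, cfg, availability))
planned
#> <planned_schedule> MSSP: 114 cases scheduled (386 left on waitlist)
#>   planned overtime 0 min, underutilization 0 min, objective 0 min (optimal)

realized <- realize(planned, waitlist, cfg)
realized
#> <realized_schedule> MSSP (compress policy): 114 cases performed
#>   realized overtime 620 min, underutilization 290 min, objective 1530 min
```

Reading this: the predictor landed 79.4% of bookings within 30 minutes of
the truth; on those bookings the optimizer packed 114 of 500 waitlisted
cases into a *perfect* plan (every room-day filled to exactly 540 regular
minutes). Replayed against the true durations, prediction errors turned
that perfect plan into 620 minutes of overtime and 290 idle minutes across
the week's 25 room-days — the gap between planned and realized performance
that the package exists to measure. `run_simulation()` repeats this paired
experiment (two-stage vs mean vs hindsight arms on identical weekly
waitlists) over many weeks and reports mean (SD) metrics, win rates, paired
Wilcoxon signed-rank tests and formulation comparisons.

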