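Package: orsched
Title: Predict-Then-Optimize Elective Operating Room Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage predict-then-optimize scheduling of elective surgery
    (total knee and hip arthroplasty) over a block-discretized week. Provides
    three integer-programming formulations of weekly operating-room
    scheduling -- Any (unrestricted surgeon-room mixing), Split (at most two
    surgeons per room-day, one room per surgeon-day) and MSSP (one surgeon
    per room-day, solved as per-surgeon multiple subset sum problems) --
    together with pluggable duration-of-surgery predictors, a realization
    engine that replays planned schedules against true durations including
    cross-room surgeon cascades, and a paired multi-week simulation with
    overtime, underutilization and win-rate statistics. Synthetic lognormal
    waitlists emulate the role of the surgical registry data the approach
    was developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
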