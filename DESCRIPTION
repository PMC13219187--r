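Package: cfrdispatch
Title: Volunteer Dispatch Policies for Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating smartphone-based dispatch of
    community first responders (CFRs) to out-of-hospital cardiac arrest.
    Provides an exact finite-horizon Markov decision process for phased
    volunteer alerting solved by backward induction, a discrete-event
    simulator of the CFR response process (triage delay, alert view delays,
    travel, ambulance arrival), a seeded synthetic incident generator based
    on a spatial Poisson volunteer field, and a classification-tree strategy
    that selects the best dispatch policy per incident by simulation-based
    labeling. The objective trades patient survival, from a logistic model in
    time-to-CPR and time-to-EMS, against volunteer fatigue measured as
    redundant arrivals. Includes Pareto-frontier and trade-off analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
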