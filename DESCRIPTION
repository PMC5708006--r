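Package: paam
Title: Patient Access Area Model for Small-Area Healthcare Supply-Demand Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic small-area simulator of the balance between inpatient
    healthcare demand and hospital bed supply. Mesh-level populations are
    projected forward with a per-person Monte Carlo cohort-component method,
    converted to daily inpatient counts via sex- and age-specific inpatient
    care rates, restricted to travel-time-bounded Patient Access Areas on a
    road network, and allocated to capacity-limited hospital beds. Reports
    per-mesh over-demand (patients with no reachable bed) and per-hospital
    over-supply (vacant beds) under policy scenarios, with a synthetic-region
    generator so the whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
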