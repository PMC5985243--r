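Package: avcea
Title: Cost-Effectiveness Microsimulation of Autonomous Vehicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A Markov-chain Monte Carlo microsimulation comparing autonomous
    vehicles (AVs) and human-piloted vehicles (HPVs), privately owned and as
    taxis, as a health-economic decision model. Simulates paired driver
    cohorts over annual timesteps with crash, injury, mortality and
    vehicle-expiration events; accrues discounted costs and quality-adjusted
    life years (QALYs); and computes incremental cost-effectiveness ratios
    (ICERs), dominance verdicts, one-way sensitivity analyses and
    probabilistic sensitivity analyses with triangular parameter
    distributions. Ships a synthetic driver-age distribution, period
    mortality lifetable and vehicle survival lifetable so the full pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
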