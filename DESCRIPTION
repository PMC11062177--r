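Package: exploregen
Title: Exploration-Exploitation Trade-Offs in Intergenerational Technology Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how much time a rational agent should invest
    in exploring a culturally transmitted technology versus exploiting it,
    within a two-generation transmission chain. Provides an analytic solver
    for the continuous two-player time-allocation game (optimal switching
    times under 'repaid' and 'unrepaid' incentive schemes), a win-stay/
    lose-shift agent-based simulation of the virtual-arrowhead task on a
    unimodal quadratic fitness landscape that locates the optimal number of
    exploration trials per condition, and a behavioural-statistics pipeline
    (Welch t-tests with Bonferroni correction, Cohen's d, efficiency
    trajectories, payment computation) together with a synthetic-participant
    generator so the pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
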