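Package: physarum
Title: Multi-Agent Simulation of Physarum Plasmodium Network Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of the Physarum polycephalum plasmodium as a
    population of chemoattractant-depositing particles on a 2D diffusive
    lattice, with declarative stimulation protocols over a 5x5 node array:
    attractant addition and removal, relative and repellent negative stimuli,
    and repeated stimulation. Provides node-occupancy time-series measurement
    (space-time matrices, baseline-activity traces, per-node variance), an
    exact two-tailed Mann-Whitney U test by full enumeration, and a synthetic
    generator plus analyzer for electrode-pair resistance experiments under
    high-amplitude/high-frequency and low-amplitude/low-frequency stimulation
    regimes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
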