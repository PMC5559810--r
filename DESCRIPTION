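Package: treeconsensus
Title: Objective Consensus Analysis of Clinical Decision Trees
Version: 0.1.0
Authors@R:
    person("Pattern", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for "patterns of algorithms" analyses of clinical treatment
    strategies. Participant treatment algorithms are represented as decision
    trees over categorical criteria, validated for gaps, conflicts and
    overlaps, harmonized across heterogeneous criterion encodings (e.g.
    performance-status cut-offs mapped to fit/unfit), expanded over every
    permutation of decision criteria, and aggregated into per-scenario
    consensus statistics (mode recommendation, strict majority, congruency
    rate). A compact consensus decision tree is induced from the modal
    recommendations, and criteria-usage and treatment-portfolio profiles are
    reported. Includes a reproducible synthetic expert-ensemble generator and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
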