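Package: probescore
Title: Objective Fitness Scoring of Chemical Probes from Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Probe", "Score Maintainers", email = "maintainers@probescore.invalid",
           role = c("aut", "cre"))
Description: Aggregates raw compound-target bioactivity measurements into
    median pActivities with censored-value handling, computes six
    fitness-factor scores (potency, selectivity, cell activity,
    structure-activity relationships, inactive analogs, PAINS liability)
    and a weighted Global Score for every compound-reference-target pair,
    and derives target-level summaries: quality icons, minimum-standard
    probe counts, Information Richness and liganded-proteome statistics.
    Includes a deterministic synthetic bioactivity landscape generator so
    the full pipeline is testable without external databases, and a
    command-line interface for scoring, probe cards and simulation.
    Structure-level operations (level-1 scaffold-tree assignment and PAINS
    substructure alerts) are delegated to the RDKit toolkit through a
    bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package, discoverable as
    'python' on the PATH (configurable via option 'probescore.python').
Config/testthat/edition: 3
RoxygenNote: 7.3.3
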