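Package: beprofiler
Title: Base-Editing Outcome Profiling for Sequence-Context Substrate Libraries
Version: 0.1.0
Authors@R: person("BE", "Profiler Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling cytosine and adenine base-editor outcomes on
    combinatorial sequence-context substrate libraries. Enumerates UMI-barcoded
    amplicon libraries that vary the bases flanking a target C or A across
    protospacer positions, simulates amplicon sequencing reads with known
    ground-truth editing rates, demultiplexes and quantifies per-position
    substitution frequencies, and computes editing-window, C-versus-A
    selectivity (geometric mean with limit-of-detection censoring) and
    Kullback-Leibler context-preference logo statistics. Also provides
    directed-evolution bookkeeping: plaque-assay titers, phage fold
    enrichment, and cumulative fold-dilution accounting for serial and
    continuous selection campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
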