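Package: vSDC
Title: Standard-Deviation Consensus Methods for Structure-Based Virtual
    Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines the ranked score lists produced by several docking
    programs into a single short list of candidate molecules for
    experimental testing. Implements the standard-deviation consensus
    (SDC) at a fixed cutoff of x standard deviations above the library
    mean, the variable standard-deviation consensus (vSDC) in which the
    cutoff is lowered from 3.5 in steps of 0.001 until a user-fixed
    number of consensus molecules is reached, and the united subset
    consensus (USC) that pools each program's top-ranked molecules.
    Provides the early-recognition metrics used to evaluate such
    selections (yield of actives, docking enrichment, corrected yield,
    fraction of targets with hits, net balance of targets), Spearman
    rank-correlation diagnostics between programs, enrichment curves,
    an active-dilution benchmark harness over many targets, and a
    synthetic score-table generator so the whole pipeline can be
    exercised without docking output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, optparse
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'scoreTable.R'
    'synthetic.R'
    'consensus.R'
    'metrics.R'
    'benchmark.R'
    'cli.R'
    'vSDC-package.R'
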