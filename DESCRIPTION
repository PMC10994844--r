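Package: bactatlas
Title: Bacterial Transcriptome Atlas Annotation and Conditional Expression Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates bacterial transcriptomes from dRNA-seq evidence and
    integrates the annotation with conditional expression and mutant-fitness
    data. Detects and classifies transcription start sites from Terminator
    Exonuclease (TEX) treated versus untreated coverage, predicts intrinsic
    terminators by hairpin and coverage-drop heuristics, assembles operons and
    sub-operons, discovers and curates small regulatory RNAs with a folding
    stability proxy, scans genomes for invertible repeats under
    length-dependent mismatch budgets, provides counts-per-million filtering,
    a negative-binomial differential-expression test, preranked gene-set
    enrichment, co-expression summaries, transposon-fitness phenotype
    categorization, and a one-site binding-curve fit. A synthetic-data
    generator plants every feature class with known truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
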