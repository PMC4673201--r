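Package: itdseq
Title: Alignment-Free FLT3-ITD Detection and MRD Quantification from
    Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects FLT3 internal tandem duplications (ITDs) directly in
    merged paired-end amplicon reads, without alignment: paired-end reads
    are merged by overlap consensus, tandem repeats are found inside
    individual reads, duplications are anchored to the amplicon reference
    and pooled into clone definitions, and ITD-breakpoint versus wild-type
    breakpoint reads are counted per sample. Minimal residual disease (MRD)
    positivity is called with a one-sided Fisher exact test against in-run
    control samples; per-sample sensitivity (the minimal detectable ITD/WT
    ratio at the observed depth) and longitudinal decimal log reductions
    are reported. A paired-end amplicon read simulator with truth tables
    supports validation, dilution experiments and clonal-tracking
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
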