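Package: adarsense
Title: Design and Verification of ADAR-Recruiting Hairpin RNA Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing programmable ADAR-recruiting hairpin RNA
    sensors that report RNA, single-nucleotide variants, or ligands through
    A-to-I editing of an in-frame UAG stop codon. Builds hairpin substrates,
    inert sensors, RNA/SNV/aptamer sensors and full BFP-P2A-sensor-GFP
    reporter cassettes under the hairpin geometry rules; verifies designs by
    constrained Nussinov secondary-structure folding, intended-pair checks
    and reading-frame audits; scans target transcripts for candidate sensor
    sites with bystander-adenosine auditing; quantifies A-to-G editing from
    amplicon sequencing reads (quality trimming, pair merging, fit alignment,
    pileup); computes GFP/BFP fold activation from flow-cytometry event
    tables; and ships seeded simulators for transcripts, edited amplicon
    reads and flow events so the whole chain is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
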