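Package: editscreen
Title: Rigorous mRNA Editing Detection from Matched DNA and RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects candidate mRNA editing events as differences between
    matched genomic DNA and mRNA short-read alignments of the same
    individual, then removes sequencing and mapping artifacts with five
    dedicated filters (read-extremity bias, strand bias, splice-junction
    proximity, homopolymer and simple-sequence-repeat context, and
    multimapping control via a consensus search in raw DNA reads).
    Surviving events are merged across biological replicates, classified
    into the twelve substitution classes with canonical (ADAR/APOBEC)
    collapsing, localized against gene models, and quantified as editing
    levels with pooled-variance group comparisons. A seeded simulator
    generates matched DNA/RNA read sets with planted edits, genomic SNPs
    and every artifact class so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
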