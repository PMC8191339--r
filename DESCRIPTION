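Package: isoscope
Title: Isoform Classification and Differential Isoform Usage for Long-Read cDNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of full-length cDNA isoform models against a
    reference annotation: SQANTI-style categorization of isoforms
    (full-splice match, incomplete-splice match, novel in catalog, novel not
    in catalog, intergenic), transcript end-distance analysis, full-CDS
    containment by three-frame translation, discovery and short-read
    validation of unannotated exons, and per-gene chi-squared contingency
    testing of differential isoform usage between stimulation conditions with
    Bonferroni correction. Includes a synthetic-data generator that emits
    genomes, annotations, isoform models of every category, Dirichlet-
    multinomial usage counts with injected usage switches, and splice-junction
    files, together with a ground-truth manifest, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
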