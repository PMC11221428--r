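Package: panTE
Title: Pan-Genome Transposable Element Variant Calling and Population Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a non-redundant pan-genome map of transposable element (TE)
    presence/absence variants from whole-genome alignments in PAF format,
    genotypes the map across accessions, polarizes loci against outgroup
    genomes into derived TE variations (dTEs), and runs the downstream
    population-genetic and association analyses: carrier-frequency spectra,
    Hudson FST selection scans with permutation enrichment against SNP-based
    selective windows, TE-family enrichment, presence/absence diversity,
    linkage disequilibrium with nearby small variants, genic-context
    assignment, population structure, LTR insertion-age dating, cis-eQTL
    scans and trait GWAS. A synthetic rice-like population simulator with a
    known truth set makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
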