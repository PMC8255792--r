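Package: cnbprepeat
Title: Decomposition, Classification and Diagnostic Simulation of the CNBP (DM2) Repeat Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complex (TG)v(TCTG)w(CCTG)x(NCTG)y(CCTG)z tandem
    repeat in intron 1 of the CNBP gene, the locus expanded in myotonic
    dystrophy type 2 (DM2). Provides a motif grammar to render, locate and
    decompose repeat tracts from DNA sequence, structural and diagnostic
    classification of alleles (normal, gray-zone premutation, pathogenic
    expansion), a simulator of the SR-PCR / TP-PCR / LR-PCR molecular
    diagnostic workflow, cohort-level summaries (registry tallies, allele
    frequency spectrum, heterozygosity, interruption-motif frequencies),
    and seeded generators for sequenced-allele catalogues, allele length
    spectra and diploid cohorts with expansions and somatic mosaicism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
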