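Package: mlstpop
Title: Multilocus Sequence Typing and Population Structure for Bacterial Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for six-locus multilocus sequence typing (MLST) of
    Bifidobacterium longum and similar bacterial collections: deterministic
    allele and sequence-type (ST) assignment, goeBURST clonal-complex and
    BURST-group inference with the canonical founder tie-break chain, minimum
    spanning trees over allelic profiles, per-locus diversity and selection
    statistics (segregating sites, nucleotide diversity, Tajima's D,
    Nei-Gojobori dN/dS), a PHI-style permutation test and clustered-SNP scan
    for recombination with a simple r/m summary, and neighbor-joining
    phylogenies from Kimura two-parameter distances.  A seeded multi-lineage
    isolate simulator with implanted recombinant fragments provides ground
    truth for calibration and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
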