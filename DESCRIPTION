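Package: crisprikit
Title: CRISPRi Guide Design for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design toolkit for bacterial CRISPR interference (CRISPRi)
    experiments with S. pyogenes dCas9. Enumerates candidate single-guide
    RNAs within annotated coding sequences and small RNAs under the
    non-template-strand / NGG-PAM convention, screens candidates for
    genome-wide uniqueness of the PAM-proximal seed, ranks guides by
    proximity to the 5' end of the target, predicts the polar knockdown
    footprint of a guide within its operon, runs PAM-constraint
    targetability censuses over feature sets, designs synonymous escape
    alleles that abolish guide pairing while preserving the encoded
    protein, and generates guide-swap cloning oligonucleotides. Includes a
    deterministic synthetic genome/annotation generator with exact truth
    tables for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
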