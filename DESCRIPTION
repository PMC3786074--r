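Package: trnfscan
Title: Annotation of Tandem trnF(GAA) Pseudogene Arrays in Plastid trnL-F Spacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and annotates tandemly repeated pseudogene copies of the
    plastid phenylalanine transfer-RNA gene (trnF-GAA) in trnL-F intergenic
    spacer sequences. Provides a structural reference model of the trnF gene
    decomposed into cloverleaf domains, an edit-distance anchor scanner with
    bordering-motif (ATT(G)n) segmentation, sigma70-type promoter and simple
    tandem-repeat detection, copy-number counting, Fitch and Dollo parsimony
    mapping of pseudogene presence onto rooted phylogenies to delimit
    single-origin clades, a planted-truth spacer simulator, and GFF3/TSV/
    newick input and output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
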