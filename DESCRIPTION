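Package: foundersplice
Title: Splice-Variant Consequence Analysis and Founder-Haplotype IBD Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the two bespoke computations of a recessive-disease
    gene-panel study. First, a transcript-level splice-consequence engine:
    exon skipping, partial intron retention and ectopic-acceptor exon
    truncation are applied to a transcript model to derive the altered mRNA,
    reading-frame class, premature termination codon, protein-level HGVS
    notation, a nonsense-mediated decay prediction, and the RT-PCR amplicon
    sizes expected on a gel. Second, a windowed identity-by-descent scan:
    pairwise PI_HAT is estimated by method of moments from biallelic SNP
    genotypes in expanding windows around an index variant and compared with
    randomized control intervals to call a shared founder haplotype. Also
    includes the study-style variant prioritization filter with trio-based
    phasing, and seeded synthetic-data generators producing transcripts with
    planted splice events, SNP cohorts with planted founder segments, and
    annotated variant tables with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
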