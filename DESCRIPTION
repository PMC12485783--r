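Package: allergomics
Title: Multi-Omics Pipeline for Allergen-Exposure Lung Tumor Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of the computational pipeline used in
    multi-omics studies of aeroallergen-driven lung tumorigenesis in mouse
    models: ensemble somatic-variant consensus filtering with blacklist,
    germline, shared-mutation and clustered-mutation filters; mutational
    spectrum construction in the SBS96, DBS78 and ID83 channel catalogs with
    per-megabase burden and cosine-similarity comparison; expression
    normalization (median-of-ratios size factors, TPM, TMM log2 CPM), a
    negative-binomial Wald differential-expression test and Benjamini-Hochberg
    FDR; gene-set mean z-score module scoring and marker-signature immune
    scoring; differential promoter-methylation calling on beta values; and the
    methylation-expression integration that identifies epigenetically
    controlled genes via quadrant classification and an inverse Pearson
    correlation filter. A synthetic multi-omics generator with exported truth
    tables makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    optparse
Config/testthat/edition: 3
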