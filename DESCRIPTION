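Package: GVPprofiler
Title: Genetically Variant Peptide Profiling for Protein-Based Human
    Identification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers individualizing missense SNPs from hair-shaft proteomic
    data via genetically variant peptides (GVPs). Builds major/minor GVP
    catalogs from protein sequences and missense SNP annotations by in-silico
    tryptic digestion, matches per-sample peptide observations to the catalog
    to call SNP detection states, selects robust SNP panels by exome-proteome
    consistency criteria, and scores GVP profiles with observed phenotype
    frequencies to obtain pairwise profile differences and random match
    probabilities. Includes label-free precursor-area protein quantification
    and a synthetic-data generator emulating the multi-body-location single
    hair study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Proteomics, MassSpectrometry, SNP, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
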