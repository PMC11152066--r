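Package: GenoConcord
Title: Cross-Platform Genotype Concordance and SNP-Array Ascertainment Diagnostics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating and combining genotypes obtained for the
    same populations on a SNP genotyping array and by low-coverage whole-genome
    sequencing. Provides replicate reproducibility and cross-platform
    concordance statistics (per-individual and per-site, with allele and
    genotype-class sensitivities and a logistic model of concordance against
    sequencing depth or site quality), ascertainment-bias diagnostics (observed
    heterozygosity under site subsampling, folded site-frequency spectra),
    Weir-Cockerham F_ST with pairwise matrices and cross-platform regression,
    PCA on dosage matrices, an auditable array+WGS merging pipeline with allele
    harmonization and LD pruning, and a ground-truthed two-platform genotype
    simulator built on the Balding-Nichols model with a depth-limited
    likelihood-based genotype caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: Genetics, SNP, PopulationGenetics, QualityControl, Sequencing,
    Microarray
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
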