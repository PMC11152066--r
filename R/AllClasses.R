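#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData rowData<- colData assayNames
NULL

MISSING_CODE <- NA_integer_
VALID_BASES <- c("A", "C", "G", "T")

#' GenotypeMatrix: biallelic SNV dosages for a set of samples
#'
#' The central container of the package. Variants are rows (a
#' [GenomicRanges::GRanges] with single-base `ref` and `alt` alleles in its
#' metadata columns), samples are columns, and the `"calls"` assay holds the
#' alternate-allele dosage coded 0/1/2 with `NA` for missing calls. An
#' optional `"depth"` assay carries per-call read depth and an optional
#' per-variant `qual` column in `rowData` carries Phred-scaled site quality.
#' Because the class extends `RangedSummarizedExperiment`, all the usual
#' subsetting, `metadata()`, `colData()` and `rowData()` machinery applies.
#'
#' @slot .. see `RangedSummarizedExperiment`; the class adds validity rules
#'   only (dosage codes, allele alphabet, unique variant keys).
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"calls" %in% assayNames(object))
        return("assay 'calls' is required")
    cl <- assay(object, "calls")
    vals <- cl[!is.na(cl)]
    if (length(vals) && !all(vals %in% 0:2))
        msg <- c(msg, "dosage calls must be 0, 1, 2 or NA")
    rr <- rowRanges(object)
    mc <- mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc))) {
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
    } else {
        ref <- as.character(mc$ref); alt <- as.character(mc$alt)
        if (!all(ref %in% VALID_BASES) || !all(alt %in% VALID_BASES))
            msg <- c(msg, "ref/alt must be single bases A/C/G/T")
        if (any(ref == alt))
            msg <- c(msg, "ref and alt alleles must differ")
        if (anyDuplicated(paste(seqnames(rr), start(rr), ref, alt)))
            msg <- c(msg, "variant keys (chrom,pos,ref,alt) must be unique")
    }
    if ("depth" %in% assayNames(object)) {
        dp <- assay(object, "depth")
        if (any(dp[!is.na(dp)] < 0))
            msg <- c(msg, "depths must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' PairedCalls: allele-harmonized call pairs across two platforms
#'
#' Holds, for a list of individuals genotyped on two platforms ("A" = array,
#' "B" = sequencing by convention), the dosage calls of both platforms over
#' the shared variants that survived allele harmonization, plus optional
#' per-call depth and per-variant quality for platform B. Built by
#' [pairPlatforms()].
#'
#' @slot variants GRanges of shared harmonized variants (ref/alt mcols).
#' @slot pairs DataFrame with columns `sampleA`, `sampleB` and an
#'   `individual` label.
#' @slot callsA,callsB integer matrices, variants x individuals.
#' @slot depthB optional depth matrix for platform B (or NULL).
#' @slot qualB optional per-variant quality for platform B (or NULL).
#' @slot report list of harmonization counters (kept, swapped, flipped,
#'   flippedSwapped, palindromicDropped, thirdAlleleDropped).
#' @export
setClass("PairedCalls", representation(
    variants = "GRanges",
    pairs = "DataFrame",
    callsA = "matrix",
    callsB = "matrix",
    depthB = "ANY",
    qualB = "ANY",
    report = "list"))

setValidity("PairedCalls", function(object) {
    msg <- character()
    if (!identical(dim(object@callsA), dim(object@callsB)))
        msg <- c(msg, "callsA and callsB must have identical dimensions")
    if (nrow(object@callsA) != length(object@variants))
        msg <- c(msg, "call matrices must have one row per variant")
    if (ncol(object@callsA) != nrow(object@pairs))
        msg <- c(msg, "call matrices must have one column per individual pair")
    if (!is.null(object@depthB) && !identical(dim(object@depthB), dim(object@callsB)))
        msg <- c(msg, "depthB must match callsB dimensions")
    if (!is.null(object@qualB) && length(object@qualB) != length(object@variants))
        msg <- c(msg, "qualB must have one value per variant")
    if (length(msg)) msg else TRUE
})

#' FoldedSFS: folded site-frequency spectrum
#'
#' Counts of sites by minor-allele count among `nChromosomes = 2k` chromosomes
#' of `k` diploids, bins 0..k. Built by [foldedSFS()] from complete-case
#' sites only; the monomorphic bin 0 is kept for accounting but excluded from
#' normalized comparisons (see [sfsDistance()]).
#'
#' @slot counts named integer vector, bins "0".."k".
#' @slot nChromosomes integer, 2k.
#' @slot nSites integer, number of sites tallied (equals `sum(counts)`).
#' @export
setClass("FoldedSFS", representation(
    counts = "numeric", nChromosomes = "integer", nSites = "integer"))

setValidity("FoldedSFS", function(object) {
    k <- object@nChromosomes %/% 2L
    msg <- character()
    if (length(object@counts) != k + 1L)
        msg <- c(msg, "counts must have one bin per minor-allele count 0..k")
    if (!isTRUE(all.equal(sum(object@counts), as.numeric(object@nSites))))
        msg <- c(msg, "counts must sum to nSites")
    if (length(msg)) msg else TRUE
})

#' FstResult: Weir-Cockerham variance components and weighted estimate
#'
#' Per-locus among-population (`a`), among-individual-within-population (`b`)
#' and within-individual (`c`) variance components with the per-locus ratio
#' `theta = a/(a+b+c)`, plus the multi-locus weighted estimate
#' `thetaWeighted = sum(a)/sum(a+b+c)` (ratio of sums, never a mean of
#' ratios). Small negative per-locus values are retained: the estimator is
#' unbiased, not constrained to [0,1].
#'
#' @slot perLocus DataFrame with columns a, b, c, theta (one row per used locus).
#' @slot thetaWeighted numeric, the weighted multi-locus estimate.
#' @slot meanOfRatios numeric, the (reported-but-not-headline) mean of
#'   per-locus ratios.
#' @slot nLociUsed integer.
#' @slot nSkipped named integer counts of excluded loci (missing-population,
#'   monomorphic).
#' @slot populations character, labels used.
#' @export
setClass("FstResult", representation(
    perLocus = "DataFrame",
    thetaWeighted = "numeric",
    meanOfRatios = "numeric",
    nLociUsed = "integer",
    nSkipped = "integer",
    populations = "character"))

#' SimTruth: ground truth of a simulated two-platform study
#'
#' Ancestral and per-population allele frequencies drawn under the
#' Balding-Nichols model, true diploid genotypes, and the sample sheet of the
#' simulated study. Platform-specific observed matrices are generated from it
#' by [genotypeChip()] and [genotypeWgs()].
#'
#' @slot config the [simConfig()] list that produced it.
#' @slot variants GRanges of candidate loci (ref/alt mcols).
#' @slot ancestralFreq numeric ancestral alt-allele frequency per locus.
#' @slot popFreq matrix loci x populations of population frequencies.
#' @slot genotypes integer matrix loci x samples of true dosages.
#' @slot sampleData DataFrame: sample, population, group (native/invasive).
#' @slot panel logical per-locus panel membership (all FALSE before
#'   [ascertainPanel()] is applied).
#' @export
setClass("SimTruth", representation(
    config = "list",
    variants = "GRanges",
    ancestralFreq = "numeric",
    popFreq = "matrix",
    genotypes = "matrix",
    sampleData = "DataFrame",
    panel = "logical"))
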