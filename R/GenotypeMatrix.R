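#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of alt-allele dosages (0/1/2, `NA` = missing),
#'   variants in rows and samples in columns. Column names are the sample
#'   ids; row names are set to the `chrom:pos:ref:alt` key.
#' @param variants either a `GRanges` with metadata columns `ref` and `alt`,
#'   or a data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param depth optional matrix of per-call read depths, same shape as
#'   `calls`.
#' @param qual optional numeric vector of per-variant Phred-scaled site
#'   qualities.
#' @param sampleData optional `DataFrame`/data.frame of per-sample metadata
#'   (one row per column of `calls`).
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   variants = data.frame(chrom = "1", pos = c(100, 200),
#'                         ref = c("A", "C"), alt = c("G", "T")))
#' calls(gm)
#' @export
GenotypeMatrix <- function(calls, variants, depth = NULL, qual = NULL,
                           sampleData = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.data.frame(variants)) {
        gr <- GRanges(as.character(variants$chrom),
                      IRanges(as.integer(variants$pos), width = 1L))
        mcols(gr)$ref <- toupper(as.character(variants$ref))
        mcols(gr)$alt <- toupper(as.character(variants$alt))
    } else {
        gr <- variants
    }
    ids <- variantIdsFromRanges(gr)
    rownames(calls) <- ids
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("S", seq_len(ncol(calls)))
    assays <- list(calls = calls)
    if (!is.null(depth)) {
        depth <- as.matrix(depth)
        storage.mode(depth) <- "integer"
        dimnames(depth) <- dimnames(calls)
        assays$depth <- depth
    }
    if (is.null(sampleData)) {
        cd <- DataFrame(row.names = colnames(calls))
    } else {
        cd <- DataFrame(sampleData, row.names = colnames(calls))
    }
    names(gr) <- ids
    se <- SummarizedExperiment(assays = assays, rowRanges = gr, colData = cd)
    if (!is.null(qual))
        rowData(se)$qual <- as.numeric(qual)
    new("GenotypeMatrix", se)
}

variantIdsFromRanges <- function(gr) {
    paste(as.character(seqnames(gr)), start(gr),
          as.character(mcols(gr)$ref), as.character(mcols(gr)$alt), sep = ":")
}

#' Accessors for GenotypeMatrix
#'
#' `calls()` returns the dosage matrix (variants x samples, `NA` missing);
#' `callDepth()` the per-call depth matrix or NULL; `siteQual()` the
#' per-variant quality vector or NULL; `variantIds()` the
#' `chrom:pos:ref:alt` keys; `sampleIds()` the sample names;
#' `genotypingRate()` the fraction of non-missing calls.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return see the description of each accessor.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
calls <- function(gm) assay(gm, "calls")

#' @rdname genotype-accessors
#' @export
callDepth <- function(gm) {
    if ("depth" %in% assayNames(gm)) assay(gm, "depth") else NULL
}

#' @rdname genotype-accessors
#' @export
siteQual <- function(gm) {
    rd <- rowData(gm)
    if ("qual" %in% colnames(rd)) rd$qual else NULL
}

#' @rdname genotype-accessors
#' @export
variantIds <- function(gm) variantIdsFromRanges(rowRanges(gm))

#' @rdname genotype-accessors
#' @export
sampleIds <- function(gm) colnames(gm)

#' @rdname genotype-accessors
#' @export
genotypingRate <- function(gm) {
    cl <- calls(gm)
    if (!length(cl)) return(NA_real_)
    mean(!is.na(cl))
}

setMethod("show", "GenotypeMatrix", function(object) {
    cl <- calls(object)
    cat("GenotypeMatrix:", nrow(cl), "variants x", ncol(cl), "samples\n")
    cat("  genotyping rate:",
        if (length(cl)) sprintf("%.4f", mean(!is.na(cl))) else "NA", "\n")
    cat("  depth assay:", "depth" %in% assayNames(object),
        "| site qual:", "qual" %in% colnames(rowData(object)), "\n")
    if (length(metadata(object)))
        cat("  metadata:", paste(names(metadata(object)), collapse = ", "), "\n")
})

# per-variant minor allele frequency from called genotypes only
mafPerVariant <- function(cl) {
    n <- rowSums(!is.na(cl))
    p <- rowSums(cl, na.rm = TRUE) / (2 * n)
    p[n == 0] <- NA_real_
    pmin(p, 1 - p)
}

#' Filter a genotype matrix on missingness and allele frequency
#'
#' Applies, in a fixed order mirroring the standard PLINK semantics:
#' (1) drop samples whose missing rate exceeds `mind`; (2) drop variants
#' whose missing rate, recomputed over the remaining samples, exceeds
#' `geno`; (3) drop variants whose minor-allele frequency (computed from
#' called genotypes only) is below `maf`. The stage-by-stage removal counts
#' are recorded in `metadata(result)$filterReport`. Emptying the matrix is a
#' warning, not an error.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param mind maximum per-sample missing rate (default 1 = no filter).
#' @param geno maximum per-variant missing rate (default 1).
#' @param maf minimum minor-allele frequency (default 0).
#' @return the filtered [GenotypeMatrix-class]; see
#'   `metadata(result)$filterReport` for counts removed at each stage.
#' @export
filterGenotypes <- function(gm, mind = 1, geno = 1, maf = 0) {
    stopifnot(mind >= 0, mind <= 1, geno >= 0, geno <= 1, maf >= 0, maf <= 1)
    cl <- calls(gm)
    sampMiss <- colMeans(is.na(cl))
    keepS <- sampMiss <= mind
    out <- gm[, keepS]
    cl <- calls(out)
    varMiss <- rowMeans(is.na(cl))
    if (!ncol(cl)) varMiss <- rep(1, nrow(cl))
    keepGeno <- varMiss <= geno
    out <- out[keepGeno, ]
    m <- mafPerVariant(calls(out))
    keepMaf <- if (maf > 0) !is.na(m) & m >= maf else rep(TRUE, length(m))
    out <- out[keepMaf, ]
    report <- list(
        samplesIn = ncol(gm), variantsIn = nrow(gm),
        samplesRemovedMind = sum(!keepS),
        variantsRemovedGeno = sum(!keepGeno),
        variantsRemovedMaf = sum(keepGeno) - sum(keepMaf),
        samplesOut = ncol(out), variantsOut = nrow(out),
        order = c("mind", "geno", "maf"),
        thresholds = c(mind = mind, geno = geno, maf = maf))
    if (!ncol(out) || !nrow(out))
        warning("filterGenotypes removed all ",
                if (!ncol(out)) "samples" else "variants")
    metadata(out)$filterReport <- report
    out
}

#' Uniform random subsample of variants
#'
#' Draws `n` variants uniformly at random without replacement, reproducibly
#' under a fixed seed. Used to compare diversity statistics across panels of
#' matched size.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param n number of variants to keep (must not exceed `nrow(gm)`).
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the seed is recorded in `metadata()$subsampleSeed`.
#' @return a [GenotypeMatrix-class] with `n` variants (original order kept).
#' @export
subsampleSites <- function(gm, n, seed = NULL) {
    if (n > nrow(gm))
        stop("requested ", n, " sites but only ", nrow(gm), " available")
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    idx <- sort(sample.int(nrow(gm), n))
    out <- gm[idx, ]
    metadata(out)$subsampleSeed <- seed
    out
}
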