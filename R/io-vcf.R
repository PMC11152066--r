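#' Read genotypes from a VCF file
#'
#' Imports GT (plus per-call DP and site QUAL when present) from a VCF into a
#' [GenotypeMatrix-class]. Only biallelic single-nucleotide records are
#' loaded; multiallelic and non-SNV records are skipped and counted in
#' `metadata()$skipReport`. Half-calls (e.g. `0/.`) are treated as missing.
#' Parsing is delegated to \pkg{vcfR}.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @return a [GenotypeMatrix-class]; `metadata()$skipReport` holds counts of
#'   skipped records (`multiallelic`, `nonSNV`).
#' @export
readVcfGenotypes <- function(path) {
    if (!file.exists(path)) stop("cannot read VCF: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    if (nrow(fix) == 0) {
        samples <- colnames(v@gt)
        samples <- samples[samples != "FORMAT"]
        gm <- GenotypeMatrix(
            matrix(integer(), 0, length(samples),
                   dimnames = list(NULL, samples)),
            variants = data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
        metadata(gm)$skipReport <- c(multiallelic = 0L, nonSNV = 0L)
        return(gm)
    }
    if (is.null(v@gt) || !ncol(v@gt))
        stop("VCF has no genotype (FORMAT/GT) columns: ", path)
    alt <- fix[, "ALT"]
    ref <- fix[, "REF"]
    multi <- grepl(",", alt, fixed = TRUE)
    snv <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
        toupper(ref) %in% VALID_BASES & toupper(alt) %in% VALID_BASES
    keep <- which(snv)
    key <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
                 toupper(ref[keep]), toupper(alt[keep]), sep = ":")
    if (anyDuplicated(key))
        stop("duplicate variant key in VCF: ", key[duplicated(key)][1])
    fmt <- v@gt[, "FORMAT"]
    if (!all(grepl("(^|:)GT(:|$)", fmt)))
        stop("record without GT in FORMAT field: ", path)
    gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
    dose <- dosageFromGt(gt)
    hasDP <- any(grepl("(^|:)DP(:|$)", fmt))
    depth <- NULL
    if (hasDP) {
        depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
        depth <- depth[keep, , drop = FALSE]
    }
    qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
    variants <- data.frame(chrom = fix[keep, "CHROM"],
                           pos = as.integer(fix[keep, "POS"]),
                           ref = toupper(ref[keep]), alt = toupper(alt[keep]))
    colnames(dose) <- colnames(gt)
    gm <- GenotypeMatrix(dose, variants, depth = depth,
                         qual = if (all(is.na(qual))) NULL else qual)
    metadata(gm)$skipReport <- c(multiallelic = sum(multi),
                                 nonSNV = sum(!multi & !snv))
    gm
}

# "0/1", "0|1", "./.", half-calls "0/." -> dosage or NA
dosageFromGt <- function(gt) {
    d <- matrix(NA_integer_, nrow(gt), ncol(gt))
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
    d[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
    d
}

#' Write a GenotypeMatrix to VCF
#'
#' Emits a position-sorted VCF v4.2 with GT (and DP when a depth assay is
#' present, QUAL when site qualities are present). Missing calls are written
#' as `./.`. Chromosomes are ordered by first appearance in the matrix
#' unless `chromOrder` supplies an explicit order; chromosomes absent from a
#' supplied order are an error.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path; a `.gz` suffix selects gzip output.
#' @param chromOrder optional character vector fixing the chromosome order.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(gm, path, chromOrder = NULL) {
    cl <- calls(gm)
    chrom <- as.character(seqnames(rowRanges(gm)))
    if (is.null(chromOrder)) chromOrder <- unique(chrom)
    if (!all(chrom %in% chromOrder))
        stop("chromosome(s) not in declared order: ",
             paste(setdiff(chrom, chromOrder), collapse = ", "))
    ord <- order(match(chrom, chromOrder), start(rowRanges(gm)))
    gm <- gm[ord, ]
    cl <- calls(gm)
    dp <- callDepth(gm)
    qual <- siteQual(gm)
    rr <- rowRanges(gm)
    meta <- c("##fileformat=VCFv4.2",
              "##source=GenoConcord",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    if (!is.null(dp))
        meta <- c(meta, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                               "Description=\"Read depth\">"))
    gtStr <- matrix(c("0/0", "0/1", "1/1")[cl + 1L], nrow(cl), ncol(cl))
    gtStr[is.na(cl)] <- "./."
    if (!is.null(dp)) {
        dpStr <- ifelse(is.na(dp), ".", as.character(dp))
        gtStr <- matrix(paste(gtStr, dpStr, sep = ":"), nrow(cl), ncol(cl))
        fmt <- "GT:DP"
    } else fmt <- "GT"
    fix <- cbind(CHROM = as.character(seqnames(rr)),
                 POS = as.character(start(rr)),
                 ID = rep(".", nrow(cl)),
                 REF = as.character(mcols(rr)$ref),
                 ALT = as.character(mcols(rr)$alt),
                 QUAL = if (is.null(qual)) rep(".", nrow(cl)) else
                     ifelse(is.na(qual), ".", sprintf("%.10g", qual)),
                 FILTER = rep(".", nrow(cl)),
                 INFO = rep(".", nrow(cl)))
    gt <- cbind(FORMAT = rep(fmt, nrow(cl)), gtStr)
    colnames(gt) <- c("FORMAT", colnames(cl))
    if (grepl("\\.gz$", path)) {
        v <- new("vcfR", meta = meta, fix = fix, gt = gt)
        vcfR::write.vcf(v, file = path)
    } else {
        header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", colnames(cl)),
                        collapse = "\t")
        body <- if (nrow(cl)) apply(cbind(fix, gt), 1, paste, collapse = "\t")
                else character()
        writeLines(c(meta, header, body), path)
    }
    invisible(path)
}
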