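#' Read a PLINK bed/bim/fam triplet
#'
#' Decodes the variant-major PLINK 1 binary layout (magic bytes `0x6C 0x1B`,
#' mode byte `0x01`; two bits per call packed four calls per byte) into a
#' [GenotypeMatrix-class]. The `.bim` A1 allele is taken as the alternate
#' allele, so the 2-bit codes map to dosage as: `00` (hom A1) -> 2, `10`
#' (het) -> 1, `11` (hom A2) -> 0, `01` -> missing. Sample and variant order
#' follow the `.fam` and `.bim` files.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return a [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
    for (f in c(bed, bim, fam))
        if (!file.exists(f)) stop("missing PLINK file: ", f)
    bimTab <- utils::read.table(bim, header = FALSE,
                                colClasses = c("character", "character",
                                               "numeric", "integer",
                                               "character", "character"))
    colnames(bimTab) <- c("chrom", "id", "cm", "pos", "a1", "a2")
    famTab <- utils::read.table(fam, header = FALSE,
                                colClasses = "character")
    samples <- famTab[[2]]
    n <- length(samples)
    m <- nrow(bimTab)
    raw <- readBin(bed, "raw", n = file.size(bed))
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("not a PLINK bed file (bad magic bytes): ", bed)
    if (raw[3] != as.raw(0x01))
        stop("sample-major PLINK bed files are not supported: ", bed)
    bytesPerVariant <- ceiling(n / 4)
    body <- raw[-(1:3)]
    if (length(body) != bytesPerVariant * m)
        stop("PLINK bed length mismatch: expected ", bytesPerVariant * m,
             " data bytes, found ", length(body))
    codes <- decodeBedBytes(body, n, m)
    # code -> alt(A1) dosage: 0b00 hom A1 = 2, 0b10 het = 1, 0b11 hom A2 = 0
    lut <- c(2L, NA_integer_, 1L, 0L)
    dose <- matrix(lut[codes + 1L], nrow = m, ncol = n)
    colnames(dose) <- samples
    GenotypeMatrix(dose, variants = data.frame(
        chrom = bimTab$chrom, pos = bimTab$pos,
        ref = toupper(bimTab$a2), alt = toupper(bimTab$a1)))
}

# unpack 2-bit codes; returns m x n matrix of codes 0..3 flattened row-major
decodeBedBytes <- function(body, n, m) {
    ints <- as.integer(body)
    bpv <- ceiling(n / 4)
    # all four 2-bit fields of every byte, sample index = 4*(byte-1)+field
    codes <- rbind(bitwAnd(ints, 3L),
                   bitwAnd(bitwShiftR(ints, 2L), 3L),
                   bitwAnd(bitwShiftR(ints, 4L), 3L),
                   bitwAnd(bitwShiftR(ints, 6L), 3L))
    dim(codes) <- c(4L * bpv, m)
    t(codes[seq_len(n), , drop = FALSE])
}

#' Write a GenotypeMatrix as PLINK bed/bim/fam
#'
#' Inverse of [readPlink()]: emits the variant-major PLINK 1 binary layout
#' with the alternate allele written as A1.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(gm, prefix) {
    cl <- calls(gm)
    rr <- rowRanges(gm)
    n <- ncol(cl)
    m <- nrow(cl)
    # dosage -> code: 2 -> 0b00, 1 -> 0b10, 0 -> 0b11, NA -> 0b01
    code <- matrix(3L, m, n)
    code[cl == 2] <- 0L
    code[cl == 1] <- 2L
    code[is.na(cl)] <- 1L
    bpv <- ceiling(n / 4)
    padded <- matrix(0L, m, 4 * bpv)
    padded[, seq_len(n)] <- code
    bytes <- matrix(0L, m, bpv)  # low bits = first sample of the byte
    for (j in 0:3)
        bytes <- bytes + bitwShiftL(padded[, seq(j + 1, 4 * bpv, by = 4),
                                           drop = FALSE], 2L * j)
    writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(as.vector(t(bytes)))),
             paste0(prefix, ".bed"))
    bimTab <- data.frame(chrom = as.character(seqnames(rr)),
                         id = variantIds(gm), cm = 0,
                         pos = start(rr),
                         a1 = as.character(mcols(rr)$alt),
                         a2 = as.character(mcols(rr)$ref))
    utils::write.table(bimTab, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    famTab <- data.frame(fid = colnames(cl), iid = colnames(cl),
                         pat = 0, mat = 0, sex = 0, pheno = -9)
    utils::write.table(famTab, paste0(prefix, ".fam"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(prefix)
}

#' Read a probe coordinate map from BED
#'
#' Loads single-base probe intervals from a BED file (0-based, half-open;
#' probe id in the name column) into a `GRanges` of 1-based positions
#' (`pos = BED start + 1`). Intervals of length other than one and duplicate
#' probe ids are errors.
#'
#' @param path path to a BED file.
#' @return a `GRanges`, one range per probe, names = probe ids.
#' @export
readProbeMap <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!length(gr)) return(gr)
    if (any(GenomicRanges::width(gr) != 1L)) {
        bad <- gr$name[GenomicRanges::width(gr) != 1L][1]
        stop("probe interval is not a single base: ", bad)
    }
    if (is.null(gr$name) || anyDuplicated(gr$name))
        stop("duplicate (or missing) probe id in BED: ",
             gr$name[duplicated(gr$name)][1])
    names(gr) <- gr$name
    gr
}

#' Read a sample metadata table
#'
#' Tab-separated table with header
#' `sample_id, population, region, platform, replicate`. `sample_id` must be
#' unique within each (platform, replicate) combination.
#'
#' @param path path to a TSV file.
#' @return a `DataFrame`.
#' @export
readSampleMeta <- function(path) {
    tab <- utils::read.delim(path, colClasses = "character")
    need <- c("sample_id", "population", "region", "platform", "replicate")
    if (!all(need %in% colnames(tab)))
        stop("sample metadata must have columns: ",
             paste(need, collapse = ", "))
    tab$replicate <- as.integer(tab$replicate)
    if (anyDuplicated(tab[, c("sample_id", "platform", "replicate")]))
        stop("sample_id must be unique per (platform, replicate)")
    DataFrame(tab)
}
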