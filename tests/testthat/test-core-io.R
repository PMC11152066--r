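test_that("VCF genotypes decode to dosages with missing and half-calls", {
    f <- writeToyVcf(tempfile(fileext = ".vcf"), c(
        "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
        "1\t200\t.\tC\tT\t.\t.\t.\tGT\t1/1\t./.",
        "1\t300\t.\tG\tA\t.\t.\t.\tGT\t0/.\t1|1"))
    gm <- readVcfGenotypes(f)
    expect_identical(unname(calls(gm)),
                     matrix(c(0L, 2L, NA, 1L, NA, 2L), 3, 2))
    expect_identical(variantIds(gm), c("1:100:A:G", "1:200:C:T", "1:300:G:A"))
})

test_that("multiallelic and non-SNV records are skipped and counted", {
    f <- writeToyVcf(tempfile(fileext = ".vcf"), c(
        "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
        "1\t200\t.\tA\tC,T\t.\t.\t.\tGT\t0/1\t0/2",
        "1\t300\t.\tAT\tA\t.\t.\t.\tGT\t0/1\t0/0"))
    gm <- readVcfGenotypes(f)
    expect_equal(nrow(gm), 1)
    expect_equal(metadata(gm)$skipReport[["multiallelic"]], 1)
    expect_equal(metadata(gm)$skipReport[["nonSNV"]], 1)
})

test_that("duplicate variant keys in a VCF are an explicit error", {
    f <- writeToyVcf(tempfile(fileext = ".vcf"), c(
        "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
        "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/1"))
    expect_error(readVcfGenotypes(f), "1:100:A:G")
})

test_that("VCF write/read round trip preserves calls, depth and qual", {
    set.seed(11)
    cl <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 20, 3)
    dp <- matrix(rpois(60, 6), 20, 3)
    gm <- makeGM(cl, depth = dp, qual = round(runif(20, 10, 200), 3),
                 samples = c("a", "b", "c"))
    f <- tempfile(fileext = ".vcf")
    writeVcfGenotypes(gm, f)
    gm2 <- readVcfGenotypes(f)
    expect_identical(calls(gm2), calls(gm))
    expect_equal(unname(callDepth(gm2)), unname(callDepth(gm)))
    expect_equal(siteQual(gm2), siteQual(gm))
    # missing calls appear as ./.
    expect_true(any(grepl("\\./\\.", readLines(f))))
})

test_that("an empty matrix writes a header-only VCF that reads back empty", {
    gm <- makeGM(matrix(integer(), 0, 2, dimnames = list(NULL, c("x", "y"))))
    f <- tempfile(fileext = ".vcf")
    writeVcfGenotypes(gm, f)
    lns <- readLines(f)
    expect_true(all(grepl("^#", lns)))
    gm2 <- readVcfGenotypes(f)
    expect_equal(nrow(gm2), 0)
    expect_equal(sampleIds(gm2), c("x", "y"))
})

test_that("writeVcfGenotypes rejects chromosomes outside a declared order", {
    gm <- makeGM(matrix(c(0L, 1L), 2, 1), chrom = c("1", "7"))
    expect_error(writeVcfGenotypes(gm, tempfile(), chromOrder = "1"), "7")
})

test_that("PLINK bed round trip is lossless and variant-major", {
    set.seed(7)
    for (n in c(3, 4, 9)) {
        cl <- matrix(sample(c(0:2, NA), 11 * n, replace = TRUE), 11, n)
        gm <- makeGM(cl, samples = paste0("s", seq_len(n)))
        p <- tempfile()
        writePlink(gm, p)
        back <- readPlink(p)
        expect_identical(unname(calls(back)), unname(cl))
        expect_identical(sampleIds(back), paste0("s", seq_len(n)))
    }
})

test_that("a hand-packed bed byte decodes to the hand-computed dosages", {
    # 3 samples, 1 variant; 2-bit fields (low to high): 00 hom A1, 10 het,
    # 01 missing -> byte 0b00011000 = 0x18; A1 = alt so dosages 2, 1, NA
    p <- tempfile()
    writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x18)), paste0(p, ".bed"))
    writeLines("1\tv1\t0\t500\tG\tA", paste0(p, ".bim"))
    writeLines(c("f1\ts1\t0\t0\t0\t-9", "f2\ts2\t0\t0\t0\t-9",
                 "f3\ts3\t0\t0\t0\t-9"), paste0(p, ".fam"))
    gm <- readPlink(p)
    expect_identical(unname(calls(gm)), matrix(c(2L, 1L, NA), 1, 3))
    expect_identical(variantIds(gm), "1:500:A:G")
})

test_that("bad magic bytes and sample-major mode are format errors", {
    p <- tempfile()
    writeLines("1\tv1\t0\t500\tG\tA", paste0(p, ".bim"))
    writeLines("f1\ts1\t0\t0\t0\t-9", paste0(p, ".fam"))
    writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x18)), paste0(p, ".bed"))
    expect_error(readPlink(p), "magic")
    writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x18)), paste0(p, ".bed"))
    expect_error(readPlink(p), "sample-major")
    writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x18, 0x18)), paste0(p, ".bed"))
    expect_error(readPlink(p), "length mismatch")
})

test_that("probe maps convert BED 0-based starts to 1-based positions", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t99\t100\tprobeA", "chr2\t4\t5\tprobeB"), f)
    pm <- readProbeMap(f)
    expect_equal(unname(GenomicRanges::start(pm["probeA"])), 100)
    expect_equal(unname(GenomicRanges::start(pm["probeB"])), 5)

    writeLines("chr1\t99\t101\tprobeC", f)
    expect_error(readProbeMap(f), "probeC")
    writeLines(c("chr1\t99\t100\tprobeA", "chr1\t5\t6\tprobeA"), f)
    expect_error(readProbeMap(f), "probeA")
})

test_that("filters apply in sample-then-variant order with a stage report", {
    # 10 samples x 20 variants; sample 'bad' misses 2/20 = 10% of calls,
    # variant v1 misses in {bad, s2}: 20% before the sample filter, 1/9 =
    # 11.1% after, so v1 survives geno = 0.15 only because 'bad' went first
    cl <- matrix(0L, 20, 10)
    cl[, 2] <- rep(c(0L, 1L), 10)  # keep MAF healthy
    cl[, 3] <- rep(c(1L, 0L), 10)
    cl[1, 1] <- NA; cl[2, 1] <- NA          # 'bad' sample, 10% missing
    cl[1, 2] <- NA                           # v1 also missing in s2
    gm <- makeGM(cl, samples = c("bad", paste0("s", 2:10)))
    out <- filterGenotypes(gm, mind = 0.05, geno = 0.15, maf = 0)
    rep <- metadata(out)$filterReport
    expect_equal(rep$samplesRemovedMind, 1)
    expect_equal(rep$variantsRemovedGeno, 0)
    expect_true("1:100:A:G" %in% variantIds(out))
})

test_that("geno and maf thresholds drop the documented cases", {
    cl <- matrix(rep(c(0L, 1L), 50), 10, 10, byrow = TRUE)
    cl[1, 1:3] <- NA                     # 30% missing at variant 1
    cl[2, ] <- c(rep(0L, 9), 1L)           # alt frequency 0.05
    cl[3, ] <- 0L; cl[3, 1] <- 1L          # alt frequency 0.05
    gm <- makeGM(cl)
    out <- filterGenotypes(gm, mind = 1, geno = 0.2, maf = 0.06)
    rep <- metadata(out)$filterReport
    expect_equal(rep$variantsRemovedGeno, 1)
    expect_equal(rep$variantsRemovedMaf, 2)
    expect_equal(nrow(out), 7)
})

test_that("filtering is idempotent and never raises a missing rate", {
    set.seed(42)
    cl <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                        prob = c(.3, .3, .3, .1)), 30, 10)
    gm <- makeGM(cl)
    once <- filterGenotypes(gm, mind = 0.2, geno = 0.2, maf = 0.05)
    twice <- filterGenotypes(once, mind = 0.2, geno = 0.2, maf = 0.05)
    expect_identical(calls(twice), calls(once))
    expect_true(all(rowMeans(is.na(calls(once))) <= 0.2))
    expect_true(all(colMeans(is.na(calls(once))) <= 0.2))
})

test_that("emptying the matrix is a warning, not an error", {
    gm <- makeGM(matrix(c(NA, NA, NA, 1L), 2, 2))
    expect_warning(out <- filterGenotypes(gm, mind = 0.4), "samples")
    expect_equal(ncol(out), 0)
})

test_that("sample metadata tables enforce per-platform uniqueness", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tpopulation\tregion\tplatform\treplicate",
                 "a\tp1\tnative\tchip\t1", "a\tp1\tnative\tchip\t2",
                 "a\tp1\tnative\twgs\t0"), f)
    meta <- readSampleMeta(f)
    expect_equal(nrow(meta), 3)
    writeLines(c("sample_id\tpopulation\tregion\tplatform\treplicate",
                 "a\tp1\tnative\tchip\t1", "a\tp1\tnative\tchip\t1"), f)
    expect_error(readSampleMeta(f), "unique")
})
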