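# toy-object builders and independent brute-force oracles used across tests

makeGM <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                   depth = NULL, qual = NULL, samples = NULL) {
    calls <- as.matrix(calls)
    m <- nrow(calls)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(pos)) pos <- seq_len(m) * 100L
    if (is.null(ref)) ref <- rep(c("A", "C"), length.out = m)
    if (is.null(alt)) alt <- rep(c("G", "T"), length.out = m)
    if (!is.null(samples)) colnames(calls) <- samples
    GenotypeMatrix(calls, data.frame(chrom = chrom, pos = pos,
                                     ref = ref, alt = alt),
                   depth = depth, qual = qual)
}

# PairedCalls straight from matrices (bypasses harmonization)
makePC <- function(callsA, callsB, depthB = NULL, qualB = NULL) {
    callsA <- as.matrix(callsA); callsB <- as.matrix(callsB)
    storage.mode(callsA) <- "integer"
    storage.mode(callsB) <- "integer"
    m <- nrow(callsA)
    gr <- GenomicRanges::GRanges(rep("1", m),
                                 IRanges::IRanges(seq_len(m) * 100L, width = 1))
    S4Vectors::mcols(gr)$ref <- rep("A", m)
    S4Vectors::mcols(gr)$alt <- rep("G", m)
    names(gr) <- paste("1", seq_len(m) * 100L, "A", "G", sep = ":")
    ind <- colnames(callsA)
    if (is.null(ind)) ind <- paste0("ind", seq_len(ncol(callsA)))
    colnames(callsA) <- colnames(callsB) <- ind
    rownames(callsA) <- rownames(callsB) <- names(gr)
    if (!is.null(depthB)) {
        depthB <- as.matrix(depthB)
        dimnames(depthB) <- dimnames(callsB)
    }
    new("PairedCalls", variants = gr,
        pairs = S4Vectors::DataFrame(sampleA = ind, sampleB = ind,
                                     individual = ind),
        callsA = callsA, callsB = callsB, depthB = depthB, qualB = qualB,
        report = list())
}

# cell-by-cell concordance recount, written independently of the package
bruteConcordance <- function(A, B) {
    out <- data.frame(individual = colnames(A), nCommon = 0, nConcordant = 0,
                      nDiscordant = 0, nMissingA = 0, nMissingB = 0,
                      nConcordantHom = 0, nConcordantHet = 0)
    for (j in seq_len(ncol(A))) for (i in seq_len(nrow(A))) {
        a <- A[i, j]; b <- B[i, j]
        if (is.na(a) && !is.na(b)) out$nMissingA[j] <- out$nMissingA[j] + 1
        if (!is.na(a) && is.na(b)) out$nMissingB[j] <- out$nMissingB[j] + 1
        if (is.na(a) || is.na(b)) next
        out$nCommon[j] <- out$nCommon[j] + 1
        if (a == b) {
            out$nConcordant[j] <- out$nConcordant[j] + 1
            if (a == 1) out$nConcordantHet[j] <- out$nConcordantHet[j] + 1
            else out$nConcordantHom[j] <- out$nConcordantHom[j] + 1
        } else out$nDiscordant[j] <- out$nDiscordant[j] + 1
    }
    out
}

# scalar, locus-by-locus evaluation of the Weir & Cockerham (1984) diploid
# variance components; intentionally naive and loop-based
bruteWcFst <- function(cl, pops) {
    labs <- unique(pops)
    r <- length(labs)
    comps <- matrix(NA_real_, nrow(cl), 3)
    for (l in seq_len(nrow(cl))) {
        n <- p <- h <- numeric(r)
        for (g in seq_len(r)) {
            x <- cl[l, pops == labs[g]]
            x <- x[!is.na(x)]
            n[g] <- length(x)
            if (n[g] == 0) next
            p[g] <- sum(x) / (2 * n[g])
            h[g] <- mean(x == 1)
        }
        if (any(n == 0)) next
        nbar <- mean(n)
        nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
        pbar <- sum(n * p) / sum(n)
        if (pbar <= 0 || pbar >= 1) next
        s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(n * h) / sum(n)
        a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                        (2 * nbar - 1) / (4 * nbar) * hbar)
        comps[l, ] <- c(a, b, hbar / 2)
    }
    used <- !is.na(comps[, 1])
    list(components = comps[used, , drop = FALSE],
         theta = sum(comps[used, 1]) / sum(comps[used, ]))
}

# the greedy pairwise pruner evaluated naively over one whole window
brutePairwisePrune <- function(cl, pos, r2Max) {
    keep <- seq_len(nrow(cl))
    repeat {
        if (length(keep) < 2) break
        best <- c(0, 0, -1)
        for (ii in seq_along(keep)[-1]) for (jj in seq_len(ii - 1)) {
            a <- cl[keep[ii], ]; b <- cl[keep[jj], ]
            ok <- !is.na(a) & !is.na(b)
            r <- suppressWarnings(stats::cor(a[ok], b[ok]))
            r2 <- if (is.finite(r)) r^2 else 0
            if (r2 > best[3]) best <- c(keep[jj], keep[ii], r2)
        }
        if (best[3] <= r2Max) break
        i <- best[1]; j <- best[2]
        mi <- mean(is.na(cl[i, ])); mj <- mean(is.na(cl[j, ]))
        drop <- if (mi > mj) i else if (mj > mi) j else
            if (pos[i] >= pos[j]) i else j
        keep <- setdiff(keep, drop)
    }
    keep
}

# write a small VCF from raw field strings
writeToyVcf <- function(path, records,
                        samples = c("S1", "S2"),
                        format = "GT") {
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(header, records), path)
    path
}
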