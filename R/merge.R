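#' Pairwise-r2 LD pruning
#'
#' Sliding window of `windowSnps` variants advancing by `step` over each
#' position-sorted chromosome. Within a window, while any variant pair has
#' squared genotype correlation above `r2Max`, the member of the
#' strongest-correlated offending pair with the greater missing rate is
#' removed (tie: the later position). Entirely deterministic.
#'
#' @param gm a [GenotypeMatrix-class] with variants position-sorted within
#'   each chromosome.
#' @param windowSnps window size in variants (default 50).
#' @param step window advance in variants (default 10).
#' @param r2Max maximum tolerated pairwise r-squared (default 0.3).
#' @return character vector of kept variant keys.
#' @export
ldPrunePairwise <- function(gm, windowSnps = 50, step = 10, r2Max = 0.3) {
    checkSorted(gm)
    cl <- calls(gm)
    ids <- variantIds(gm)
    chrom <- as.character(seqnames(rowRanges(gm)))
    removed <- logical(nrow(cl))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        n <- length(idx)
        starts <- seq(1L, max(1L, n), by = step)
        for (s in starts) {
            win <- idx[s:min(s + windowSnps - 1L, n)]
            repeat {
                act <- win[!removed[win]]
                if (length(act) < 2) break
                R2 <- pairwiseR2(cl[act, , drop = FALSE])
                R2[upper.tri(R2, diag = TRUE)] <- 0
                if (max(R2) <= r2Max) break
                hit <- which(R2 == max(R2), arr.ind = TRUE)[1, ]
                removed[dropChoice(act[hit[1]], act[hit[2]], cl,
                                   start(rowRanges(gm)))] <- TRUE
            }
        }
    }
    ids[!removed]
}

# r2 between variant rows (pairwise-complete); zero-variance rows -> 0
pairwiseR2 <- function(rows) {
    suppressWarnings(R <- stats::cor(t(rows), use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    R^2
}

# which of two variants to drop: greater missing rate, tie -> later position
dropChoice <- function(i, j, cl, pos) {
    mi <- mean(is.na(cl[i, ])); mj <- mean(is.na(cl[j, ]))
    if (mi > mj) i
    else if (mj > mi) j
    else if (pos[i] >= pos[j]) i else j
}

#' Variance-inflation-factor LD pruning
#'
#' Windows of `windowKb` kilobases of physical span, advancing by
#' `stepSnps` variants, over each position-sorted chromosome. Within a
#' window the variant with the largest variance-inflation factor (1/(1-R2)
#' from regressing its dosage on the other window members, computed via the
#' ridge-stabilized inverse correlation matrix, epsilon 1e-8) is removed
#' until all VIFs are at most `vifMax`. Ties broken by greater missing rate
#' then later position.
#'
#' @param gm a [GenotypeMatrix-class], position-sorted per chromosome.
#' @param windowKb physical window span in kb (default 75).
#' @param stepSnps window advance in variants (default 50).
#' @param vifMax maximum tolerated VIF (default 2).
#' @return character vector of kept variant keys.
#' @export
ldPruneVif <- function(gm, windowKb = 75, stepSnps = 50, vifMax = 2) {
    checkSorted(gm)
    cl <- calls(gm)
    ids <- variantIds(gm)
    pos <- start(rowRanges(gm))
    chrom <- as.character(seqnames(rowRanges(gm)))
    removed <- logical(nrow(cl))
    span <- windowKb * 1000
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        starts <- seq(1L, length(idx), by = stepSnps)
        for (s in starts) {
            anchor <- pos[idx[s]]
            win <- idx[pos[idx] >= anchor & pos[idx] < anchor + span]
            repeat {
                act <- win[!removed[win]]
                if (length(act) < 2) break
                vif <- windowVif(cl[act, , drop = FALSE])
                if (max(vif) <= vifMax) break
                worst <- act[vif == max(vif)]
                if (length(worst) > 1) {
                    drop <- worst[1]
                    for (w in worst[-1]) drop <- dropChoice(drop, w, cl, pos)
                } else drop <- worst
                removed[drop] <- TRUE
            }
        }
    }
    ids[!removed]
}

# VIFs of variants (rows) within a window via inverse correlation matrix
windowVif <- function(rows) {
    suppressWarnings(R <- stats::cor(t(rows), use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    Ri <- solve(R + diag(1e-8, nrow(R)))
    diag(Ri)
}

checkSorted <- function(gm) {
    pos <- start(rowRanges(gm))
    chrom <- as.character(seqnames(rowRanges(gm)))
    ok <- all(vapply(split(pos, factor(chrom, unique(chrom))),
                     function(p) !is.unsorted(p), logical(1)))
    if (!ok) stop("variants must be position-sorted within chromosomes")
    invisible(TRUE)
}

# canonical orientation: among the four equivalent representations of a
# biallelic site (as given, strand-complemented, ref/alt-exchanged,
# complemented + exchanged) pick the alphabetically smallest (ref, alt);
# ties prefer the representation that keeps dosages. Exchanging ref/alt
# recodes dosages 2 - d. Makes merge output independent of which platform
# is handed in first.
canonicalAlleles <- function(ref, alt) {
    cr <- unname(BASE_COMPLEMENT[ref])
    ca <- unname(BASE_COMPLEMENT[alt])
    n <- length(ref)
    keys <- cbind(paste(ref, alt), paste(cr, ca),   # dosage kept
                  paste(alt, ref), paste(ca, cr))   # dosage recoded
    pick <- max.col(-matrix(match(keys, sort(unique(as.vector(keys)))),
                            n, 4), ties.method = "first")
    outRef <- c(ref, cr, alt, ca)[(pick - 1) * n + seq_len(n)]
    outAlt <- c(alt, ca, ref, cr)[(pick - 1) * n + seq_len(n)]
    list(ref = outRef, alt = outAlt, recode = pick > 2)
}

canonicalizeOrientation <- function(variants, callsList) {
    can <- canonicalAlleles(as.character(mcols(variants)$ref),
                            as.character(mcols(variants)$alt))
    mcols(variants)$ref <- can$ref
    mcols(variants)$alt <- can$alt
    names(variants) <- variantIdsFromRanges(variants)
    callsList <- lapply(callsList, function(m) {
        m[can$recode, ] <- 2L - m[can$recode, , drop = FALSE]
        rownames(m) <- names(variants)
        m
    })
    list(variants = variants, calls = callsList)
}

canonicalKeys <- function(keys) {
    if (!length(keys)) return(character(0))
    parts <- strsplit(keys, ":", fixed = TRUE)
    if (any(lengths(parts) != 4))
        stop("unparseable variant key (expect chrom:pos:ref:alt): ",
             keys[lengths(parts) != 4][1])
    ref <- toupper(vapply(parts, `[`, "", 3))
    alt <- toupper(vapply(parts, `[`, "", 4))
    can <- canonicalAlleles(ref, alt)
    paste(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
          can$ref, can$alt, sep = ":")
}

#' Merge array and sequencing genotype panels
#'
#' The staged merging pipeline: harmonize alleles over the variant
#' intersection (strand flips corrected, swapped ref/alt recoded,
#' palindromic-ambiguous and third-allele sites dropped), canonicalize
#' orientation, intersect with a concordance-validated site list and a
#' Mendelian-inheritance site list, drop variants exceeding a missingness
#' bound over the union of samples, LD prune, and concatenate the samples.
#' Every stage's removal count is logged in `metadata()$mergeReport`, whose
#' counts telescope to the final variant total.
#'
#' @param gmA,gmB [GenotypeMatrix-class] inputs with disjoint sample ids.
#' @param validated optional character vector of `chrom:pos:ref:alt` keys
#'   (sites validated by cross-platform concordance); NULL = no filter.
#' @param mendel optional character vector of keys for Mendelian-validated
#'   sites; NULL = no filter.
#' @param genoMax maximum per-variant missing rate over the merged samples
#'   (default 0.2).
#' @param prune LD-pruning stage: `list(type = "vif", windowKb = 75,
#'   stepSnps = 50, vifMax = 2)` (default), `list(type = "pairwise",
#'   windowSnps, step, r2Max)`, or NULL to skip.
#' @return the merged [GenotypeMatrix-class];
#'   `metadata()$mergeReport` holds the stage counts and the final
#'   genotyping rate.
#' @export
mergeDatasets <- function(gmA, gmB, validated = NULL, mendel = NULL,
                          genoMax = 0.2,
                          prune = list(type = "vif", windowKb = 75,
                                       stepSnps = 50, vifMax = 2)) {
    if (length(intersect(sampleIds(gmA), sampleIds(gmB))))
        stop("sample ids must be disjoint across datasets")
    rrA <- rowRanges(gmA); rrB <- rowRanges(gmB)
    posA <- paste(seqnames(rrA), start(rrA))
    posB <- paste(seqnames(rrB), start(rrB))
    if (anyDuplicated(posA) || anyDuplicated(posB))
        stop("duplicate positions within an input dataset")
    shared <- intersect(posA, posB)
    ia <- match(shared, posA); ib <- match(shared, posB)
    refA <- as.character(mcols(rrA)$ref)[ia]
    altA <- as.character(mcols(rrA)$alt)[ia]
    action <- classifyAlleles(refA, altA,
                              as.character(mcols(rrB)$ref)[ib],
                              as.character(mcols(rrB)$alt)[ib])
    keep <- action %in% c("keep", "swap", "flip", "flipSwap")
    report <- list(shared = length(shared),
                   flipped = sum(action %in% c("flip", "flipSwap")),
                   dosageSwapped = sum(action %in% c("swap", "flipSwap")),
                   palindromicDropped = sum(action == "palindromic"),
                   thirdAlleleDropped = sum(action == "third"))
    ia <- ia[keep]; ib <- ib[keep]
    act <- action[keep]
    callsA <- calls(gmA)[ia, , drop = FALSE]
    callsB <- calls(gmB)[ib, , drop = FALSE]
    recode <- act %in% c("swap", "flipSwap")
    callsB[recode, ] <- 2L - callsB[recode, , drop = FALSE]
    variants <- GenomicRanges::granges(rrA[ia])
    mcols(variants)$ref <- refA[keep]
    mcols(variants)$alt <- altA[keep]
    canon <- canonicalizeOrientation(variants, list(callsA, callsB))
    variants <- canon$variants
    combined <- cbind(canon$calls[[1]], canon$calls[[2]])
    ids <- names(variants)

    applyList <- function(list_, label) {
        if (is.null(list_)) return(rep(TRUE, length(ids)))
        ids %in% canonicalKeys(list_)
    }
    inVal <- applyList(validated)
    report$failedValidated <- sum(!inVal)
    variants <- variants[inVal]; combined <- combined[inVal, , drop = FALSE]
    ids <- ids[inVal]
    inMen <- if (is.null(mendel)) rep(TRUE, length(ids)) else
        ids %in% canonicalKeys(mendel)
    report$failedMendel <- sum(!inMen)
    variants <- variants[inMen]; combined <- combined[inMen, , drop = FALSE]
    ids <- ids[inMen]
    missRate <- rowMeans(is.na(combined))
    okMiss <- missRate <= genoMax
    report$failedMissingness <- sum(!okMiss)
    variants <- variants[okMiss]; combined <- combined[okMiss, , drop = FALSE]
    ids <- ids[okMiss]

    merged <- GenotypeMatrix(combined, variants)
    ord <- order(match(as.character(seqnames(rowRanges(merged))),
                       unique(as.character(seqnames(rowRanges(merged))))),
                 start(rowRanges(merged)))
    merged <- merged[ord, ]
    if (!is.null(prune) && nrow(merged)) {
        keptIds <- switch(prune$type,
            vif = ldPruneVif(merged,
                             windowKb = prune$windowKb %||% 75,
                             stepSnps = prune$stepSnps %||% 50,
                             vifMax = prune$vifMax %||% 2),
            pairwise = ldPrunePairwise(merged,
                                       windowSnps = prune$windowSnps %||% 50,
                                       step = prune$step %||% 10,
                                       r2Max = prune$r2Max %||% 0.3),
            stop("unknown prune type: ", prune$type))
        report$prunedLD <- nrow(merged) - length(keptIds)
        merged <- merged[variantIds(merged) %in% keptIds, ]
    } else {
        report$prunedLD <- 0L
    }
    report$finalVariants <- nrow(merged)
    report$genotypingRate <- genotypingRate(merged)
    if (!nrow(merged)) warning("merge produced an empty variant set")
    metadata(merged)$mergeReport <- report
    merged
}

`%||%` <- function(a, b) if (is.null(a)) b else a
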