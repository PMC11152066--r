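BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

isPalindromic <- function(ref, alt) ref == unname(BASE_COMPLEMENT[alt])

# classify how B's alleles relate to A's at a shared position:
# keep | swap | flip | flipSwap | palindromic | third
classifyAlleles <- function(refA, altA, refB, altB) {
    crB <- unname(BASE_COMPLEMENT[refB])
    caB <- unname(BASE_COMPLEMENT[altB])
    pal <- isPalindromic(refA, altA)
    out <- rep("third", length(refA))
    out[refB == refA & altB == altA] <- "keep"
    swap <- refB == altA & altB == refA & out == "third"
    out[swap & !pal] <- "swap"
    out[swap & pal] <- "palindromic"
    flip <- crB == refA & caB == altA & out == "third"
    out[flip] <- "flip"
    flipSwap <- crB == altA & caB == refA & out == "third"
    out[flipSwap & !pal] <- "flipSwap"
    out[flipSwap & pal] <- "palindromic"
    out
}

#' Pair two platforms over shared, allele-harmonized variants
#'
#' Intersects two genotype matrices on (chrom, pos) and harmonizes alleles
#' before comparison: exact matches are kept; swapped ref/alt sites have
#' platform-B dosages recoded `2 - d`; strand-complement matches are flipped
#' to platform A's orientation; palindromic (A/T, C/G) sites whose
#' resolution would require a strand flip are dropped and counted, as are
#' sites carrying a third allele. Platform B's depth assay and site
#' qualities (when present) travel along.
#'
#' @param gmA,gmB [GenotypeMatrix-class] objects (A = array, B = sequencing
#'   by convention).
#' @param pairs data.frame with columns `sampleA`, `sampleB` (and optional
#'   `individual` label) naming the same individual's sample in each matrix.
#' @return a [PairedCalls-class]; its `report` slot counts harmonization
#'   outcomes.
#' @export
pairPlatforms <- function(gmA, gmB, pairs) {
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("sampleA", "sampleB") %in% colnames(pairs)))
    if (is.null(pairs$individual)) pairs$individual <- pairs$sampleA
    missA <- setdiff(pairs$sampleA, sampleIds(gmA))
    missB <- setdiff(pairs$sampleB, sampleIds(gmB))
    if (length(missA) || length(missB))
        stop("pair samples absent from matrices: ",
             paste(c(missA, missB), collapse = ", "))
    rrA <- rowRanges(gmA); rrB <- rowRanges(gmB)
    posA <- paste(seqnames(rrA), start(rrA))
    posB <- paste(seqnames(rrB), start(rrB))
    if (anyDuplicated(posA))
        stop("duplicate position in platform A: ", posA[duplicated(posA)][1])
    if (anyDuplicated(posB))
        stop("duplicate position in platform B: ", posB[duplicated(posB)][1])
    shared <- intersect(posA, posB)
    if (!length(shared)) stop("no shared positions between platforms")
    ia <- match(shared, posA); ib <- match(shared, posB)
    refA <- as.character(mcols(rrA)$ref)[ia]
    altA <- as.character(mcols(rrA)$alt)[ia]
    refB <- as.character(mcols(rrB)$ref)[ib]
    altB <- as.character(mcols(rrB)$alt)[ib]
    action <- classifyAlleles(refA, altA, refB, altB)
    keep <- action %in% c("keep", "swap", "flip", "flipSwap")
    report <- list(shared = length(shared),
                   kept = sum(action == "keep"),
                   swapped = sum(action == "swap"),
                   flipped = sum(action == "flip"),
                   flippedSwapped = sum(action == "flipSwap"),
                   palindromicDropped = sum(action == "palindromic"),
                   thirdAlleleDropped = sum(action == "third"))
    ia <- ia[keep]; ib <- ib[keep]; action <- action[keep]
    callsA <- calls(gmA)[ia, pairs$sampleA, drop = FALSE]
    callsB <- calls(gmB)[ib, pairs$sampleB, drop = FALSE]
    recode <- action %in% c("swap", "flipSwap")
    callsB[recode, ] <- 2L - callsB[recode, , drop = FALSE]
    dpB <- callDepth(gmB)
    if (!is.null(dpB)) dpB <- dpB[ib, pairs$sampleB, drop = FALSE]
    qB <- siteQual(gmB)
    if (!is.null(qB)) qB <- qB[ib]
    colnames(callsA) <- colnames(callsB) <- pairs$individual
    if (!is.null(dpB)) colnames(dpB) <- pairs$individual
    variants <- GenomicRanges::granges(rrA[ia])
    mcols(variants)$ref <- refA[keep]
    mcols(variants)$alt <- altA[keep]
    names(variants) <- variantIdsFromRanges(variants)
    rownames(callsA) <- rownames(callsB) <- names(variants)
    new("PairedCalls", variants = variants,
        pairs = DataFrame(pairs), callsA = callsA, callsB = callsB,
        depthB = dpB, qualB = qB, report = report)
}

setMethod("show", "PairedCalls", function(object) {
    cat("PairedCalls:", length(object@variants), "harmonized variants x",
        nrow(object@pairs), "individual pairs\n")
    r <- object@report
    cat(sprintf("  shared %d | kept %d | swapped %d | flipped %d+%d | dropped %d pal, %d third\n",
                r$shared, r$kept, r$swapped, r$flipped, r$flippedSwapped,
                r$palindromicDropped, r$thirdAlleleDropped))
})

#' Per-individual cross-platform concordance summary
#'
#' For each individual pair, counts sites called on both platforms
#' (`nCommon`), concordant and discordant calls, per-platform-only missing
#' calls, and the genotype-class breakdown of the concordant calls
#' (homozygous = dosage 0 or 2, heterozygous = 1). The concordance rate is
#' `nConcordant / (nConcordant + nDiscordant)`; individuals with no
#' co-called site get `NA` rates, never 0.
#'
#' @param pc a [PairedCalls-class].
#' @return a `DataFrame`, one row per individual, with columns `individual`,
#'   `nCommon`, `nConcordant`, `nDiscordant`, `nMissingA`, `nMissingB`,
#'   `concordanceRate`, `nConcordantHom`, `nConcordantHet`,
#'   `homFractionOfConcordant`.
#' @export
concordanceSummary <- function(pc) {
    A <- pc@callsA; B <- pc@callsB
    bothCalled <- !is.na(A) & !is.na(B)
    eq <- bothCalled & A == B
    nCommon <- unname(colSums(bothCalled))
    nConc <- unname(colSums(eq))
    nHom <- unname(colSums(eq & A != 1L))
    res <- DataFrame(
        individual = colnames(A),
        nCommon = nCommon,
        nConcordant = nConc,
        nDiscordant = nCommon - nConc,
        nMissingA = unname(colSums(is.na(A) & !is.na(B))),
        nMissingB = unname(colSums(!is.na(A) & is.na(B))),
        concordanceRate = ifelse(nCommon > 0, nConc / nCommon, NA_real_),
        nConcordantHom = nHom,
        nConcordantHet = nConc - nHom,
        homFractionOfConcordant = ifelse(nConc > 0, nHom / nConc, NA_real_),
        row.names = colnames(A))
    res
}

#' Replicate reproducibility of a genotyping platform
#'
#' For individuals genotyped two or more times, computes every unordered
#' replicate-pair concordance and reports the mean count of concordant
#' genotypes, the reproducibility percent (mean concordant count divided by
#' the panel size, the convention used for array replicate runs), the mean
#' pairwise concordance rate over co-called sites, and the number of sites
#' at which all replicates agree. Individuals with a single replicate are
#' excluded with a warning.
#'
#' @param gm a [GenotypeMatrix-class] (already filtered to the working
#'   panel).
#' @param individuals character vector, one entry per sample column, naming
#'   the individual each replicate belongs to.
#' @param panelSize denominator for the percent form; defaults to
#'   `nrow(gm)`.
#' @return a `DataFrame`, one row per individual: `nReplicates`,
#'   `meanConcordant`, `reproducibility` (meanConcordant / panelSize),
#'   `meanConcordanceRate`, `nAllAgree`.
#' @export
replicateReproducibility <- function(gm, individuals, panelSize = nrow(gm)) {
    stopifnot(length(individuals) == ncol(gm))
    cl <- calls(gm)
    byInd <- split(seq_len(ncol(cl)), individuals)
    single <- names(byInd)[lengths(byInd) < 2]
    if (length(single)) {
        warning("excluding individuals with a single replicate: ",
                paste(single, collapse = ", "))
        byInd <- byInd[lengths(byInd) >= 2]
    }
    rows <- lapply(names(byInd), function(ind) {
        idx <- byInd[[ind]]
        prs <- utils::combn(idx, 2)
        concCount <- rateSum <- 0
        for (k in seq_len(ncol(prs))) {
            a <- cl[, prs[1, k]]; b <- cl[, prs[2, k]]
            both <- !is.na(a) & !is.na(b)
            nc <- sum(a[both] == b[both])
            concCount <- concCount + nc
            rateSum <- rateSum + if (sum(both)) nc / sum(both) else NA_real_
        }
        sub <- cl[, idx, drop = FALSE]
        allAgree <- sum(rowSums(is.na(sub)) == 0 &
                        apply(sub, 1, function(x) all(x == x[1])))
        DataFrame(individual = ind, nReplicates = length(idx),
                  meanConcordant = concCount / ncol(prs),
                  reproducibility = concCount / ncol(prs) / panelSize,
                  meanConcordanceRate = rateSum / ncol(prs),
                  nAllAgree = allAgree)
    })
    do.call(rbind, rows)
}

#' Symmetric allele (variant) sensitivity
#'
#' Per individual: the number of concordant sites carrying the alternate
#' allele (dosage >= 1 on both platforms, equal) divided by the number of
#' sites where either platform has a non-missing call carrying the
#' alternate allele. `NA` when no site carries the alternate allele on
#' either platform.
#'
#' @param pc a [PairedCalls-class].
#' @return a `DataFrame` with columns `individual`, `nAltEither`,
#'   `nConcordantAlt`, `sensitivity`.
#' @export
alleleSensitivity <- function(pc) {
    A <- pc@callsA; B <- pc@callsB
    altEither <- (!is.na(A) & A >= 1L) | (!is.na(B) & B >= 1L)
    concAlt <- !is.na(A) & !is.na(B) & A == B & A >= 1L
    den <- unname(colSums(altEither))
    num <- unname(colSums(concAlt))
    DataFrame(individual = colnames(A), nAltEither = den,
              nConcordantAlt = num,
              sensitivity = ifelse(den > 0, num / den, NA_real_),
              row.names = colnames(A))
}

#' Per-platform genotype-class sensitivity
#'
#' For a genotype class (heterozygous, dosage 1; or homozygous-alternate,
#' dosage 2): among sites co-called on both platforms where at least one
#' platform's call is in the class, the sensitivity of a platform is the
#' fraction at which that platform's call is in the class. Quantifies, e.g.,
#' heterozygote undercalling of low-depth sequencing relative to an array.
#'
#' @param pc a [PairedCalls-class].
#' @param genotypeClass `"het"` or `"hom-alt"`.
#' @return a `DataFrame` with columns `individual`, `nEligible`,
#'   `sensitivityA`, `sensitivityB`.
#' @export
classSensitivity <- function(pc, genotypeClass = c("het", "hom-alt")) {
    genotypeClass <- match.arg(genotypeClass)
    target <- if (genotypeClass == "het") 1L else 2L
    A <- pc@callsA; B <- pc@callsB
    both <- !is.na(A) & !is.na(B)
    inClsA <- both & A == target
    inClsB <- both & B == target
    elig <- inClsA | inClsB
    den <- unname(colSums(elig))
    DataFrame(individual = colnames(A), nEligible = den,
              sensitivityA = ifelse(den > 0, unname(colSums(inClsA)) / den,
                                    NA_real_),
              sensitivityB = ifelse(den > 0, unname(colSums(inClsB)) / den,
                                    NA_real_),
              row.names = colnames(A))
}

#' Per-site concordance across individuals
#'
#' For each harmonized variant, the concordance rate over individuals at
#' which both platforms made a call ("when present"). Sites never co-called
#' get an `NA` rate and are excluded from every threshold list.
#'
#' @param pc a [PairedCalls-class].
#' @return a `DataFrame` with columns `variant`, `nBothCalled`,
#'   `nConcordant`, `rate`.
#' @export
siteConcordance <- function(pc) {
    A <- pc@callsA; B <- pc@callsB
    both <- !is.na(A) & !is.na(B)
    eq <- both & A == B
    n <- unname(rowSums(both))
    DataFrame(variant = rownames(A), nBothCalled = n,
              nConcordant = unname(rowSums(eq)),
              rate = ifelse(n > 0, unname(rowSums(eq)) / n, NA_real_),
              row.names = rownames(A))
}

#' Concordance-validated site list
#'
#' Variants whose per-site concordance rate is defined and at least `tau`
#' (inclusive). Lists are nested across thresholds:
#' `validatedSites(sc, 0.9)` is a subset of `validatedSites(sc, 0.75)`.
#'
#' @param sc output of [siteConcordance()].
#' @param tau threshold in (0, 1].
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
validatedSites <- function(sc, tau) {
    stopifnot(tau > 0, tau <= 1)
    as.character(sc$variant[!is.na(sc$rate) & sc$rate >= tau])
}

#' Logistic model of concordance against depth or quality
#'
#' Fits, by maximum likelihood (IRLS, tolerance 1e-8, at most 50
#' iterations), a fixed-effects binomial-logit model of the per-observation
#' concordant/discordant outcome at co-called sites against platform-B
#' sequencing depth or site quality, mean-centered and scaled to unit
#' variance before fitting. Returns the slope per scaled unit and its odds
#' ratio; complete separation and non-convergence are flagged. Optionally
#' fits each individual separately as a stratified alternative to a
#' random-intercept model.
#'
#' @param pc a [PairedCalls-class] carrying depth (and/or quality) for
#'   platform B.
#' @param covariate `"depth"` (per call) or `"qual"` (per site, replicated
#'   across individuals).
#' @param byIndividual if TRUE, also return per-individual slopes.
#' @return a list of class `"concordLogit"`: `intercept`, `slope`,
#'   `oddsRatio`, `se` (named), `scaling` (`mean`, `sd`), `converged`,
#'   `separation`, `pseudoR2` (McFadden), `nObs`, `fitted` (predicted
#'   concordance probabilities), and optionally `perIndividual`.
#' @export
fitConcordanceLogit <- function(pc, covariate = c("depth", "qual"),
                                byIndividual = FALSE) {
    covariate <- match.arg(covariate)
    A <- pc@callsA; B <- pc@callsB
    both <- !is.na(A) & !is.na(B)
    if (covariate == "depth") {
        if (is.null(pc@depthB)) stop("no depth available for platform B")
        x <- pc@depthB[both]
    } else {
        if (is.null(pc@qualB)) stop("no site quality available for platform B")
        x <- matrix(pc@qualB, nrow(B), ncol(B))[both]
    }
    y <- as.integer(A[both] == B[both])
    ind <- matrix(rep(colnames(A), each = nrow(A)), nrow(A), ncol(A))[both]
    ok <- !is.na(x)
    x <- x[ok]; y <- y[ok]; ind <- ind[ok]
    mu <- mean(x); sdev <- stats::sd(x)
    if (!isTRUE(sdev > 0)) stop("covariate has zero variance")
    xs <- (x - mu) / sdev
    fit <- stats::glm(y ~ xs, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 50))
    sep <- any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
    if (sep) warning("possible complete separation in logistic fit")
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    null <- stats::glm(y ~ 1, family = stats::binomial())
    out <- list(intercept = unname(cf[1]), slope = unname(cf[2]),
                oddsRatio = exp(unname(cf[2])),
                se = c(intercept = unname(se[1]), slope = unname(se[2])),
                scaling = c(mean = mu, sd = sdev),
                converged = fit$converged, separation = sep,
                pseudoR2 = 1 - as.numeric(stats::logLik(fit) / stats::logLik(null)),
                nObs = length(y), fitted = unname(fit$fitted.values))
    if (byIndividual) {
        out$perIndividual <- vapply(split(seq_along(y), ind), function(i) {
            if (length(unique(xs[i])) < 2 || length(unique(y[i])) < 2)
                return(NA_real_)
            stats::coef(stats::glm(y[i] ~ xs[i],
                                   family = stats::binomial()))[2]
        }, numeric(1))
    }
    class(out) <- "concordLogit"
    out
}

#' @export
print.concordLogit <- function(x, ...) {
    cat("Binomial-logit concordance model (", x$nObs, " observations)\n",
        sep = "")
    cat(sprintf("  slope %.4f (SE %.4f), OR per scaled unit %.3f\n",
                x$slope, x$se["slope"], x$oddsRatio))
    cat(sprintf("  covariate scaling: mean %.3f, sd %.3f; McFadden R2 %.4f\n",
                x$scaling["mean"], x$scaling["sd"], x$pseudoR2))
    if (!x$converged) cat("  WARNING: did not converge\n")
    if (x$separation) cat("  WARNING: possible complete separation\n")
    invisible(x)
}
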