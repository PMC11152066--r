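#' Weir-Cockerham F_ST
#'
#' Per-locus variance components for r populations of diploids: among
#' populations (`a`), among individuals within populations (`b`) and within
#' individuals (`c`), computed from per-population sample sizes, allele
#' frequencies and observed heterozygote proportions via the standard
#' intermediates (mean sample size, the n_c correction, weighted mean
#' frequency, among-population frequency variance, mean observed
#' heterozygosity). The multi-locus weighted estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)` — never a mean of per-locus ratios, which is
#' reported separately. Negative per-locus values are retained (unbiased
#' estimator). Loci with an entirely-missing population are skipped and
#' counted; loci monomorphic across all populations are excluded from the
#' sums.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops character/factor of population labels, one per sample.
#' @return an [FstResult-class].
#' @export
wcFst <- function(gm, pops) {
    cl <- calls(gm)
    stopifnot(length(pops) == ncol(cl))
    pops <- as.character(pops)
    labs <- unique(pops)
    r <- length(labs)
    if (r < 2) stop("need at least two populations")
    L <- nrow(cl)
    nMat <- pMat <- hMat <- matrix(0, L, r)
    for (g in seq_len(r)) {
        sub <- cl[, pops == labs[g], drop = FALSE]
        nMat[, g] <- rowSums(!is.na(sub))
        pMat[, g] <- rowSums(sub, na.rm = TRUE) / (2 * nMat[, g])
        hMat[, g] <- rowSums(sub == 1L, na.rm = TRUE) / nMat[, g]
    }
    comp <- wcComponents(nMat, pMat, hMat)
    hasAllPops <- rowSums(nMat > 0) == r
    poly <- comp$pbar > 0 & comp$pbar < 1
    use <- hasAllPops & poly & is.finite(comp$a)
    a <- comp$a[use]; b <- comp$b[use]; cc <- comp$c[use]
    denom <- a + b + cc
    theta <- ifelse(denom != 0, a / denom, NA_real_)
    perLocus <- DataFrame(variant = variantIds(gm)[use],
                          a = a, b = b, c = cc, theta = theta)
    new("FstResult",
        perLocus = perLocus,
        thetaWeighted = sum(a) / sum(denom),
        meanOfRatios = mean(theta, na.rm = TRUE),
        nLociUsed = sum(use),
        nSkipped = c(missingPopulation = sum(!hasAllPops),
                     monomorphic = sum(hasAllPops & !poly)),
        populations = labs)
}

# vectorized Weir & Cockerham (1984) a, b, c for diploids over r populations
wcComponents <- function(nMat, pMat, hMat) {
    r <- ncol(nMat)
    nsum <- rowSums(nMat)
    nbar <- nsum / r
    nc <- (nsum - rowSums(nMat^2) / nsum) / (r - 1)
    pbar <- rowSums(nMat * pMat) / nsum
    s2 <- rowSums(nMat * (pMat - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(nMat * hMat) / nsum
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c <- hbar / 2
    list(a = a, b = b, c = c, pbar = pbar)
}

#' @rdname wcFst
#' @param x an [FstResult-class].
#' @export
thetaWeighted <- function(x) x@thetaWeighted

setMethod("show", "FstResult", function(object) {
    cat("Weir-Cockerham F_ST over", object@nLociUsed, "loci,",
        length(object@populations), "populations\n")
    cat(sprintf("  weighted theta = %.5f (mean of ratios %.5f)\n",
                object@thetaWeighted, object@meanOfRatios))
    cat("  skipped:", paste(names(object@nSkipped), object@nSkipped,
                            collapse = ", "), "\n")
})

#' Pairwise weighted F_ST matrix
#'
#' Weighted Weir-Cockerham estimates for every unordered population pair
#' (each from [wcFst()] on the pair's samples). Diagonal is 0; a pair with
#' no shared polymorphic locus gets `NA` with a warning.
#'
#' @inheritParams wcFst
#' @return a symmetric matrix of weighted theta values.
#' @export
pairwiseFst <- function(gm, pops) {
    pops <- as.character(pops)
    labs <- unique(pops)
    if (length(labs) < 2) stop("need at least two populations")
    M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_along(labs)[-1]) for (j in seq_len(i - 1)) {
        sel <- pops %in% labs[c(i, j)]
        res <- wcFst(gm[, sel], pops[sel])
        if (res@nLociUsed == 0) {
            warning("no shared polymorphic loci for pair ",
                    labs[i], "/", labs[j])
            M[i, j] <- M[j, i] <- NA_real_
        } else {
            M[i, j] <- M[j, i] <- res@thetaWeighted
        }
    }
    M
}

#' Cross-platform F_ST regression
#'
#' Ordinary least squares of one platform's pairwise F_ST values on the
#' other's, over the lower-triangle entries of two matrices indexed by the
#' same populations. A slope above 1 indicates the x-axis platform's
#' differentiation is magnified on the y axis.
#'
#' @param x,y symmetric pairwise F_ST matrices over identical population
#'   sets (order may differ).
#' @return a list: `slope`, `intercept`, `r.squared`, `nPairs`, `model`
#'   (the `lm` fit).
#' @export
fstRegression <- function(x, y) {
    if (is.null(rownames(x)) || is.null(rownames(y)) ||
        !setequal(rownames(x), rownames(y)))
        stop("matrices must be over identical population sets")
    y <- y[rownames(x), rownames(x)]
    lt <- lower.tri(x)
    xv <- x[lt]; yv <- y[lt]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 3) stop("fewer than 3 population pairs")
    fit <- stats::lm(yv[ok] ~ xv[ok])
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r.squared = suppressWarnings(summary(fit)$r.squared),
         nPairs = sum(ok), model = fit)
}

#' PCA of a genotype dosage matrix
#'
#' Missing calls are mean-imputed per variant, variants are centered by
#' their mean dosage (optionally scaled by their dosage standard
#' deviation), and sample coordinates are obtained by singular value
#' decomposition. Imputation is used for PCA only — never for F_ST or
#' spectra.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param k number of components (less than `min(samples, variants)`).
#' @param scale. scale variants to unit variance (default FALSE:
#'   center-only).
#' @return a list of class `"genoPca"`: `coords` (samples x k),
#'   `varExplained` (fractions, all components), `k`.
#' @export
pcaGenotypes <- function(gm, k = 2, scale. = FALSE) {
    cl <- calls(gm)
    if (ncol(cl) < 2) stop("need at least two samples")
    if (k >= min(ncol(cl), nrow(cl)))
        stop("k must be smaller than min(samples, variants)")
    rowMean <- rowMeans(cl, na.rm = TRUE)
    X <- cl
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- rowMean[idx[, 1]]
    X <- t(X)  # samples x variants
    keep <- apply(X, 2, stats::sd) > 0
    if (!any(keep)) stop("matrix has zero variance everywhere")
    pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                        scale. = scale.)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                   varExplained = ve, k = k),
              class = "genoPca")
}

#' @export
print.genoPca <- function(x, ...) {
    cat("Genotype PCA:", nrow(x$coords), "samples,", x$k, "components\n")
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$varExplained[seq_len(x$k)]),
              collapse = ", "), "\n")
    invisible(x)
}
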