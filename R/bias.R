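#' Individual observed heterozygosity
#'
#' Per sample: the number of heterozygous calls divided by the number of
#' non-missing calls. Columns of per-sample metadata present in
#' `colData(gm)` are carried through, so group contrasts (e.g. array vs
#' sequencing, native vs invasive) can be made directly.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return a `DataFrame` with columns `sample`, `nHet`, `nCalled`,
#'   `hetRate` (NA for samples with zero calls) plus any `colData` columns.
#' @export
observedHet <- function(gm) {
    cl <- calls(gm)
    nCalled <- unname(colSums(!is.na(cl)))
    nHet <- unname(colSums(cl == 1L, na.rm = TRUE))
    res <- DataFrame(sample = colnames(cl), nHet = nHet, nCalled = nCalled,
                     hetRate = ifelse(nCalled > 0, nHet / nCalled, NA_real_),
                     row.names = colnames(cl))
    cd <- colData(gm)
    if (ncol(cd)) res <- cbind(res, cd)
    res
}

#' Folded site-frequency spectrum
#'
#' Tallies sites by minor-allele count `m = min(ac, 2k - ac)` over `k`
#' selected diploids. Only complete-case sites (no missing call among the
#' selected samples) enter the spectrum; the monomorphic bin 0 is reported
#' for accounting but excluded from normalized comparisons.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param samples optional character vector of sample ids to include
#'   (default: all).
#' @return a [FoldedSFS-class].
#' @export
foldedSFS <- function(gm, samples = NULL) {
    cl <- calls(gm)
    if (!is.null(samples)) {
        bad <- setdiff(samples, colnames(cl))
        if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
        cl <- cl[, samples, drop = FALSE]
    }
    k <- ncol(cl)
    complete <- rowSums(is.na(cl)) == 0
    if (!any(complete)) stop("no complete-case sites for the selected samples")
    ac <- rowSums(cl[complete, , drop = FALSE])
    m <- pmin(ac, 2L * k - ac)
    counts <- as.numeric(tabulate(m + 1L, nbins = k + 1L))
    names(counts) <- as.character(0:k)
    new("FoldedSFS", counts = counts, nChromosomes = 2L * k,
        nSites = as.integer(sum(counts)))
}

#' @rdname FoldedSFS-class
#' @param sfs a [FoldedSFS-class].
#' @export
sfsCounts <- function(sfs) sfs@counts

setMethod("show", "FoldedSFS", function(object) {
    cat("FoldedSFS over", object@nChromosomes, "chromosomes,",
        object@nSites, "sites\n")
    print(object@counts)
})

#' Total-variation distance between folded spectra
#'
#' Normalizes both spectra over their polymorphic bins (minor count >= 1)
#' and returns half the L1 distance, a value in [0, 1]. Spectra must be over
#' the same number of chromosomes.
#'
#' @param a,b [FoldedSFS-class] objects with equal `nChromosomes`.
#' @return numeric in [0, 1].
#' @export
sfsDistance <- function(a, b) {
    if (a@nChromosomes != b@nChromosomes)
        stop("spectra are over different numbers of chromosomes (",
             a@nChromosomes, " vs ", b@nChromosomes, ")")
    pa <- a@counts[-1]; pb <- b@counts[-1]
    if (sum(pa) == 0 || sum(pb) == 0)
        stop("a spectrum has no polymorphic sites")
    sum(abs(pa / sum(pa) - pb / sum(pb))) / 2
}
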