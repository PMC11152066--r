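#' Configuration for the two-platform genotype simulator
#'
#' Defaults emulate a two-range study design: three native-range
#' populations diverged from the ancestral pool at F = 0.05 and three
#' bottlenecked invasive-range populations whose drift compounds the native
#' branch with an additional F = 0.20; an array panel ascertained for
#' intermediate-frequency alleles balanced between the two groups; array
#' genotyping with small per-call error and missingness; and shotgun
#' sequencing at mean depth 6.4x with likelihood-based calls that undercall
#' heterozygotes when depth is low.
#'
#' @param popGroups named character vector mapping population name to
#'   `"native"` or `"invasive"`.
#' @param fNative,fInvasive Balding-Nichols drift parameters of the native
#'   branch and the additional invasive bottleneck branch.
#' @param samplesPerPop study samples per population.
#' @param nLoci candidate loci simulated.
#' @param ancestralRange range of the uniform ancestral-frequency law.
#' @param discoveryPerGroup discovery-sample size per group used for panel
#'   ascertainment (disjoint from study samples).
#' @param ascMafMin minor-allele-frequency threshold a locus must reach in a
#'   group's discovery sample to enter that group's candidate pool.
#' @param balancedPanel take equal numbers of panel SNPs from each group's
#'   pool.
#' @param panelSize number of SNPs on the simulated array.
#' @param chipError per-call probability the array reports a uniformly
#'   chosen different genotype.
#' @param chipMissing per-call array missing probability.
#' @param wgsDepth mean sequencing depth (Poisson lambda); a named numeric
#'   vector gives per-sample depths.
#' @param wgsBaseError per-read base error probability.
#' @param seed master seed; every generator operation derives its stream
#'   from it, so a config is fully reproducible.
#' @return a list of class `"simConfig"`.
#' @export
simConfig <- function(popGroups = c(native1 = "native", native2 = "native",
                                    native3 = "native",
                                    invasive1 = "invasive",
                                    invasive2 = "invasive",
                                    invasive3 = "invasive"),
                      fNative = 0.05, fInvasive = 0.20,
                      samplesPerPop = 5, nLoci = 20000,
                      ancestralRange = c(0.01, 0.99),
                      discoveryPerGroup = 18, ascMafMin = 0.10,
                      balancedPanel = TRUE, panelSize = 8000,
                      chipError = 0.005, chipMissing = 0.01,
                      wgsDepth = 6.4, wgsBaseError = 0.01, seed = 1L) {
    stopifnot(all(popGroups %in% c("native", "invasive")),
              fNative > 0, fNative < 1, fInvasive > 0, fInvasive < 1,
              chipError >= 0, chipError <= 1,
              chipMissing >= 0, chipMissing <= 1,
              all(wgsDepth > 0), wgsBaseError >= 0, wgsBaseError < 0.5)
    structure(as.list(environment()), class = "simConfig")
}

# Balding-Nichols draw of population frequencies around p with drift F
rBaldingNichols <- function(p, F) {
    if (F <= 1e-6) {
        warning("F clamped at 1e-6: returning ancestral frequencies")
        return(p)
    }
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate ground-truth population frequencies and genotypes
#'
#' Ancestral frequencies are uniform on `ancestralRange`; each native
#' population's frequency is a Balding-Nichols draw around the ancestral
#' value at `fNative`; the invasive group first drifts along the native
#' branch and each invasive population then adds bottleneck drift at
#' `fInvasive`. Genotypes are Hardy-Weinberg binomial draws within
#' populations. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return a [SimTruth-class].
#' @export
simulateTruth <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    L <- cfg$nLoci
    pops <- names(cfg$popGroups)
    pAnc <- stats::runif(L, cfg$ancestralRange[1], cfg$ancestralRange[2])
    qInvasiveRoot <- rBaldingNichols(pAnc, cfg$fNative)
    popFreq <- matrix(0, L, length(pops), dimnames = list(NULL, pops))
    for (g in seq_along(pops)) {
        popFreq[, g] <- if (cfg$popGroups[g] == "native")
            rBaldingNichols(pAnc, cfg$fNative)
        else
            rBaldingNichols(qInvasiveRoot, cfg$fInvasive)
    }
    n <- cfg$samplesPerPop
    samples <- as.vector(vapply(pops, function(p) paste0(p, "_s", seq_len(n)),
                                character(n)))
    geno <- matrix(0L, L, length(samples), dimnames = list(NULL, samples))
    for (g in seq_along(pops)) {
        cols <- (g - 1) * n + seq_len(n)
        geno[, cols] <- stats::rbinom(L * n, 2L, rep(popFreq[, g], n))
    }
    variants <- simVariants(L)
    rownames(geno) <- names(variants)
    sd <- DataFrame(sample = samples,
                    population = rep(pops, each = n),
                    group = rep(unname(cfg$popGroups), each = n),
                    row.names = samples)
    new("SimTruth", config = unclass(cfg), variants = variants,
        ancestralFreq = pAnc, popFreq = popFreq, genotypes = geno,
        sampleData = sd, panel = logical(L))
}

# loci spread over 3 chromosomes, 25 kb apart (simulated loci are unlinked,
# so they are spaced past the default LD-pruning window), random alleles
simVariants <- function(L) {
    chrom <- rep(c("1", "2", "3"), length.out = L)
    pos <- integer(L)
    for (ch in c("1", "2", "3")) {
        i <- chrom == ch
        pos[i] <- seq_len(sum(i)) * 25000L
    }
    ref <- sample(VALID_BASES, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(VALID_BASES, b), 1),
                  character(1))
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr)$ref <- ref
    mcols(gr)$alt <- unname(alt)
    names(gr) <- variantIdsFromRanges(gr)
    gr
}

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@variants), "loci,",
        ncol(object@genotypes), "samples in",
        ncol(object@popFreq), "populations\n")
    cat("  panel:", sum(object@panel), "SNPs ascertained\n")
})

#' Ascertain an array SNP panel from discovery samples
#'
#' Draws fresh discovery genotypes (disjoint individuals, spread evenly
#' over each group's populations) and admits a locus to a group's candidate
#' pool when its discovery-sample minor-allele frequency reaches
#' `ascMafMin`. The balanced panel takes equal numbers from each group's
#' pool without replacement; pools too small shrink the panel with a
#' warning. Returns the updated truth with panel flags set.
#'
#' @param truth a [SimTruth-class].
#' @param cfg the [simConfig()] used to build it.
#' @return the [SimTruth-class] with its `panel` slot filled.
#' @export
ascertainPanel <- function(truth, cfg) {
    set.seed(cfg$seed + 1L)
    groups <- c("native", "invasive")
    pool <- list()
    for (grp in groups) {
        popsIn <- names(cfg$popGroups)[cfg$popGroups == grp]
        perPop <- ceiling(cfg$discoveryPerGroup / length(popsIn))
        popIdx <- rep(match(popsIn, colnames(truth@popFreq)),
                      each = perPop)[seq_len(cfg$discoveryPerGroup)]
        L <- length(truth@ancestralFreq)
        disc <- matrix(0L, L, length(popIdx))
        for (k in seq_along(popIdx))
            disc[, k] <- stats::rbinom(L, 2L, truth@popFreq[, popIdx[k]])
        p <- rowMeans(disc) / 2
        maf <- pmin(p, 1 - p)
        pool[[grp]] <- which(maf >= cfg$ascMafMin)
    }
    panel <- logical(length(truth@ancestralFreq))
    if (cfg$balancedPanel) {
        quota <- floor(cfg$panelSize / 2)
        take1 <- samplePool(pool$native, quota)
        take2 <- samplePool(setdiff(pool$invasive, take1), quota)
        chosen <- c(take1, take2)
    } else {
        chosen <- samplePool(union(pool$native, pool$invasive), cfg$panelSize)
    }
    if (length(chosen) < cfg$panelSize)
        warning("candidate pools support only ", length(chosen),
                " of the requested ", cfg$panelSize, " panel SNPs")
    panel[chosen] <- TRUE
    truth@panel <- panel
    truth
}

samplePool <- function(pool, k) {
    if (length(pool) <= k) pool else sample(pool, k)
}

#' Simulate array genotyping of the panel
#'
#' Array calls equal the true genotypes on the panel sites, independently
#' perturbed to a uniformly chosen different genotype with probability
#' `chipError` and set missing with probability `chipMissing`. Distinct
#' `replicate` numbers give independent error realizations of the same
#' truth (for reproducibility studies).
#'
#' @param truth a [SimTruth-class] with an ascertained panel.
#' @param cfg the [simConfig()].
#' @param replicate integer replicate id (enters the derived seed).
#' @return a [GenotypeMatrix-class] over the panel sites;
#'   `colData` carries population/group labels.
#' @export
genotypeChip <- function(truth, cfg, replicate = 1L) {
    if (!any(truth@panel)) stop("truth has no ascertained panel")
    set.seed(cfg$seed + 1000L + as.integer(replicate))
    g <- truth@genotypes[truth@panel, , drop = FALSE]
    n <- length(g)
    err <- stats::runif(n) < cfg$chipError
    if (any(err)) {
        shift <- 1L + (stats::runif(sum(err)) < 0.5)  # +1 or +2 mod 3
        g[err] <- (g[err] + shift) %% 3L
    }
    g[stats::runif(n) < cfg$chipMissing] <- NA_integer_
    GenotypeMatrix(g, truth@variants[truth@panel],
                   sampleData = truth@sampleData)
}

#' Simulate low-coverage sequencing genotype calls
#'
#' Per call: depth is Poisson(`wgsDepth`) (zero depth is a missing call);
#' alternate-read counts are binomial with success probability `e`, 1/2 or
#' `1 - e` by true genotype; the call is the flat-prior maximum-likelihood
#' genotype, with likelihood ties broken toward the homozygote matching the
#' majority read; the per-call quality is the Phred-scaled gap between the
#' best and second-best genotype log-likelihood. Site QUAL is the mean
#' per-call quality; the per-call quality matrix is kept in
#' `metadata()$callQual` and read counts in `metadata()$altReads`.
#'
#' @param truth a [SimTruth-class].
#' @param cfg the [simConfig()].
#' @param sites `"panel"` (default) or `"all"` candidate loci.
#' @return a [GenotypeMatrix-class] with a depth assay and site qualities.
#' @export
genotypeWgs <- function(truth, cfg, sites = c("panel", "all")) {
    sites <- match.arg(sites)
    set.seed(cfg$seed + 2000L)
    idx <- if (sites == "panel") {
        if (!any(truth@panel)) stop("truth has no ascertained panel")
        which(truth@panel)
    } else seq_along(truth@variants)
    g <- truth@genotypes[idx, , drop = FALSE]
    L <- nrow(g); n <- ncol(g)
    lambda <- cfg$wgsDepth
    if (length(lambda) > 1) {
        lambda <- lambda[colnames(g)]
        if (anyNA(lambda)) stop("per-sample wgsDepth must name every sample")
        dp <- matrix(stats::rpois(L * n, rep(lambda, each = L)), L, n)
    } else {
        dp <- matrix(stats::rpois(L * n, lambda), L, n)
    }
    e <- cfg$wgsBaseError
    pAlt <- c(e, 0.5, 1 - e)[g + 1L]
    k <- matrix(stats::rbinom(L * n, dp, pAlt), L, n)
    called <- callFromReads(as.vector(k), as.vector(dp), e)
    cl <- matrix(called$genotype, L, n, dimnames = dimnames(g))
    qual <- matrix(called$qual, L, n, dimnames = dimnames(g))
    cl[dp == 0] <- NA_integer_
    qual[dp == 0] <- NA_real_
    gm <- GenotypeMatrix(cl, truth@variants[idx], depth = dp,
                         qual = rowMeans(qual, na.rm = TRUE),
                         sampleData = truth@sampleData)
    metadata(gm)$callQual <- qual
    metadata(gm)$altReads <- k
    gm
}

# flat-prior ML genotype from (alt reads k, depth d); ties to the
# homozygote matching the majority read; Phred-scaled best/second gap
callFromReads <- function(k, d, e) {
    ll0 <- stats::dbinom(k, d, e, log = TRUE)
    ll1 <- stats::dbinom(k, d, 0.5, log = TRUE)
    ll2 <- stats::dbinom(k, d, 1 - e, log = TRUE)
    best <- pmax(ll0, ll1, ll2)
    tol <- 1e-12
    is0 <- ll0 >= best - tol; is1 <- ll1 >= best - tol; is2 <- ll2 >= best - tol
    majAlt <- 2 * k > d
    majRef <- 2 * k < d
    geno <- integer(length(k))
    geno[majAlt] <- ifelse(is2[majAlt], 2L, ifelse(is1[majAlt], 1L, 0L))
    geno[majRef] <- ifelse(is0[majRef], 0L, ifelse(is1[majRef], 1L, 2L))
    half <- !majAlt & !majRef
    geno[half] <- ifelse(is1[half], 1L, ifelse(is0[half], 0L, 2L))
    second <- pmax(pmin(ll0, ll1), pmin(pmax(ll0, ll1), ll2))  # median of 3
    list(genotype = geno, qual = 10 / log(10) * (best - second))
}

#' Write a complete simulated two-platform study to disk
#'
#' One call produces a seed-stamped fixture consumable by the whole
#' pipeline: array VCF and PLINK bed/bim/fam, sequencing VCF with DP and
#' QUAL, sample metadata TSV, platform pairing table, and truth tables
#' (population frequencies, true genotypes, panel membership). Re-running
#' with the same config yields byte-identical files.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the `truth`, `chip` and `wgs` objects and
#'   the written `paths`.
#' @export
makeScenario <- function(cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- simulateTruth(cfg)
    truth <- ascertainPanel(truth, cfg)
    chip <- genotypeChip(truth, cfg)
    wgs <- genotypeWgs(truth, cfg)
    paths <- list(
        chipVcf = file.path(dir, "chip.vcf"),
        chipPlink = file.path(dir, "chip"),
        wgsVcf = file.path(dir, "wgs.vcf"),
        meta = file.path(dir, "samples.tsv"),
        pairs = file.path(dir, "pairs.tsv"),
        popFreq = file.path(dir, "truth_pop_freqs.tsv"),
        truthGeno = file.path(dir, "truth_genotypes.tsv"),
        panel = file.path(dir, "panel_sites.txt"))
    ok <- FALSE
    on.exit(if (!ok) unlink(unlist(paths)))
    writeVcfGenotypes(chip, paths$chipVcf)
    writePlink(chip, paths$chipPlink)
    writeVcfGenotypes(wgs, paths$wgsVcf)
    sd <- as.data.frame(truth@sampleData)
    meta <- rbind(
        data.frame(sample_id = sd$sample, population = sd$population,
                   region = sd$group, platform = "chip", replicate = 0L),
        data.frame(sample_id = sd$sample, population = sd$population,
                   region = sd$group, platform = "wgs", replicate = 0L))
    utils::write.table(meta, paths$meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(sampleA = sd$sample, sampleB = sd$sample),
                       paths$pairs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pf <- data.frame(variant = names(truth@variants),
                     ancestral = truth@ancestralFreq, truth@popFreq)
    utils::write.table(format(pf, digits = 10), paths$popFreq, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(variant = rownames(truth@genotypes),
                                  truth@genotypes),
                       paths$truthGeno, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(names(truth@variants)[truth@panel], paths$panel)
    ok <- TRUE
    invisible(list(truth = truth, chip = chip, wgs = wgs, paths = paths))
}
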