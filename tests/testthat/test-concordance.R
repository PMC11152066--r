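test_that("allele harmonization applies strand, swap and third-allele rules", {
    gmA <- makeGM(matrix(c(0L, 1L, 2L, 1L), 4, 1),
                  pos = c(100L, 200L, 300L, 400L),
                  ref = c("A", "A", "C", "A"), alt = c("G", "G", "A", "T"))
    # B: complement-flip at 100, swapped ref/alt at 200, third allele at 300,
    # palindromic swap at 400
    gmB <- makeGM(matrix(c(2L, 2L, 1L, 0L), 4, 1),
                  pos = c(100L, 200L, 300L, 400L),
                  ref = c("T", "G", "C", "T"), alt = c("C", "A", "T", "A"))
    colnames(calls(gmA))  # touch
    pc <- pairPlatforms(gmA, gmB, data.frame(sampleA = "S1", sampleB = "S1"))
    expect_equal(pc@report$flipped, 1)
    expect_equal(pc@report$swapped, 1)
    expect_equal(pc@report$thirdAlleleDropped, 1)
    expect_equal(pc@report$palindromicDropped, 1)
    expect_equal(length(pc@variants), 2)
    # flip keeps dosage; swap recodes 2 - d
    expect_identical(unname(pc@callsB[, 1]), c(2L, 0L))
})

test_that("pairing fails on empty intersections and duplicate positions", {
    gmA <- makeGM(matrix(0L, 2, 1), pos = c(10L, 20L))
    gmB <- makeGM(matrix(0L, 2, 1), pos = c(30L, 40L))
    expect_error(pairPlatforms(gmA, gmB,
                               data.frame(sampleA = "S1", sampleB = "S1")),
                 "no shared")
    gmDup <- makeGM(matrix(0L, 2, 1), pos = c(10L, 10L),
                    ref = c("A", "A"), alt = c("G", "C"))
    expect_error(pairPlatforms(gmDup, gmA,
                               data.frame(sampleA = "S1", sampleB = "S1")),
                 "duplicate position")
})

test_that("concordance counts match the enumerated example", {
    pc <- makePC(cbind(c(0L, 1L, 2L, NA, 2L)), cbind(c(0L, 2L, 2L, 1L, NA)))
    cs <- concordanceSummary(pc)
    expect_equal(cs$nCommon, 3)
    expect_equal(cs$nConcordant, 2)
    expect_equal(cs$nDiscordant, 1)
    expect_equal(cs$concordanceRate, 2 / 3)
    expect_equal(cs$nMissingA, 1)
    expect_equal(cs$nMissingB, 1)
    expect_equal(cs$nConcordantHom, 2)
    expect_equal(cs$nConcordantHet, 0)
})

test_that("identical platforms give rate 1 and zero common sites give NA", {
    cl <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 20, 2)
    pc <- makePC(cl, cl)
    cs <- concordanceSummary(pc)
    expect_true(all(cs$concordanceRate == 1))
    pc0 <- makePC(cbind(c(0L, NA)), cbind(c(NA, 1L)))
    expect_true(is.na(concordanceSummary(pc0)$concordanceRate))
})

test_that("concordance summary equals a brute-force recount", {
    set.seed(101)
    for (i in 1:20) {
        A <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE), 50, 20)
        B <- matrix(sample(c(0:2, NA), 20 * 50, replace = TRUE), 50, 20)
        colnames(A) <- colnames(B) <- paste0("i", 1:20)
        cs <- as.data.frame(concordanceSummary(makePC(A, B)))
        ref <- bruteConcordance(A, B)
        for (col in c("nCommon", "nConcordant", "nDiscordant", "nMissingA",
                      "nMissingB", "nConcordantHom", "nConcordantHet"))
            expect_equal(unname(cs[[col]]), ref[[col]])
        expect_true(all(cs$nCommon ==
                        cs$nConcordant + cs$nDiscordant))
    }
})

test_that("missingness partition covers all shared variants", {
    set.seed(5)
    A <- matrix(sample(c(0:2, NA), 300, replace = TRUE), 30, 10)
    B <- matrix(sample(c(0:2, NA), 300, replace = TRUE), 30, 10)
    cs <- concordanceSummary(makePC(A, B))
    missBoth <- colSums(is.na(A) & is.na(B))
    expect_true(all(cs$nCommon + cs$nMissingA + cs$nMissingB +
                    missBoth == 30))
})

test_that("allele sensitivity matches the enumerated example", {
    s <- alleleSensitivity(makePC(cbind(c(1L, 2L, 0L, NA)),
                                  cbind(c(1L, 0L, 0L, 2L))))
    expect_equal(s$nAltEither, 3)
    expect_equal(s$nConcordantAlt, 1)
    expect_equal(s$sensitivity, 1 / 3)
    # identical platforms with alt present -> 1
    cl <- cbind(c(1L, 2L, 0L))
    expect_equal(alleleSensitivity(makePC(cl, cl))$sensitivity, 1)
    # no alternate allele anywhere -> undefined
    z <- cbind(c(0L, 0L))
    expect_true(is.na(alleleSensitivity(makePC(z, z))$sensitivity))
})

test_that("class sensitivity matches the enumerated example and symmetry", {
    s <- classSensitivity(makePC(cbind(c(1L, 1L, 0L, 1L)),
                                 cbind(c(1L, 0L, 0L, 2L))), "het")
    expect_equal(s$nEligible, 3)
    expect_equal(s$sensitivityA, 1)
    expect_equal(s$sensitivityB, 1 / 3)
    cl <- cbind(c(1L, 2L, 0L, 1L))
    sym <- classSensitivity(makePC(cl, cl), "hom-alt")
    expect_equal(sym$sensitivityA, sym$sensitivityB)
})

test_that("site concordance and validated lists respect thresholds and nest", {
    A <- cbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, NA), c(0L, NA))
    B <- cbind(c(0L, 1L), c(0L, 2L), c(1L, NA), c(0L, NA), c(2L, NA))
    pc <- makePC(A, B)
    sc <- siteConcordance(pc)
    expect_equal(sc$nBothCalled, c(5, 2))
    expect_equal(sc$rate[1], 3 / 5)
    expect_equal(sc$rate[2], 1 / 2)
    # inclusive threshold at the boundary
    site75 <- makePC(rbind(c(0L, 0L, 0L, 1L)), rbind(c(0L, 0L, 0L, 0L)))
    sc75 <- siteConcordance(site75)
    expect_equal(sc75$rate, 0.75)
    expect_true(sc75$variant %in% validatedSites(sc75, 0.75))
    expect_true(sc75$variant %in% validatedSites(sc75, 0.5))
    expect_false(sc75$variant %in% validatedSites(sc75, 0.9))
})

test_that("never co-called sites are excluded from every validated list", {
    pc <- makePC(cbind(c(0L, NA)), cbind(c(NA, 1L)))
    sc <- siteConcordance(pc)
    expect_true(all(is.na(sc$rate)))
    expect_length(validatedSites(sc, 0.5), 0)
})

test_that("validated lists nest across thresholds on random paired calls", {
    set.seed(33)
    for (i in 1:10) {
        A <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
        B <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
        sc <- siteConcordance(makePC(A, B))
        l90 <- validatedSites(sc, 0.9)
        l75 <- validatedSites(sc, 0.75)
        l50 <- validatedSites(sc, 0.5)
        expect_true(all(l90 %in% l75))
        expect_true(all(l75 %in% l50))
        # brute recount of one threshold
        rate <- sapply(seq_len(nrow(A)), function(i) {
            ok <- !is.na(A[i, ]) & !is.na(B[i, ])
            if (!any(ok)) NA_real_ else mean(A[i, ok] == B[i, ok])
        })
        expect_setequal(l75, as.character(sc$variant)[!is.na(rate) & rate >= 0.75])
    }
})

test_that("replicate reproducibility handles identical and discordant runs", {
    cl <- matrix(rep(sample(0:2, 100, replace = TRUE), 3), 100, 3)
    colnames(cl) <- c("r1", "r2", "r3")
    gm <- makeGM(cl)
    rr <- replicateReproducibility(gm, rep("ind1", 3))
    expect_equal(rr$meanConcordant, 100)
    expect_equal(rr$reproducibility, 1)
    expect_equal(rr$meanConcordanceRate, 1)
    expect_equal(rr$nAllAgree, 100)

    cl2 <- cl[, 1:2]
    cl2[1:10, 2] <- (cl2[1:10, 2] + 1L) %% 3L
    gm2 <- makeGM(cl2)
    rr2 <- replicateReproducibility(gm2, rep("ind1", 2))
    expect_equal(rr2$meanConcordanceRate, 0.9)
    expect_equal(rr2$meanConcordant, 90)
})

test_that("single-replicate individuals are excluded with a warning", {
    gm <- makeGM(matrix(0L, 10, 3), samples = c("a1", "a2", "b1"))
    expect_warning(rr <- replicateReproducibility(gm, c("a", "a", "b")), "b")
    expect_equal(nrow(rr), 1)
    expect_equal(rr$individual, "a")
})

test_that("logistic fit recovers the closed-form two-cell solution", {
    # depth 1: 50/100 concordant; depth 3: 90/100 concordant
    n <- 100
    A <- rbind(matrix(0L, n, 1), matrix(0L, n, 1))
    B <- rbind(cbind(c(rep(0L, 50), rep(1L, 50))),
               cbind(c(rep(0L, 90), rep(1L, 10))))
    dp <- rbind(matrix(1L, n, 1), matrix(3L, n, 1))
    fit <- fitConcordanceLogit(makePC(A, B, depthB = dp), "depth")
    slopeRaw <- (qlogis(0.9) - qlogis(0.5)) / 2     # per depth unit
    expect_equal(fit$slope, slopeRaw * fit$scaling["sd"],
                 ignore_attr = TRUE, tolerance = 1e-6)
    expect_equal(exp(fit$slope / fit$scaling["sd"]), 3.0,
                 ignore_attr = TRUE, tolerance = 1e-5)
    expect_true(fit$converged)
})

test_that("logistic slope is near zero when outcome ignores the covariate", {
    set.seed(77)
    n <- 2000
    A <- matrix(0L, n, 1)
    B <- cbind(ifelse(runif(n) < 0.8, 0L, 1L))
    dp <- cbind(rpois(n, 6) + 1L)
    fit <- fitConcordanceLogit(makePC(A, B, depthB = dp), "depth")
    expect_lt(abs(fit$slope), 3 * fit$se["slope"] + 0.1)
    expect_equal(fit$oddsRatio, exp(fit$slope))
})

test_that("logistic fit recovers a known slope within three standard errors", {
    set.seed(123)
    n <- 10000
    x <- rpois(n, 6)
    xs <- scale(x)[, 1]
    beta <- 0.8
    p <- plogis(0.5 + beta * xs)
    y <- rbinom(n, 1, p)
    A <- matrix(0L, n, 1)
    B <- cbind(ifelse(y == 1, 0L, 1L))
    fit <- fitConcordanceLogit(makePC(A, B, depthB = cbind(x)), "depth")
    expect_lt(abs(fit$slope - beta), 3 * fit$se["slope"])
    expect_gt(fit$pseudoR2, 0)
})
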