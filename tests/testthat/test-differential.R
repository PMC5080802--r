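test_that("library-size equalization preserves column totals by contract", {
    set.seed(71)
    x <- matrix(rnbinom(100 * 4, mu = 50, size = 5), 100, 4)
    x[, 2] <- x[, 2] * 3L
    adj <- equalizeLibrarySizes(x)
    target <- exp(mean(log(colSums(x))))
    expect_true(all(abs(colSums(adj) - target) < 1))
    expect_true(all(adj >= 0))
})

test_that("the conditional exact test matches brute-force enumeration", {
    for (phi in c(0, 0.1, 0.5)) {
        for (t in c(1, 2, 7, 15, 30)) {
            for (a in unique(c(0, 1, t %/% 3, t))) {
                b <- t - a
                p <- exactTestNB(a, b, 3, 5, phi)
                expect_equal(p, oracleExactP(a, b, 3, 5, phi),
                             tolerance = 1e-9,
                             info = sprintf("phi=%g a=%d b=%d", phi, a, b))
            }
        }
    }
})

test_that("exact-test special cases behave as documented", {
    # identical group sums with equal sizes: most likely outcome, p = 1
    expect_equal(exactTestNB(12, 12, 4, 4, 0.2), 1)
    expect_equal(exactTestNB(0, 0, 4, 4, 0.2), 1)
    # Poisson limit equals the exact binomial minimum-likelihood test
    a <- 3; b <- 14; nA <- 2; nB <- 5
    pk <- dbinom(0:(a + b), a + b, nA / (nA + nB))
    pBinom <- sum(pk[pk <= pk[a + 1] * (1 + 1e-10)])
    expect_equal(exactTestNB(a, b, nA, nB, 0), pBinom, tolerance = 1e-12)
    expect_error(exactTestNB(-1, 3, 2, 2, 0.1), "non-negative")
    expect_true(all(exactTestNB(c(5, 80), c(9, 11), 3, 3, 0.3) <= 1))
})

test_that("BH adjustment reproduces the hand step-up computation", {
    expect_equal(bhFdr(0.03), 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 1.0)),
                 c(0.04, 0.04, 0.04, 1.0))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_error(bhFdr(c(0.1, NaN)), "finite")
    expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
})

test_that("common dispersion estimation recovers simulated truth", {
    set.seed(72)
    grp <- rep(c("A", "B"), each = 5)
    # Poisson counts: estimate collapses toward zero
    xp <- matrix(rpois(20 * 10, lambda = rep(exp(runif(20, 2, 5)), 10)),
                 20, 10)
    expect_lte(commonDispersion(estimateDispersion(xp, grp)), 0.05)
    # NB truth 0.4 at n = 10 per group, 500 genes
    grp2 <- rep(c("A", "B"), each = 10)
    mu <- exp(runif(500, 2, 6))
    xn <- matrix(rnbinom(500 * 20, mu = rep(mu, 20), size = 1 / 0.4),
                 500, 20)
    est <- commonDispersion(estimateDispersion(xn, grp2))
    expect_gte(est, 0.3); expect_lte(est, 0.5)
    # invariance to sample order
    perm <- sample(20)
    expect_equal(commonDispersion(estimateDispersion(xn[, perm],
                                                     grp2[perm])), est,
                 tolerance = 1e-6)
    expect_error(estimateDispersion(xn[, 1:3], c("A", "A", "B")),
                 "at least 2")
})

test_that("dispersion estimates track the edgeR qCML reference", {
    skip_if_not_installed("edgeR")
    set.seed(73)
    grp <- rep(c("A", "B"), each = 6)
    x <- matrix(rnbinom(300 * 12, mu = rep(exp(runif(300, 2, 6)), 12),
                        size = 1 / 0.25), 300, 12)
    mine <- commonDispersion(estimateDispersion(x, grp))
    ref <- edgeR::estimateCommonDisp(edgeR::DGEList(x, group = grp))
    expect_equal(mine, ref$common.dispersion, tolerance = 0.15)
})

test_that("null count matrices yield no DE calls at FDR < 0.001", {
    cfg <- CountSimConfig(1000, c(Warmblood = 10, pony = 10),
                          groupVar = "breed", dispersion = 0.2,
                          seed = 74)
    se <- simulateCounts(cfg)
    de <- runDE(SummarizedExperiment::assay(se),
                SummarizedExperiment::colData(se)$breed)
    expect_equal(sum(de$de), 0)
})

test_that("planted effects are recovered at the unbalanced serum design", {
    planted <- data.frame(mirna = 1:50, group = "pony",
                          log2FC = rep(c(2, -2, 3, -3, 4), 10))
    cfg <- CountSimConfig(600, c(Warmblood = 44, pony = 5),
                          groupVar = "breed", dispersion = 0.15,
                          libSizeRange = c(8e5, 1.2e6),
                          effects = planted, seed = 75)
    se <- simulateCounts(cfg)
    de <- runDE(SummarizedExperiment::assay(se),
                SummarizedExperiment::colData(se)$breed,
                levels = c("Warmblood", "pony"))
    called <- de$id[de$de]
    plantedIds <- paste0("mir-", 1:50)
    testable <- intersect(plantedIds, de$id)  # planted rows that pass the
    recall <- sum(called %in% plantedIds) / length(testable)  # prefilter
    precision <- mean(called %in% plantedIds)
    expect_gte(recall, 0.8)
    expect_gte(precision, 0.9)
    # label swap flips fold changes, leaves p-values untouched
    sw <- runDE(SummarizedExperiment::assay(se),
                SummarizedExperiment::colData(se)$breed,
                levels = c("pony", "Warmblood"))
    sw <- sw[match(de$id, sw$id), ]
    expect_equal(sw$logFC, -de$logFC, tolerance = 1e-9)
    expect_equal(sw$PValue, de$PValue, tolerance = 1e-12)
})

test_that("power is monotone in the planted effect size", {
    hit <- vapply(c(1, 2, 4), function(lfc) {
        cfg <- CountSimConfig(300, c(A = 8, B = 8), dispersion = 0.1,
                              libSizeRange = c(1e6, 1e6),
                              effects = data.frame(mirna = 1:30,
                                                   group = "B",
                                                   log2FC = lfc),
                              seed = 76)
        se <- simulateCounts(cfg)
        de <- runDE(SummarizedExperiment::assay(se),
                    SummarizedExperiment::colData(se)$tissue,
                    fdrThreshold = 0.001)
        sum(de$de & de$id %in% paste0("mir-", 1:30))
    }, numeric(1))
    expect_true(all(diff(hit) >= 0))
    expect_gt(hit[3], hit[1])
})

test_that("covariate screening is calibrated and detects planted slopes", {
    cfg <- CountSimConfig(400, c(Warmblood = 44, pony = 5),
                          groupVar = "breed", dispersion = 0.1,
                          seed = 77)
    se <- simulateCounts(cfg)
    x <- SummarizedExperiment::assay(se)
    cd <- SummarizedExperiment::colData(se)
    # independent numeric covariate: near-nominal false positive rate
    null <- covariateScreen(x, cd$absorbance414)
    expect_lte(mean(null$FDR < 0.05), 0.05)
    # plant one miRNA proportional to absorbance (strong slope)
    x2 <- x
    set.seed(79)
    x2[3, ] <- round(5000 + 30000 * cd$absorbance414) +
        rpois(ncol(x), 20)
    hit <- covariateScreen(x2, cd$absorbance414)
    expect_lt(hit$FDR[hit$id == "mir-3"], 0.05)
    expect_error(covariateScreen(x, rep(1, ncol(x))), "constant")
    # a binary covariate equal to the group labels reproduces the DE
    # p-value ordering on the same prefiltered rows
    byCov <- covariateScreen(x, as.character(cd$breed))
    byDe <- runDE(x, cd$breed)
    expect_equal(byCov$id, byDe$id)
    expect_equal(byCov$PValue, byDe$PValue, tolerance = 1e-12)
})

test_that("null exact-test p-values are stochastically conservative", {
    set.seed(78)
    n <- 3000
    mu <- exp(runif(n, 1.5, 4))
    phi <- 0.1
    a <- rnbinom(n, size = 4 / phi, mu = 4 * mu)
    b <- rnbinom(n, size = 4 / phi, mu = 4 * mu)
    p <- exactTestNB(a, b, 4, 4, phi)
    for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5))
        expect_lte(mean(p <= alpha),
                   alpha + 3 * sqrt(alpha * (1 - alpha) / n))
})
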