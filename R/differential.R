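## Two-group negative binomial exact-test differential expression with a
## common qCML dispersion, BH FDR, and single-covariate screening.

#' Equalize effective library sizes
#'
#' Scales every column to the geometric mean of the effective library
#' sizes (library size x normalization factor) with mean-preserving
#' rounding: per column, values are floored and the per-column rounding
#' deficit is distributed to the cells with the largest fractional parts,
#' so each adjusted column sum matches its scaled total. This summarizes
#' the quantile adjustment by its contract: adjusted columns share one
#' effective size.
#'
#' @param counts count matrix.
#' @param factors normalization factors (default all 1).
#' @return integer matrix of adjusted pseudo-counts.
#' @export
equalizeLibrarySizes <- function(counts, factors = NULL) {
    x <- .countsMatrix(counts)
    if (is.null(factors)) factors <- rep(1, ncol(x))
    eff <- colSums(x) * factors
    if (any(eff <= 0)) stop("non-positive effective library size",
                            call. = FALSE)
    target <- exp(mean(log(eff)))
    out <- x
    for (j in seq_len(ncol(x))) {
        v <- x[, j] * target / eff[j]
        r <- floor(v)
        deficit <- round(sum(v)) - sum(r)
        if (deficit > 0) {
            frac <- v - r
            top <- order(frac, decreasing = TRUE)[seq_len(deficit)]
            r[top] <- r[top] + 1
        }
        out[, j] <- r
    }
    storage.mode(out) <- "integer"
    out
}

# conditional log-likelihood of a common dispersion phi given per-group
# totals; counts assumed on a common effective library size
.condLogLik <- function(phi, counts, groups) {
    ll <- 0
    for (g in levels(groups)) {
        y <- counts[, groups == g, drop = FALSE]
        n <- ncol(y)
        z <- rowSums(y)
        if (phi == 0) {
            # Poisson limit: counts | total are multinomial(1/n)
            ll <- ll + sum(lgamma(z + 1) - rowSums(lgamma(y + 1)) -
                           z * log(n))
        } else {
            r <- 1 / phi
            ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) -
                           rowSums(lgamma(y + 1)) + lgamma(z + 1) +
                           lgamma(n * r) - lgamma(z + n * r))
        }
    }
    ll
}

#' Common dispersion by conditional maximum likelihood
#'
#' After equalizing effective library sizes, the common negative binomial
#' dispersion (variance = mu + phi mu^2) maximizes the conditional
#' likelihood of the counts given each group's total, summed over genes
#' and groups. The search is a coarse log-spaced grid (including the
#' Poisson boundary phi = 0) refined by golden-section; deterministic.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param groups group membership per sample (each group needs >= 2
#'   samples).
#' @param factors optional normalization factors for the equalization.
#' @return a \link{DispersionEstimate}.
#' @export
estimateDispersion <- function(counts, groups, factors = NULL) {
    x <- .countsMatrix(counts)
    groups <- droplevels(as.factor(groups))
    if (any(table(groups) < 2))
        stop("every group needs at least 2 samples", call. = FALSE)
    x <- equalizeLibrarySizes(x, factors)
    grid <- c(0, 10^seq(-4, 1, length.out = 26))
    ll <- vapply(grid, .condLogLik, numeric(1), counts = x,
                 groups = groups)
    best <- which.max(ll)
    if (best == 1L)
        return(new("DispersionEstimate", common = 0, logLik = ll[1]))
    lo <- grid[max(best - 1L, 1L)]
    hi <- grid[min(best + 1L, length(grid))]
    gr <- (sqrt(5) - 1) / 2
    a <- log(max(lo, 1e-6)); b <- log(hi)
    for (it in seq_len(40)) {
        c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
        if (.condLogLik(exp(c1), x, groups) >=
            .condLogLik(exp(c2), x, groups)) b <- c2 else a <- c1
        if (b - a < 1e-6) break
    }
    phi <- exp((a + b) / 2)
    llPhi <- .condLogLik(phi, x, groups)
    if (ll[1] >= llPhi)
        return(new("DispersionEstimate", common = 0, logLik = ll[1]))
    new("DispersionEstimate", common = phi, logLik = llPhi)
}

#' Negative binomial conditional exact test
#'
#' For each gene, conditions on the total count t = a + b of the two group
#' sums (on equalized library sizes). Under a common per-sample mean and
#' dispersion phi, the group sums are NB with sizes nA/phi and nB/phi and
#' a | t follows a beta-binomial-type law free of the mean. The two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood method, ties included); at phi = 0 it
#' reduces to the exact binomial test of a | t with proportion
#' nA / (nA + nB).
#'
#' @param a,b per-gene count sums in groups A and B.
#' @param nA,nB group sample sizes.
#' @param phi common dispersion (>= 0).
#' @return vector of p-values in (0, 1].
#' @export
exactTestNB <- function(a, b, nA, nB, phi) {
    if (any(a < 0) || any(b < 0))
        stop("counts must be non-negative", call. = FALSE)
    stopifnot(length(a) == length(b), phi >= 0)
    vapply(seq_along(a), function(i) {
        t <- a[i] + b[i]
        if (t == 0) return(1)
        # for large totals the conditional law is evaluated on a window of
        # +- ~12 sd around its mode (and the observed value); outside mass
        # is below ~1e-14 and every outside outcome is less likely than
        # the observed one, so the two-sided sum is unaffected
        pA <- nA / (nA + nB)
        if (phi == 0) {
            sdv <- sqrt(t * pA * (1 - pA))
        } else {
            sA <- nA / phi; sB <- nB / phi
            sdv <- sqrt(t * pA * (1 - pA) * (t + sA + sB) / (sA + sB + 1))
        }
        modeK <- round(t * pA)
        halfW <- ceiling(12 * sdv) + 10L
        k <- if (t <= 2000) 0:t
             else max(0L, min(modeK - halfW, a[i] - 5L)):
                  min(t, max(modeK + halfW, a[i] + 5L))
        if (phi == 0) {
            logp <- dbinom(k, t, pA, log = TRUE)
        } else {
            logp <- lgamma(k + sA) - lgamma(k + 1) +
                    lgamma(t - k + sB) - lgamma(t - k + 1)
        }
        logp <- logp - max(logp)
        p <- exp(logp); p <- p / sum(p)
        pObs <- p[match(a[i], k)]
        min(1, sum(p[p <= pObs * (1 + 1e-10)]))
    }, numeric(1))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues p-values in [0, 1]; NaN/NA is an error.
#' @return adjusted FDR values.
#' @export
bhFdr <- function(pvalues) {
    if (any(!is.finite(pvalues)))
        stop("p-values must be finite", call. = FALSE)
    if (any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression
#'
#' The full serum-comparison path: keep miRNAs with cpm above
#' \code{minCpm} in at least \code{frac} of all samples, TMM-normalize,
#' equalize library sizes, estimate the common dispersion, run the
#' conditional exact test per miRNA, adjust with Benjamini-Hochberg and
#' call miRNAs below \code{fdrThreshold} differentially expressed. log2
#' fold changes are computed on normalized group mean cpm with a 0.5
#' pseudocount (group B relative to group A), so they are always finite.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param groups two-level group membership per sample; the first level
#'   (or \code{levels[1]}) is the baseline.
#' @param levels optional explicit baseline/contrast level order.
#' @param fdrThreshold FDR below which a miRNA is called DE.
#' @param minCpm,frac expression prefilter (> minCpm cpm in >= frac of
#'   samples).
#' @return \link[S4Vectors]{DataFrame} sorted by FDR with columns id,
#'   logFC, PValue, FDR, direction, de; the dispersion used is in
#'   \code{metadata(result)$dispersion}.
#' @export
runDE <- function(counts, groups, levels = NULL, fdrThreshold = 0.001,
                  minCpm = 10, frac = 0.9) {
    x <- .countsMatrix(counts)
    groups <- as.factor(groups)
    if (is.null(levels)) levels <- base::levels(groups)
    stopifnot(length(levels) == 2)
    if (any(!(levels %in% groups)))
        stop("a group is empty", call. = FALSE)
    x <- x[, groups %in% levels, drop = FALSE]
    groups <- factor(as.character(groups[groups %in% levels]),
                     levels = levels)
    cpm0 <- cpmMatrix(x)
    keep <- rowMeans(cpm0 > minCpm) >= frac
    x <- x[keep, , drop = FALSE]
    if (!nrow(x))
        return(DataFrame(id = character(0), logFC = numeric(0),
                         PValue = numeric(0), FDR = numeric(0),
                         direction = character(0), de = logical(0)))
    f <- tmmFactors(x)
    disp <- estimateDispersion(x, groups, factors = f)
    adj <- equalizeLibrarySizes(x, f)
    ja <- groups == levels[1]; jb <- groups == levels[2]
    a <- rowSums(adj[, ja, drop = FALSE])
    b <- rowSums(adj[, jb, drop = FALSE])
    p <- exactTestNB(a, b, sum(ja), sum(jb), commonDispersion(disp))
    fdr <- bhFdr(p)
    cpmN <- cpmMatrix(x, f)
    logFC <- log2((rowMeans(cpmN[, jb, drop = FALSE]) + 0.5) /
                  (rowMeans(cpmN[, ja, drop = FALSE]) + 0.5))
    out <- DataFrame(id = rownames(x), logFC = logFC, PValue = p,
                     FDR = fdr,
                     direction = ifelse(logFC >= 0, "up", "down"),
                     de = fdr < fdrThreshold)
    out <- out[order(out$FDR, out$PValue), ]
    S4Vectors::metadata(out)$dispersion <- commonDispersion(disp)
    S4Vectors::metadata(out)$contrast <- paste(levels[2], "vs", levels[1])
    out
}

#' Screen a single covariate against miRNA expression
#'
#' Binary covariates (e.g. sex) run through the same prefilter + TMM +
#' common dispersion + conditional exact test path as the group
#' comparison; numeric covariates (e.g. age, haemolysis absorbance at
#' 414 nm) use a Spearman rank correlation test of log2(cpm + 0.5) per
#' miRNA. FDR is Benjamini-Hochberg across miRNAs.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param covariate one value per sample; two-level factor/character or
#'   numeric.
#' @param minCpm,frac expression prefilter as in \code{\link{runDE}}.
#' @return DataFrame with id, statistic, PValue, FDR sorted by FDR.
#' @export
covariateScreen <- function(counts, covariate, minCpm = 10, frac = 0.9) {
    x <- .countsMatrix(counts)
    if (length(covariate) != ncol(x))
        stop("covariate must have one value per sample", call. = FALSE)
    if (length(unique(covariate)) < 2)
        stop("constant covariate", call. = FALSE)
    if (is.numeric(covariate)) {
        cpm0 <- cpmMatrix(x)
        keep <- rowMeans(cpm0 > minCpm) >= frac
        x <- x[keep, , drop = FALSE]
        f <- tmmFactors(x)
        L <- log2(cpmMatrix(x, f) + 0.5)
        res <- t(vapply(seq_len(nrow(L)), function(i) {
            ct <- suppressWarnings(cor.test(L[i, ], covariate,
                                            method = "spearman"))
            c(ct$estimate, ct$p.value)
        }, numeric(2)))
        out <- DataFrame(id = rownames(x), statistic = res[, 1],
                         PValue = res[, 2], FDR = bhFdr(res[, 2]))
    } else {
        cv <- as.factor(covariate)
        if (nlevels(cv) != 2)
            stop("categorical covariates must have exactly 2 levels",
                 call. = FALSE)
        de <- runDE(x, cv, fdrThreshold = 1, minCpm = minCpm, frac = frac)
        out <- DataFrame(id = de$id, statistic = de$logFC,
                         PValue = de$PValue, FDR = de$FDR)
    }
    out[order(out$FDR, out$PValue), ]
}
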