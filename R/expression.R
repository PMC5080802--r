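## Quantification against the catalog, cpm/TMM normalization, the two
## expression-threshold rules (low-expression prefilter and group-level
## expressed calls), specificity/universal sets and leading-logFC MDS.

#' Quantify catalog miRNAs per sample
#'
#' A tag counts toward a mature/hairpin combination iff it is on the same
#' strand and its interval lies within the mature interval extended by
#' \code{tol} nt on each side. A tag matching several combinations (one
#' mature can derive from more than one hairpin) contributes its full count
#' to each.
#'
#' @param tagsList named list of per-sample aligned-tag GRanges.
#' @param catalog a \link{MirnaCatalog}.
#' @param tol assignment slack around the mature interval (nt).
#' @param metadata optional DataFrame of sample metadata (one row per
#'   sample, in list order).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} of raw
#'   counts (entries x samples).
#' @export
quantifyTags <- function(tagsList, catalog, tol = 2L, metadata = NULL) {
    stopifnot(is.list(tagsList), is(catalog, "MirnaCatalog"))
    e <- catalogEntries(catalog)
    target <- GRanges(seqnames(e),
                      IRanges(start(e) - tol, end(e) + tol),
                      strand = strand(e))
    counts <- matrix(0L, nrow = length(e), ncol = length(tagsList),
                     dimnames = list(mcols(e)$id, names(tagsList)))
    for (j in seq_along(tagsList)) {
        tags <- .checkTags(tagsList[[j]])
        if (!length(tags) || !length(e)) next
        hits <- findOverlaps(tags, target, type = "within")
        if (length(hits)) {
            add <- tapply(mcols(tags)$count[queryHits(hits)],
                          subjectHits(hits), sum)
            counts[as.integer(names(add)), j] <- as.integer(add)
        }
    }
    cd <- if (is.null(metadata))
        DataFrame(sample = names(tagsList)) else metadata
    SummarizedExperiment(assays = list(counts = counts), colData = cd,
                         rowData = mcols(e))
}

.countsMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
    else as.matrix(counts)
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-bias correction by the weighted trimmed mean of per-gene
#' log2 expression ratios against a reference sample (the column whose
#' upper quartile of scaled counts is closest to the mean upper quartile).
#' For each sample, M (log2 ratio) and A (mean log2 abundance) are computed
#' over genes positive in both sample and reference, the most extreme
#' \code{trimM} of M values and \code{trimA} of A values are trimmed on
#' each side, and the factor is 2 to the precision-weighted mean of the
#' remaining M values (weights are inverse asymptotic variances). Factors
#' are rescaled to geometric mean 1, so they are invariant to pure depth
#' changes.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param trimM two-sided trim fraction on M values (default 0.3).
#' @param trimA two-sided trim fraction on A values (default 0.05).
#' @return named numeric vector of per-sample factors.
#' @export
tmmFactors <- function(counts, trimM = 0.3, trimA = 0.05) {
    x <- .countsMatrix(counts)
    if (ncol(x) < 2) stop("need at least 2 samples", call. = FALSE)
    lib <- colSums(x)
    if (any(lib == 0))
        stop("all-zero column(s): ",
             paste(colnames(x)[lib == 0], collapse = ", "), call. = FALSE)
    scaled <- sweep(x, 2, lib, "/")
    uq <- apply(scaled, 2, quantile, 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(x)), function(j) {
        if (j == ref) return(1)
        keep <- x[, j] > 0 & x[, ref] > 0
        y <- x[keep, j]; r <- x[keep, ref]
        py <- y / lib[j]; pr <- r / lib[ref]
        M <- log2(py / pr)
        A <- 0.5 * (log2(py) + log2(pr))
        # binomial delta-method variances on the proportion scale, so a
        # pure depth change leaves every weight (hence the factor) intact
        w <- (1 - py) / py + (1 - pr) / pr
        n <- length(M)
        loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
        loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
        rkM <- rank(M, ties.method = "first")
        rkA <- rank(A, ties.method = "first")
        sel <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
        if (!any(sel)) return(1)
        2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    setNames(f, colnames(x))
}

#' Counts per million on effective library sizes
#'
#' cpm[i, j] = counts[i, j] / (librarySize[j] * factor[j]) * 1e6.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param factors normalization factors (default all 1).
#' @return numeric cpm matrix.
#' @export
cpmMatrix <- function(counts, factors = NULL) {
    x <- .countsMatrix(counts)
    if (is.null(factors)) factors <- rep(1, ncol(x))
    if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
    eff <- colSums(x) * factors
    if (any(eff == 0)) stop("zero effective library size", call. = FALSE)
    sweep(x, 2, eff, "/") * 1e6
}

#' Low-expression prefilter
#'
#' A miRNA is removed iff its cpm is below \code{minCpm} in at least
#' \code{frac} of all samples (lowly expressed miRNAs play minor
#' regulatory roles and mostly contribute noise).
#'
#' @param cpm cpm matrix.
#' @param minCpm expression floor (default 1 cpm).
#' @param frac sample fraction at which the floor removes a row.
#' @return logical vector of kept rows.
#' @export
filterLowExpression <- function(cpm, minCpm = 1, frac = 0.9) {
    rowMeans(cpm < minCpm) < frac
}

#' Group-level expression, specificity and universal calls
#'
#' A miRNA is expressed in a group iff its cpm reaches \code{minCpm} in at
#' least \code{frac} of the group's samples; group-specific means expressed
#' in exactly one group, universal means expressed in every group. Entries
#' specific to a group with group mean cpm above \code{highCpm} are
#' reported separately.
#'
#' @param cpm cpm matrix (TMM-normalized for downstream use).
#' @param groups factor/character of group membership per sample.
#' @param minCpm group expression threshold (default 10 cpm).
#' @param frac required fraction of group samples (default 0.9).
#' @param highCpm reporting threshold on the group mean (default 100 cpm).
#' @return a \link{GroupExpression}.
#' @export
groupExpressionCalls <- function(cpm, groups, minCpm = 10, frac = 0.9,
                                 highCpm = 100) {
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(cpm))
    small <- table(groups) < 2
    if (any(small))
        warning("group(s) with < 2 samples: ",
                paste(names(which(small)), collapse = ", "))
    lv <- levels(groups)
    expressed <- vapply(lv, function(g)
        rowMeans(cpm[, groups == g, drop = FALSE] >= minCpm) >= frac,
        logical(nrow(cpm)))
    expressed <- matrix(expressed, nrow = nrow(cpm),
                        dimnames = list(rownames(cpm), lv))
    specific <- expressed & rowSums(expressed) == 1
    universal <- rowSums(expressed) == length(lv)
    highs <- list()
    for (g in lv) {
        gm <- rowMeans(cpm[, groups == g, drop = FALSE])
        i <- which(specific[, g] & gm > highCpm)
        if (length(i))
            highs[[g]] <- DataFrame(group = g, mirna = rownames(cpm)[i],
                                    meanCpm = unname(gm[i]))
    }
    highTable <- if (length(highs)) do.call(rbind, highs)
        else DataFrame(group = character(0), mirna = character(0),
                       meanCpm = numeric(0))
    new("GroupExpression", expressed = expressed, specific = specific,
        universal = universal, highTable = highTable,
        params = c(minCpm = minCpm, frac = frac, highCpm = highCpm))
}

#' Leading log-fold-change multidimensional scaling
#'
#' The distance between two samples is the root mean square of the
#' \code{topN} largest absolute log2 fold changes between them (computed on
#' cpm with a 0.5 pseudocount), projected to two dimensions by classical
#' metric scaling. Sign and rotation of the axes are unconstrained.
#'
#' @param cpm cpm matrix.
#' @param topN number of leading fold changes per pair (default 500).
#' @return samples x 2 coordinate matrix with attribute \code{dist}.
#' @export
mdsCoordinates <- function(cpm, topN = 500L) {
    n <- ncol(cpm)
    if (n < 3) stop("need at least 3 samples", call. = FALSE)
    L <- log2(cpm + 0.5)
    k <- min(topN, nrow(cpm))
    d <- matrix(0, n, n, dimnames = list(colnames(cpm), colnames(cpm)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        fc2 <- sort((L[, i] - L[, j])^2, decreasing = TRUE)[seq_len(k)]
        d[i, j] <- d[j, i] <- sqrt(mean(fc2))
    }
    xy <- cmdscale(stats::as.dist(d), k = 2)
    colnames(xy) <- c("dim1", "dim2")
    attr(xy, "dist") <- d
    xy
}
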