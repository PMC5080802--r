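#' Read-stack shape of a transcribed miRNA locus
#'
#' Describes how simulated reads distribute over a hairpin: the fraction
#' landing on the mature arm, star arm and loop (the remainder is scattered
#' uniformly over the hairpin), the 5' end jitter (standard deviation in nt),
#' the fraction of reads carrying 1-3 untemplated 3' A/U additions, and the
#' per-locus sequencing depth.
#'
#' Mature-arm dominance (mature >= star >= loop) reflects miRNA biogenesis:
#' the loop and star strands are usually degraded, so read coverage peaks on
#' the mature sequence.
#'
#' @slot matureFraction,starFraction,loopFraction numeric fractions in [0,1]
#'   summing to at most 1.
#' @slot fivePrimeJitterSd non-negative numeric, nt.
#' @slot tailAuFraction fraction of reads with untemplated A/U tails.
#' @slot depth integer reads per locus.
#' @export
setClass("StackProfile",
    representation(matureFraction = "numeric", starFraction = "numeric",
                   loopFraction = "numeric", fivePrimeJitterSd = "numeric",
                   tailAuFraction = "numeric", depth = "integer"),
    prototype(matureFraction = 0.7, starFraction = 0.15, loopFraction = 0.02,
              fivePrimeJitterSd = 0, tailAuFraction = 0.1, depth = 50L))

setValidity("StackProfile", function(object) {
    f <- c(object@matureFraction, object@starFraction, object@loopFraction,
           object@tailAuFraction)
    if (any(f < 0) || any(f > 1))
        return("fractions must lie in [0, 1]")
    if (sum(f[1:3]) > 1 + 1e-9)
        return("matureFraction + starFraction + loopFraction must be <= 1")
    if (object@matureFraction < object@starFraction ||
        object@starFraction < object@loopFraction)
        return("expected matureFraction >= starFraction >= loopFraction")
    if (object@fivePrimeJitterSd < 0) return("fivePrimeJitterSd must be >= 0")
    if (object@depth < 0) return("depth must be >= 0")
    TRUE
})

#' @param matureFraction,starFraction,loopFraction,fivePrimeJitterSd,tailAuFraction,depth
#'   see slot descriptions.
#' @rdname StackProfile-class
#' @export
StackProfile <- function(matureFraction = 0.7, starFraction = 0.15,
                         loopFraction = 0.02, fivePrimeJitterSd = 0,
                         tailAuFraction = 0.1, depth = 50L) {
    new("StackProfile", matureFraction = matureFraction,
        starFraction = starFraction, loopFraction = loopFraction,
        fivePrimeJitterSd = fivePrimeJitterSd,
        tailAuFraction = tailAuFraction, depth = as.integer(depth))
}

setMethod("show", "StackProfile", function(object) {
    cat("StackProfile: mature", object@matureFraction,
        "star", object@starFraction, "loop", object@loopFraction,
        "| 5' jitter sd", object@fivePrimeJitterSd,
        "| A/U tail", object@tailAuFraction,
        "| depth", object@depth, "\n")
})

#' Configuration for the negative binomial count simulator
#'
#' @slot nMirnas number of simulated miRNAs.
#' @slot groupSizes named integer vector of samples per group; names are the
#'   group labels (tissues or breeds). Each group needs >= 2 samples.
#' @slot groupVar which metadata column the groups populate ("tissue" or
#'   "breed").
#' @slot dispersion common NB dispersion phi >= 0 (variance = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @slot libSizeRange length-2 numeric, uniform range of library sizes.
#' @slot effects data.frame with columns mirna (row index or id), group,
#'   log2FC: planted multiplicative effects.
#' @slot compositionFraction fraction of miRNAs inflated in the
#'   composition-bias samples (exercises TMM).
#' @slot compositionFactor fold inflation applied to those miRNAs.
#' @slot compositionSamples integer indices of biased samples.
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("CountSimConfig",
    representation(nMirnas = "integer", groupSizes = "integer",
                   groupVar = "character", dispersion = "numeric",
                   libSizeRange = "numeric", effects = "data.frame",
                   compositionFraction = "numeric",
                   compositionFactor = "numeric",
                   compositionSamples = "integer", seed = "integer"))

setValidity("CountSimConfig", function(object) {
    if (object@nMirnas < 1) return("nMirnas must be >= 1")
    if (is.null(names(object@groupSizes)) || any(names(object@groupSizes) == ""))
        return("groupSizes must be named by group label")
    if (any(object@groupSizes < 2)) return("group sizes must be >= 2")
    if (object@dispersion < 0) return("dispersion must be >= 0")
    if (length(object@libSizeRange) != 2 || any(object@libSizeRange <= 0))
        return("libSizeRange must be two positive numbers")
    if (nrow(object@effects) &&
        !all(c("mirna", "group", "log2FC") %in% colnames(object@effects)))
        return("effects needs columns mirna, group, log2FC")
    if (nrow(object@effects) &&
        !all(object@effects$group %in% names(object@groupSizes)))
        return("every effect must refer to a defined group")
    if (object@compositionFraction < 0 || object@compositionFraction > 1)
        return("compositionFraction must lie in [0, 1]")
    TRUE
})

#' @param nMirnas,groupSizes,groupVar,dispersion,libSizeRange,effects,compositionFraction,compositionFactor,compositionSamples,seed
#'   see slot descriptions.
#' @rdname CountSimConfig-class
#' @export
CountSimConfig <- function(nMirnas, groupSizes, groupVar = "tissue",
                           dispersion = 0.1, libSizeRange = c(5e5, 2e6),
                           effects = data.frame(mirna = integer(),
                                                group = character(),
                                                log2FC = numeric()),
                           compositionFraction = 0, compositionFactor = 8,
                           compositionSamples = integer(), seed = 1L) {
    new("CountSimConfig", nMirnas = as.integer(nMirnas),
        groupSizes = setNames(as.integer(groupSizes), names(groupSizes)),
        groupVar = groupVar, dispersion = dispersion,
        libSizeRange = as.numeric(libSizeRange), effects = effects,
        compositionFraction = compositionFraction,
        compositionFactor = compositionFactor,
        compositionSamples = as.integer(compositionSamples),
        seed = as.integer(seed))
}

setMethod("show", "CountSimConfig", function(object) {
    cat("CountSimConfig:", object@nMirnas, "miRNAs x",
        sum(object@groupSizes), "samples (",
        paste(names(object@groupSizes), object@groupSizes,
              sep = "=", collapse = ", "),
        ") | dispersion", object@dispersion,
        "|", nrow(object@effects), "planted effects\n")
})

#' Signal-to-noise profile over discovery score cutoffs
#'
#' Real candidate counts against position-permuted counts over integer
#' log-odds score cutoffs, mirroring the permutation calibration used to pick
#' a discovery score threshold.
#'
#' @slot cutoffs integer score cutoffs (default -10..10).
#' @slot realCounts candidate calls at or above each cutoff in the real data.
#' @slot permCounts nPerm x length(cutoffs) matrix of permuted call counts.
#' @slot snr realCounts / column means of permCounts; NaN where 0/0.
#' @export
setClass("SNRProfile",
    representation(cutoffs = "integer", realCounts = "integer",
                   permCounts = "matrix", snr = "numeric"))

setValidity("SNRProfile", function(object) {
    k <- length(object@cutoffs)
    if (length(object@realCounts) != k || length(object@snr) != k ||
        ncol(object@permCounts) != k)
        return("cutoffs, realCounts, snr and permCounts columns must align")
    TRUE
})

setMethod("show", "SNRProfile", function(object) {
    cat("SNRProfile over", length(object@cutoffs), "cutoffs,",
        nrow(object@permCounts), "permutations\n")
    print(data.frame(cutoff = object@cutoffs, real = object@realCounts,
                     permMean = colMeans(object@permCounts),
                     SNR = round(object@snr, 3)))
})

#' @rdname SNRProfile-class
#' @param object an \code{SNRProfile}.
#' @export
snrTable <- function(object) {
    stopifnot(is(object, "SNRProfile"))
    data.frame(cutoff = object@cutoffs, real = object@realCounts,
               permMean = colMeans(object@permCounts), snr = object@snr)
}

#' Consolidated miRNA catalog
#'
#' Non-redundant mature/hairpin entries after cross-sample merging, the
#' singleton filter and known-miRNA annotation. The ranges are the mature
#' intervals; mcols carry id, hairpin (IRanges), supportSamples, bestScore,
#' tools, novelty, knownOverlap and knownPartner.
#'
#' @slot entries a \link[GenomicRanges]{GRanges} of catalog entries.
#' @export
setClass("MirnaCatalog", representation(entries = "GRanges"))

setValidity("MirnaCatalog", function(object) {
    e <- object@entries
    need <- c("id", "hairpin", "supportSamples", "bestScore", "tools",
              "novelty", "knownOverlap")
    if (!all(need %in% colnames(mcols(e))))
        return(paste("entries must carry mcols:", paste(need, collapse = ", ")))
    if (length(e)) {
        if (anyDuplicated(mcols(e)$id)) return("entry ids must be unique")
        h <- mcols(e)$hairpin
        if (any(start(e) < start(h) | end(e) > end(h)))
            return("mature interval must lie within its hairpin")
        if (any(mcols(e)$novelty & mcols(e)$knownOverlap == "same-strand"))
            return("an entry cannot be both novel and known same-strand")
    }
    TRUE
})

setMethod("show", "MirnaCatalog", function(object) {
    e <- object@entries
    cat("MirnaCatalog with", length(e), "entries (",
        sum(mcols(e)$novelty), "novel )\n")
    if (length(e)) print(head(e, 5))
})

#' @rdname MirnaCatalog-class
#' @param object a \code{MirnaCatalog}.
#' @export
catalogEntries <- function(object) {
    stopifnot(is(object, "MirnaCatalog"))
    object@entries
}

#' @rdname MirnaCatalog-class
#' @export
novelEntries <- function(object) {
    e <- catalogEntries(object)
    e[mcols(e)$novelty]
}

setMethod("length", "MirnaCatalog", function(x) length(x@entries))

#' Group-level expression calls
#'
#' Boolean expressed matrix (miRNA x group) under the ">= minCpm in >= frac
#' of group samples" rule, with the derived group-specific and universal
#' sets and the high-expression (group mean cpm > 100) report.
#'
#' @slot expressed logical matrix, miRNA x group.
#' @slot specific logical matrix: expressed in exactly that one group.
#' @slot universal logical vector: expressed in every group.
#' @slot highTable DataFrame of group-specific entries with group mean cpm
#'   above the reporting threshold.
#' @slot params numeric, the minCpm/frac thresholds used.
#' @export
setClass("GroupExpression",
    representation(expressed = "matrix", specific = "matrix",
                   universal = "logical", highTable = "DataFrame",
                   params = "numeric"))

setValidity("GroupExpression", function(object) {
    if (!identical(dim(object@expressed), dim(object@specific)))
        return("expressed and specific must share dimensions")
    if (length(object@universal) != nrow(object@expressed))
        return("universal must have one value per miRNA")
    if (any(rowSums(object@specific) > 1))
        return("group-specific sets must be pairwise disjoint")
    TRUE
})

setMethod("show", "GroupExpression", function(object) {
    cat("GroupExpression:", nrow(object@expressed), "miRNAs x",
        ncol(object@expressed), "groups |",
        sum(object@universal), "universal |",
        sum(object@specific), "group-specific\n")
})

#' @rdname GroupExpression-class
#' @param object a \code{GroupExpression}.
#' @export
expressedMatrix <- function(object) object@expressed

#' @rdname GroupExpression-class
#' @export
specificMatrix <- function(object) object@specific

#' @rdname GroupExpression-class
#' @export
universalSet <- function(object)
    rownames(object@expressed)[object@universal]

#' @rdname GroupExpression-class
#' @export
highExpressionTable <- function(object) object@highTable

#' Common negative binomial dispersion estimate
#'
#' @slot common the common dispersion phi (variance = mu + phi mu^2).
#' @slot logLik conditional log-likelihood at the optimum.
#' @export
setClass("DispersionEstimate",
    representation(common = "numeric", logLik = "numeric"))

setMethod("show", "DispersionEstimate", function(object) {
    cat("DispersionEstimate: common phi =", signif(object@common, 4), "\n")
})

#' @rdname DispersionEstimate-class
#' @param object a \code{DispersionEstimate}.
#' @export
commonDispersion <- function(object) object@common
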