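## Synthetic inputs: toy genomes, planted hairpin loci, biogenesis-shaped
## read stacks and NB count matrices. Everything is seeded so downstream
## stages can be tested offline and reproducibly.

#' Generate a toy reference genome
#'
#' Uniform-composition random chromosomes (GC ~ 0.5). Chromosome names
#' default to chr1..chrN; a trailing "Unplaced" pseudo-chromosome can be
#' requested to mimic pooled unplaced scaffolds.
#'
#' @param nChroms number of chromosomes (>= 1).
#' @param lengths integer vector of chromosome lengths (recycled to
#'   \code{nChroms}); all must be positive.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @param names chromosome names; default chr1..chrN.
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
makeToyGenome <- function(nChroms, lengths, seed = 1L, names = NULL) {
    .assertScalarCount(nChroms, "nChroms")
    lengths <- rep_len(as.integer(lengths), nChroms)
    if (any(is.na(lengths)) || any(lengths <= 0))
        stop("chromosome lengths must be positive", call. = FALSE)
    if (is.null(names)) names <- paste0("chr", seq_len(nChroms))
    withSeed(seed, {
        seqs <- vapply(lengths, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), character(1))
    })
    genome <- DNAStringSet(seqs)
    names(genome) <- names
    genome
}

# Geometry of one planted hairpin in hairpin-relative 1-based coordinates.
# Perfect inverted repeat stem of armLen = matureLen + 2 with a loop; the
# mature/star duplex carries the canonical Dicer 2-nt 3' overhangs:
# star = [H + 3 - matureEnd, H + 3 - matureStart] under pairing i <-> H+1-i.
.hairpinGeometry <- function(matureLen, loopLen) {
    armLen <- matureLen + 2L
    H <- 2L * armLen + loopLen
    arm5 <- c(3L, 2L + matureLen)
    arm3 <- c(H + 3L - arm5[2], H + 3L - arm5[1])
    loop <- c(armLen + 1L, armLen + loopLen)
    list(H = H, armLen = armLen, arm5 = arm5, arm3 = arm3, loop = loop)
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.revComp <- function(x) as.character(reverseComplement(DNAString(x)))

#' Plant miRNA hairpin loci into a genome
#'
#' Writes inverted-repeat hairpins (perfect mature/star duplexes with 2-nt
#' 3' overhangs, up to \code{armIdentity}) into the genome sequence. A
#' \code{clusterFraction} of the loci is chained within 3000 nt of a
#' neighbour (genomic miRNA clusters); the rest are separated by at least
#' \code{minGap}. Strands and mature arms (5p/3p) are assigned ~50/50.
#'
#' @param genome a DNAStringSet from \code{\link{makeToyGenome}}; modified
#'   copies of its sequences are returned alongside the loci.
#' @param nLoci number of loci to plant.
#' @param clusterFraction fraction of loci placed within 3000 nt of a
#'   neighbouring locus.
#' @param minGap minimum gap (nt) between non-clustered loci.
#' @param seed integer seed.
#' @param matureLen,loopLen mature arm and loop lengths (nt).
#' @param armIdentity fraction of star bases complementary to the mature
#'   (1 = perfect duplex).
#' @return list with elements \code{genome} (sequences with hairpins
#'   written in) and \code{loci} (a GRanges of hairpins with mcols
#'   \code{mature}, \code{star}, \code{loop} (genomic IRanges),
#'   \code{matureArm}, \code{armIdentity}).
#' @export
plantMirnaLoci <- function(genome, nLoci, clusterFraction = 0, minGap = 5000L,
                           seed = 1L, matureLen = 22L, loopLen = 15L,
                           armIdentity = 1) {
    stopifnot(is(genome, "DNAStringSet"))
    if (nLoci == 0)
        return(list(genome = genome, loci = .emptyLoci()))
    if (matureLen < 19 || matureLen > 25)
        stop("matureLen must be 19-25 nt", call. = FALSE)
    geo <- .hairpinGeometry(as.integer(matureLen), as.integer(loopLen))
    H <- geo$H
    chromLens <- width(genome)
    nClustered <- round(clusterFraction * nLoci)
    if (nClustered == 1L) nClustered <- 2L  # a cluster needs a neighbour
    nClustered <- min(nClustered, nLoci)

    withSeed(seed, {
        # sequential placement: clustered loci first (chained with small
        # gaps on one chromosome), then isolated loci spread minGap apart
        gaps <- c(if (nClustered > 0) c(200L, sample(200:2500,
                      max(0, nClustered - 1), replace = TRUE)),
                  rep(as.integer(minGap), nLoci - nClustered))
        chrom <- integer(nLoci); startPos <- integer(nLoci)
        cur <- 1L; pos <- 1L
        for (i in seq_len(nLoci)) {
            pos <- pos + gaps[i]
            clustered <- i <= nClustered
            if (pos + H - 1L > chromLens[cur]) {
                if (clustered && i > 1L)
                    stop("insufficient genome space for clustered loci",
                         call. = FALSE)
                cur <- cur + 1L; pos <- 1L + gaps[i]
                if (cur > length(genome) || pos + H - 1L > chromLens[cur])
                    stop("insufficient genome space for ", nLoci, " loci",
                         call. = FALSE)
            }
            chrom[i] <- cur; startPos[i] <- pos
            pos <- pos + H - 1L
        }
        strands <- sample(c("+", "-"), nLoci, replace = TRUE)
        arms <- sample(c("5p", "3p"), nLoci, replace = TRUE)

        seqs <- as.character(genome)
        mat <- star <- loop <- matrix(0L, nLoci, 2)
        for (i in seq_len(nLoci)) {
            arm5seq <- .randSeq(geo$armLen)
            hp <- paste0(arm5seq, .randSeq(loopLen), .revComp(arm5seq))
            if (armIdentity < 1) {
                nMut <- round((1 - armIdentity) * matureLen)
                if (nMut > 0) {
                    idx <- sample(seq(geo$arm3[1], geo$arm3[2]), nMut)
                    s <- strsplit(hp, "")[[1]]
                    for (j in idx)
                        s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
                    hp <- paste(s, collapse = "")
                }
            }
            mRel <- if (arms[i] == "5p") geo$arm5 else geo$arm3
            sRel <- if (arms[i] == "5p") geo$arm3 else geo$arm5
            g0 <- startPos[i]
            rel2gen <- function(r) {
                if (strands[i] == "+") c(g0 + r[1] - 1L, g0 + r[2] - 1L)
                else c(g0 + H - r[2], g0 + H - r[1])
            }
            mat[i, ] <- rel2gen(mRel)
            star[i, ] <- rel2gen(sRel)
            loop[i, ] <- rel2gen(geo$loop)
            written <- if (strands[i] == "+") hp else .revComp(hp)
            substr(seqs[chrom[i]], g0, g0 + H - 1L) <- written
        }
    })
    out <- DNAStringSet(seqs)
    names(out) <- names(genome)
    loci <- GRanges(names(genome)[chrom],
                    IRanges(startPos, startPos + H - 1L),
                    strand = strands)
    mcols(loci)$mature <- IRanges(mat[, 1], mat[, 2])
    mcols(loci)$star <- IRanges(star[, 1], star[, 2])
    mcols(loci)$loop <- IRanges(loop[, 1], loop[, 2])
    mcols(loci)$matureArm <- arms
    mcols(loci)$armIdentity <- armIdentity
    list(genome = out, loci = loci)
}

.emptyLoci <- function() {
    g <- GRanges()
    mcols(g)$mature <- IRanges()
    mcols(g)$star <- IRanges()
    mcols(g)$loop <- IRanges()
    mcols(g)$matureArm <- character(0)
    mcols(g)$armIdentity <- numeric(0)
    g
}

#' Default background fragment length mixture
#'
#' Two peaks as observed in equine serum small RNA libraries: a dominant
#' 30-32 nt (piRNA-sized) peak and a smaller 22-23 nt (mature miRNA-sized)
#' peak; the remainder is uniform over the other lengths in
#' \code{range}. Fractions are configurable, not asserted, since only serum
#' mixtures are characterised.
#'
#' @param piFraction fraction of fragments 30-32 nt.
#' @param mirFraction fraction of fragments 22-23 nt.
#' @param range overall fragment length range.
#' @return a list consumed by \code{\link{simulateReadStacks}}.
#' @export
backgroundLengthSpec <- function(piFraction = 0.78, mirFraction = 0.04,
                                 range = c(18L, 35L)) {
    list(piFraction = piFraction, mirFraction = mirFraction,
         range = as.integer(range))
}

.sampleBackgroundLengths <- function(n, spec) {
    other <- setdiff(seq(spec$range[1], spec$range[2]), c(22:23, 30:32))
    cls <- sample(3L, n, replace = TRUE,
                  prob = c(spec$piFraction, spec$mirFraction,
                           max(0, 1 - spec$piFraction - spec$mirFraction)))
    len <- integer(n)
    len[cls == 1L] <- sample(30:32, sum(cls == 1L), replace = TRUE)
    len[cls == 2L] <- sample(22:23, sum(cls == 2L), replace = TRUE)
    len[cls == 3L] <- sample(other, sum(cls == 3L), replace = TRUE)
    len
}

.extractSeq <- function(genome, chrom, start, end, strand) {
    s <- as.character(subseq(genome[[chrom]], start, end))
    if (strand == "-") s <- .revComp(s)
    s
}

#' Simulate one sample of aligned, collapsed small RNA tags
#'
#' For each planted locus, \code{depth} reads are multinomially split over
#' mature arm, star arm, loop and a uniform remainder per the
#' \link{StackProfile}; mature/star 5' ends are jittered with the profile's
#' sd, and a \code{tailAuFraction} of reads carry 1-3 untemplated 3' A/U
#' additions (recorded in the \code{tail} column so that the genomic
#' interval still matches the templated sequence). Background fragments are
#' drawn from the two-peak length mixture at uniform genomic positions; a
#' configurable fraction of background tags is marked as heavy multimappers
#' (nHits > 5).
#'
#' @param genome DNAStringSet (with loci planted).
#' @param loci GRanges from \code{\link{plantMirnaLoci}} (may be empty).
#' @param profile a \link{StackProfile}.
#' @param nBackground number of background fragments.
#' @param background length mixture from \code{\link{backgroundLengthSpec}}.
#' @param multiHitFraction fraction of background tags with nHits in 6-50.
#' @param seed integer seed.
#' @return collapsed tags: a GRanges with mcols \code{seq}, \code{count},
#'   \code{nHits}, \code{tail}; \code{sum(count)} equals
#'   \code{sum(depth) + nBackground}.
#' @export
simulateReadStacks <- function(genome, loci, profile = StackProfile(),
                               nBackground = 0L,
                               background = backgroundLengthSpec(),
                               multiHitFraction = 0.1, seed = 1L) {
    stopifnot(is(genome, "DNAStringSet"), is(profile, "StackProfile"))
    validObject(profile)
    chromLens <- setNames(width(genome), names(genome))
    reads <- list()
    withSeed(seed, {
        for (i in seq_along(loci)) {
            lc <- loci[i]
            chrom <- as.character(seqnames(lc))
            str <- as.character(strand(lc))
            m <- mcols(loci)$mature[i]; st <- mcols(loci)$star[i]
            lp <- mcols(loci)$loop[i]
            p <- c(profile@matureFraction, profile@starFraction,
                   profile@loopFraction)
            split <- as.vector(rmultinom(1, profile@depth, c(p, 1 - sum(p))))
            mk <- function(n, anchor) {
                if (n == 0) return(NULL)
                jit <- round(rnorm(n, 0, profile@fivePrimeJitterSd))
                w <- width(anchor)
                if (str == "+") s0 <- start(anchor) + jit
                else s0 <- start(anchor) - jit  # jitter moves the 5' end
                data.frame(chrom = chrom, start = s0, end = s0 + w - 1L,
                           strand = str)
            }
            loopReads <- if (split[3] > 0)
                data.frame(chrom = chrom,
                           start = rep(start(lp), split[3]),
                           end = rep(end(lp), split[3]), strand = str)
                else NULL
            scatter <- if (split[4] > 0) {
                s0 <- sample(seq(start(lc), max(start(lc), end(lc) - 21L)),
                             split[4], replace = TRUE)
                data.frame(chrom = chrom, start = s0,
                           end = pmin(s0 + 21L, end(lc)), strand = str)
            } else NULL
            reads[[length(reads) + 1L]] <-
                rbind(mk(split[1], m), mk(split[2], st), loopReads, scatter)
        }
        locusReads <- do.call(rbind, reads)
        if (!is.null(locusReads)) {
            locusReads$start <- pmax(1L, locusReads$start)
            locusReads$end <- pmin(locusReads$end,
                                   chromLens[locusReads$chrom])
            locusReads$nHits <- 1L
            nt <- nrow(locusReads)
            tailed <- runif(nt) < profile@tailAuFraction
            locusReads$tail <- vapply(seq_len(nt), function(k)
                if (tailed[k]) paste(sample(c("A", "T"), sample(1:3, 1),
                    replace = TRUE), collapse = "") else "", character(1))
        }
        bg <- NULL
        if (nBackground > 0) {
            len <- .sampleBackgroundLengths(nBackground, background)
            ci <- sample(length(genome), nBackground, replace = TRUE,
                         prob = chromLens)
            s0 <- floor(runif(nBackground) *
                        pmax(1, chromLens[ci] - len + 1)) + 1L
            bg <- data.frame(chrom = names(genome)[ci], start = s0,
                             end = s0 + len - 1L,
                             strand = sample(c("+", "-"), nBackground,
                                             replace = TRUE))
            bg$nHits <- ifelse(runif(nBackground) < multiHitFraction,
                               sample(6:50, nBackground, replace = TRUE),
                               sample(1:5, nBackground, replace = TRUE,
                                      prob = c(0.7, rep(0.075, 4))))
            bg$tail <- ""
        }
        all <- rbind(locusReads, bg)
        if (!is.null(all) && nrow(all) > 0)
            all$seq <- vapply(seq_len(nrow(all)), function(k)
                .extractSeq(genome, all$chrom[k], all$start[k], all$end[k],
                            all$strand[k]), character(1))
    })
    if (is.null(all) || nrow(all) == 0) return(.emptyTags())
    raw <- GRanges(all$chrom, IRanges(all$start, all$end),
                   strand = all$strand)
    mcols(raw)$seq <- all$seq
    mcols(raw)$count <- 1L
    mcols(raw)$nHits <- all$nHits
    mcols(raw)$tail <- all$tail
    collapseReads(raw)
}

.emptyTags <- function() {
    g <- GRanges()
    mcols(g)$seq <- character(0)
    mcols(g)$count <- integer(0)
    mcols(g)$nHits <- integer(0)
    mcols(g)$tail <- character(0)
    g
}

#' Simulate a miRNA x sample count matrix with planted effects
#'
#' Counts are negative binomial around cpm-scale expected expression times
#' library size (Poisson when dispersion is 0). Planted log2 fold changes
#' multiply the mean in the designated group's samples; a composition-bias
#' fraction of miRNAs can be inflated in designated samples to exercise TMM
#' normalization. Sample metadata (tissue, breed, sex, age, absorbance414)
#' is generated alongside.
#'
#' @param config a \link{CountSimConfig}.
#' @param mirnaIds optional row ids (default mir-1..n).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts}, rowData \code{baseMeanCpm}, and full colData metadata.
#' @export
simulateCounts <- function(config, mirnaIds = NULL) {
    stopifnot(is(config, "CountSimConfig"))
    validObject(config)
    n <- config@nMirnas
    gs <- config@groupSizes
    nS <- sum(gs)
    group <- rep(names(gs), gs)
    if (is.null(mirnaIds)) mirnaIds <- paste0("mir-", seq_len(n))
    withSeed(config@seed, {
        # log-normal relative abundances, normalized to proportions
        rel <- exp(rnorm(n, mean = log(20), sd = 1.6))
        rel <- rel / sum(rel)
        libSize <- round(runif(nS, config@libSizeRange[1],
                               config@libSizeRange[2]))
        mu <- outer(rel, libSize)
        if (nrow(config@effects)) {
            for (k in seq_len(nrow(config@effects))) {
                i <- config@effects$mirna[k]
                if (is.character(i)) i <- match(i, mirnaIds)
                cols <- which(group == config@effects$group[k])
                mu[i, cols] <- mu[i, cols] * 2^config@effects$log2FC[k]
            }
        }
        if (config@compositionFraction > 0 &&
            length(config@compositionSamples)) {
            nBias <- round(config@compositionFraction * n)
            biasRows <- seq_len(nBias)
            mu[biasRows, config@compositionSamples] <-
                mu[biasRows, config@compositionSamples] *
                config@compositionFactor
        }
        counts <- matrix(0L, n, nS)
        if (config@dispersion == 0) {
            counts[] <- rpois(n * nS, as.vector(mu))
        } else {
            counts[] <- rnbinom(n * nS, size = 1 / config@dispersion,
                                mu = as.vector(mu))
        }
        meta <- DataFrame(sample = paste0("s", seq_len(nS)),
                          tissue = if (config@groupVar == "tissue") group
                                   else "serum",
                          breed = if (config@groupVar == "breed") group
                                  else "Warmblood",
                          sex = sample(c("M", "F"), nS, replace = TRUE),
                          age = sample(5:25, nS, replace = TRUE),
                          absorbance414 = round(runif(nS, 0.1, 1.5), 3),
                          libSize = libSize)
    })
    dimnames(counts) <- list(mirnaIds, meta$sample)
    SummarizedExperiment(assays = list(counts = counts),
                         colData = meta,
                         rowData = DataFrame(baseMeanCpm = rel * 1e6))
}
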