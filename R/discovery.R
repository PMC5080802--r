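## Hairpin candidate excision, biogenesis-criteria evaluation, log-odds
## scoring and permutation signal-to-noise calibration.

# vectorized strand-aware sequence extraction
.extractSeqs <- function(genome, chrom, start, end, strand) {
    out <- character(length(chrom))
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        ss <- extractAt(genome[[ch]], IRanges(start[i], end[i]))
        neg <- strand[i] == "-"
        if (any(neg)) ss[neg] <- reverseComplement(ss[neg])
        out[i] <- as.character(ss)
    }
    out
}

# genomic -> hairpin-relative coordinates (1-based, 5'->3' on the hairpin)
.toRelative <- function(gStart, gEnd, hStart, hEnd, strand) {
    if (strand == "+") c(gStart - hStart + 1L, gEnd - hStart + 1L)
    else c(hEnd - gEnd + 1L, hEnd - gStart + 1L)
}

.fromRelative <- function(rel, hStart, hEnd, strand) {
    if (strand == "+") c(hStart + rel[1] - 1L, hStart + rel[2] - 1L)
    else c(hEnd - rel[2] + 1L, hEnd - rel[1] + 1L)
}

# Robust mature/star duplex geometry from a pairing table: keep partners on
# the majority side of the mature and on the dominant duplex diagonal
# (i + partner ~ constant; bulges shift it slightly), so stray single pairs
# at the mature edges cannot misplace the star arm.
.duplexGeometry <- function(pt, mRel, diagTol = 6L) {
    mPos <- seq(mRel[1], mRel[2])
    paired <- mPos[pt[mPos] > 0]
    if (!length(paired)) return(NULL)
    q <- pt[paired]
    outside <- q < mRel[1] | q > mRel[2]
    paired <- paired[outside]; q <- q[outside]
    if (!length(paired)) return(NULL)
    down <- q > mRel[2]
    side <- if (sum(down) >= sum(!down)) down else !down
    paired <- paired[side]; q <- q[side]
    d <- paired + q
    keep <- abs(d - median(d)) <= diagTol
    paired <- paired[keep]; q <- q[keep]
    if (!length(paired)) return(NULL)
    a <- min(paired); b <- max(paired)
    list(a = a, b = b, starRel = c(pt[b] + 2L, pt[a] + 2L),
         nPaired = length(paired))
}

.emptyCandidates <- function() {
    g <- GRanges()
    mcols(g)$sequence <- character(0)
    mcols(g)$structure <- character(0)
    mcols(g)$mfe <- numeric(0)
    mcols(g)$mature <- IRanges()
    mcols(g)$star <- IRanges()
    mcols(g)$loop <- IRanges()
    mcols(g)$stackCount <- integer(0)
    mcols(g)$truncated <- logical(0)
    mcols(g)$pairedFrac <- numeric(0)
    g
}

#' Excise and fold hairpin candidates around read stacks
#'
#' A read stack is a set of tags on one strand sharing a modal 5' position
#' with total count >= \code{minStackCount}. For each stack (processed in
#' decreasing count order, skipping stacks inside an already accepted
#' hairpin) the most abundant tag defines the putative mature miRNA; a
#' window of flanking sequence on both sides is excised and folded, the
#' star arm is placed at the duplex partner of the mature with the
#' canonical 2-nt 3' offset, and the loop between the arms is recorded.
#' Stacks whose mature bases are mostly unpaired (below
#' \code{minPairedFrac}) are discarded as non-hairpin.
#'
#' @param tags aligned tags (already length/multimap filtered).
#' @param genome DNAStringSet.
#' @param window flanking nt excised on each side of the mature.
#' @param minStackCount minimum summed count at the modal 5' position.
#' @param minPairedFrac minimum fraction of mature bases paired in the fold.
#' @return candidate GRanges (hairpin intervals) with mcols sequence,
#'   structure, mfe, mature/star/loop (genomic IRanges), stackCount,
#'   truncated, pairedFrac.
#' @export
exciseCandidates <- function(tags, genome, window = 70L,
                             minStackCount = 5L, minPairedFrac = 0.6) {
    .checkTags(tags)
    stopifnot(is(genome, "DNAStringSet"))
    if (!length(tags)) return(.emptyCandidates())
    chromLens <- setNames(width(genome), names(genome))
    chrom <- as.character(seqnames(tags))
    str <- as.character(strand(tags))
    fp <- ifelse(str == "+", start(tags), end(tags))
    key <- paste(chrom, str, fp, sep = "\r")
    totals <- tapply(mcols(tags)$count, key, sum)
    stacks <- names(totals)[totals >= minStackCount]
    if (!length(stacks)) return(.emptyCandidates())
    ord <- order(-totals[stacks], stacks)
    stacks <- stacks[ord]

    acc <- list()
    accHairpins <- GRanges()
    for (sk in stacks) {
        idx <- which(key == sk)
        cnt <- mcols(tags)$count[idx]
        # most abundant tag is the mature; ties to the shorter, leftmost
        best <- idx[order(-cnt, width(tags)[idx], start(tags)[idx])][1]
        mStart <- start(tags)[best]; mEnd <- end(tags)[best]
        ch <- chrom[best]; sd <- str[best]
        mGR <- GRanges(ch, IRanges(mStart, mEnd), strand = sd)
        if (length(accHairpins) && overlapsAny(mGR, accHairpins)) next
        hStart <- max(1L, mStart - window)
        hEnd <- min(chromLens[ch], mEnd + window)
        truncated <- (hStart != mStart - window) || (hEnd != mEnd + window)
        hpSeq <- .extractSeqs(genome, ch, hStart, hEnd, sd)
        fold <- foldHairpin(hpSeq)
        pt <- pairTable(fold$structure)
        mRel <- .toRelative(mStart, mEnd, hStart, hEnd, sd)
        geo <- .duplexGeometry(pt, mRel)
        if (is.null(geo)) next
        pairedFrac <- geo$nPaired / (mRel[2] - mRel[1] + 1L)
        if (pairedFrac < minPairedFrac) next
        starRel <- geo$starRel
        H <- nchar(hpSeq)
        if (starRel[1] > starRel[2] || starRel[1] < 1 || starRel[2] > H) next
        if (starRel[1] <= mRel[2] && starRel[2] >= mRel[1]) next
        loopRel <- if (starRel[1] > mRel[2])
            c(mRel[2] + 1L, starRel[1] - 1L)
        else c(starRel[2] + 1L, mRel[1] - 1L)
        if (loopRel[2] < loopRel[1])
            loopRel <- c(loopRel[1], loopRel[1] - 1L)  # zero-width
        sG <- .fromRelative(starRel, hStart, hEnd, sd)
        lG <- .fromRelative(loopRel, hStart, hEnd, sd)
        cand <- GRanges(ch, IRanges(hStart, hEnd), strand = sd)
        mcols(cand)$sequence <- hpSeq
        mcols(cand)$structure <- fold$structure
        mcols(cand)$mfe <- fold$mfe
        mcols(cand)$mature <- IRanges(mStart, mEnd)
        mcols(cand)$star <- IRanges(sG[1], sG[2])
        mcols(cand)$loop <- IRanges(min(lG), max(min(lG), max(lG)))
        mcols(cand)$stackCount <- as.integer(totals[sk])
        mcols(cand)$truncated <- truncated
        mcols(cand)$pairedFrac <- pairedFrac
        acc[[length(acc) + 1L]] <- cand
        accHairpins <- c(accHairpins, granges(cand))
    }
    if (!length(acc)) return(.emptyCandidates())
    out <- do.call(c, acc)
    sort(out, ignore.strand = TRUE)
}

# read-support summary shared by evaluate/score
.supportStats <- function(candidate, tags, tol = 2L) {
    support <- tags[overlapsAny(tags, candidate)]  # strand-aware
    m <- mcols(candidate)$mature
    st <- mcols(candidate)$star
    sd <- as.character(strand(candidate))
    inRange <- function(r) length(support) > 0 &
        start(support) >= start(r) - tol & end(support) <= end(r) + tol
    mature <- support[inRange(m)]
    star <- support[inRange(st)]
    fp <- function(x) if (as.character(strand(candidate)) == "+")
        start(x) else end(x)
    tp <- function(x) if (sd == "+") end(x) else start(x)
    agg <- function(pos, cnt) if (length(pos)) tapply(cnt, pos, sum)
           else numeric(0)
    m5 <- agg(fp(mature), mcols(mature)$count)
    m3 <- agg(tp(mature), mcols(mature)$count)
    list(support = support, mature = mature, star = star,
         totalCount = sum(mcols(support)$count),
         matureCount = sum(mcols(mature)$count),
         starCount = sum(mcols(star)$count),
         modal5 = if (length(m5)) max(m5) else 0,
         modal3 = if (length(m3)) max(m3) else 0)
}

#' Stringent biogenesis-criteria thresholds
#'
#' Numeric cutoffs for \code{\link{evaluateCandidate}}. The criteria
#' themselves (end heterogeneity, duplex overhangs, duplex/flanking MFE,
#' nucleotide and structural entropy, tailing, multimapping) follow the
#' high-stringency discovery convention; the numeric values are this
#' package's defaults and are all configurable.
#'
#' @param hMax maximum 5'/3' end heterogeneity (fraction of mature reads
#'   off the modal end).
#' @param mfeMax maximum (i.e. least negative) acceptable duplex energy;
#'   the pass rule additionally requires the duplex per-nucleotide energy
#'   density to beat the flanking density.
#' @param eMin minimum nucleotide Shannon entropy (bits).
#' @param sMax maximum structural complexity, log2 of the number of
#'   dot-bracket runs over the stem-loop core.
#' @param tailingRequired require a minimum A/U tailing fraction?
#' @param tMin minimum tailing fraction when required.
#' @param maxMultimap maximum genomic hits of any supporting read.
#' @return named list of thresholds.
#' @export
dentifyThresholds <- function(hMax = 0.33, mfeMax = -15, eMin = 1.5,
                              sMax = 4, tailingRequired = FALSE,
                              tMin = 0.05, maxMultimap = 4L) {
    list(hMax = hMax, mfeMax = mfeMax, eMin = eMin, sMax = sMax,
         tailingRequired = tailingRequired, tMin = tMin,
         maxMultimap = as.integer(maxMultimap))
}

#' Evaluate a hairpin candidate against ten biogenesis criteria
#'
#' Computes end heterogeneities, the Dicer 2-nt 3' duplex overhang check,
#' duplex and flanking energies, nucleotide and structural entropy, the
#' A/U tailing fraction and the multimap factor of the supporting reads,
#' and combines them into a single pass/fail call.
#'
#' @param candidate one row from \code{\link{exciseCandidates}}.
#' @param tags the sample's aligned tags.
#' @param thresholds from \code{\link{dentifyThresholds}}.
#' @return a one-row \link[S4Vectors]{DataFrame} with the ten criterion
#'   fields and \code{pass}.
#' @export
evaluateCandidate <- function(candidate, tags,
                              thresholds = dentifyThresholds()) {
    stopifnot(is(candidate, "GRanges"), length(candidate) == 1L)
    ss <- .supportStats(candidate, tags)
    if (ss$matureCount == 0)
        stop("no supporting reads on the mature arm", call. = FALSE)
    het5 <- 1 - ss$modal5 / ss$matureCount
    het3 <- 1 - ss$modal3 / ss$matureCount

    seq <- mcols(candidate)$sequence
    pt <- pairTable(mcols(candidate)$structure)
    sd <- as.character(strand(candidate))
    hS <- start(candidate); hE <- end(candidate)
    m <- mcols(candidate)$mature
    st <- mcols(candidate)$star
    lp <- mcols(candidate)$loop
    mRel <- .toRelative(start(m), end(m), hS, hE, sd)
    stRel <- .toRelative(start(st), end(st), hS, hE, sd)
    geo <- .duplexGeometry(pt, mRel)
    overhangOk <- !is.null(geo) &&
        geo$a == mRel[1] && geo$b == mRel[2] &&
        stRel[1] == pt[mRel[2]] + 2L && stRel[2] == pt[mRel[1]] + 2L

    inMature <- function(x) x >= mRel[1] & x <= mRel[2]
    duplexMfe <- .structureEnergy(seq, pt,
        keep = function(i, j) xor(inMature(i), inMature(j)))
    core <- range(c(mRel, stRel))
    flankingMfe <- .structureEnergy(seq, pt,
        keep = function(i, j) (i < core[1] | i > core[2]) &
                              (j < core[1] | j > core[2]))
    # per-nucleotide energy densities: the duplex must be more stably
    # paired than an equal stretch of flanking sequence
    duplexNt <- (mRel[2] - mRel[1] + 1L) + (stRel[2] - stRel[1] + 1L)
    flankNt <- nchar(seq) - (core[2] - core[1] + 1L)
    duplexDensity <- duplexMfe / max(duplexNt, 1L)
    flankDensity <- flankingMfe / max(flankNt, 1L)
    base <- table(factor(strsplit(chartr("T", "U", seq), "")[[1]],
                         levels = c("A", "C", "G", "U")))
    p <- base / sum(base); p <- p[p > 0]
    nucleotideEntropy <- -sum(p * log2(p))
    coreDb <- substr(mcols(candidate)$structure, core[1], core[2])
    structuralEntropy <- log2(length(rle(strsplit(coreDb, "")[[1]])$values))

    tail <- mcols(ss$mature)$tail
    if (is.null(tail)) tail <- rep("", length(ss$mature))
    auTail <- tail != "" & !grepl("[^ATU]", tail)
    tailingFraction <- sum(mcols(ss$mature)$count[auTail]) / ss$matureCount
    multimapFactor <- max(mcols(ss$support)$nHits)

    th <- thresholds
    pass <- het5 <= th$hMax && het3 <= th$hMax && overhangOk &&
        duplexMfe <= th$mfeMax && duplexDensity < flankDensity &&
        nucleotideEntropy >= th$eMin && structuralEntropy <= th$sMax &&
        (!th$tailingRequired || tailingFraction >= th$tMin) &&
        multimapFactor <= th$maxMultimap
    DataFrame(fivePrimeHeterogeneity = het5,
              threePrimeHeterogeneity = het3,
              overhangOk = overhangOk, duplexMfe = duplexMfe,
              flankingMfe = flankingMfe,
              nucleotideEntropy = nucleotideEntropy,
              structuralEntropy = structuralEntropy,
              tailingFraction = tailingFraction,
              multimapFactor = multimapFactor, pass = pass)
}

# dinucleotide chunk shuffle: permute consecutive 2-mers
.dinucShuffle <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    cuts <- seq(1L, n, by = 2L)
    chunks <- substring(seq, cuts, pmin(cuts + 1L, n))
    paste(sample(chunks), collapse = "")
}

#' Log-odds score of a hairpin candidate
#'
#' Four additive log2 likelihood-ratio terms against a uniform
#' fragmentation null: (i) read concentration on the mature arm, (ii) 5'
#' end consistency of the mature reads, (iii) star-arm support bonus, and
#' (iv) a structure term from the z-score of the hairpin energy against
#' dinucleotide-shuffled refolds; a fixed null offset of 10 centres clean
#' background stacks below the conventional score cutoff of 1. Adding
#' mature-arm reads at the modal 5' position never decreases the score.
#'
#' @param candidate one excised candidate.
#' @param tags the sample's aligned tags.
#' @param nShuffle number of shuffled refolds for the structure term.
#' @param seed seed for the shuffles (score is deterministic given it).
#' @return numeric score with attribute \code{terms} (the four components).
#' @export
scoreCandidate <- function(candidate, tags, nShuffle = 20L, seed = 1L) {
    ss <- .supportStats(candidate, tags)
    mW <- width(mcols(candidate)$mature)
    hW <- width(candidate)
    termPosition <- log2(((ss$matureCount + 1) / (ss$totalCount + 2)) /
                         (mW / hW))
    termConsistency <- log2(((ss$modal5 + 1) / (ss$matureCount + 2)) * mW)
    termStar <- min(log2(1 + ss$starCount), 4)
    seq <- mcols(candidate)$sequence
    mfes <- withSeed(seed, vapply(seq_len(nShuffle), function(k)
        foldHairpin(.dinucShuffle(seq))$mfe, numeric(1)))
    z <- (mcols(candidate)$mfe - mean(mfes)) / max(sd(mfes), 0.5)
    termStructure <- min(max(-z, 0), 8)
    terms <- c(position = termPosition, consistency = termConsistency,
               star = termStar, structure = termStructure)
    structure(sum(terms) - 10, terms = terms)
}

#' Call miRNAs in one sample
#'
#' Excises candidates and retains them either by log-odds score
#' (\code{mode = "deep"}: score >= \code{scoreCutoff}) or by the ten
#' stringent biogenesis criteria (\code{mode = "dentify"}: pass).
#'
#' @param tags the sample's aligned tags.
#' @param genome DNAStringSet.
#' @param mode "deep" (score-based) or "dentify" (criteria-based).
#' @param scoreCutoff minimum score for deep-style calls.
#' @param sampleId identifier recorded with each call.
#' @param thresholds criteria thresholds for dentify mode.
#' @param window,minStackCount passed to \code{\link{exciseCandidates}}.
#' @param nShuffle,seed passed to \code{\link{scoreCandidate}}.
#' @return calls as a GRanges over the mature intervals with mcols sample,
#'   tool, score, pass, hairpin (IRanges), matureSeq.
#' @export
callMirnas <- function(tags, genome, mode = c("deep", "dentify"),
                       scoreCutoff = 1, sampleId = "s1",
                       thresholds = dentifyThresholds(), window = 70L,
                       minStackCount = 5L, nShuffle = 20L, seed = 1L) {
    mode <- match.arg(mode)
    cands <- exciseCandidates(tags, genome, window = window,
                              minStackCount = minStackCount)
    if (!length(cands)) return(.emptyCalls())
    scores <- numeric(length(cands))
    pass <- logical(length(cands))
    for (i in seq_along(cands)) {
        scores[i] <- scoreCandidate(cands[i], tags, nShuffle = nShuffle,
                                    seed = seed)
        pass[i] <- if (mode == "dentify")
            evaluateCandidate(cands[i], tags, thresholds)$pass else NA
    }
    keep <- if (mode == "deep") scores >= scoreCutoff else pass
    keep[is.na(keep)] <- FALSE
    cands <- cands[keep]
    if (!length(cands)) return(.emptyCalls())
    m <- mcols(cands)$mature
    calls <- GRanges(seqnames(cands), m, strand = strand(cands))
    mcols(calls)$sample <- sampleId
    mcols(calls)$tool <- mode
    mcols(calls)$score <- scores[keep]
    mcols(calls)$pass <- pass[keep]
    mcols(calls)$hairpin <- ranges(cands)
    mcols(calls)$matureSeq <- .extractSeqs(genome,
        as.character(seqnames(cands)), start(m), end(m),
        as.character(strand(cands)))
    calls
}

.emptyCalls <- function() {
    g <- GRanges()
    mcols(g)$sample <- character(0)
    mcols(g)$tool <- character(0)
    mcols(g)$score <- numeric(0)
    mcols(g)$pass <- logical(0)
    mcols(g)$hairpin <- IRanges()
    mcols(g)$matureSeq <- character(0)
    g
}

#' Uniformly permute tag positions
#'
#' Each tag keeps its chromosome, length, strand, count and hit count but
#' is moved to a uniform random position; sequences are re-extracted so the
#' permuted tags remain well formed. Untemplated tails are dropped.
#'
#' @param tags aligned tags.
#' @param genome DNAStringSet.
#' @param seed integer seed.
#' @return permuted tags.
#' @export
permuteTags <- function(tags, genome, seed = 1L) {
    .checkTags(tags)
    chromLens <- setNames(width(genome), names(genome))
    ch <- as.character(seqnames(tags))
    w <- width(tags)
    withSeed(seed, {
        s0 <- floor(runif(length(tags)) * pmax(1, chromLens[ch] - w + 1)) + 1L
    })
    out <- GRanges(ch, IRanges(s0, s0 + w - 1L), strand = strand(tags))
    mcols(out)$seq <- .extractSeqs(genome, ch, s0, s0 + w - 1L,
                                   as.character(strand(tags)))
    mcols(out)$count <- mcols(tags)$count
    mcols(out)$nHits <- mcols(tags)$nHits
    mcols(out)$tail <- ""
    out
}

#' Permutation signal-to-noise profile over score cutoffs
#'
#' Counts real candidate calls at each integer score cutoff and compares
#' them with \code{nPerm} position-permuted re-runs of excision and
#' scoring. SNR is real count over mean permuted count (NaN where both are
#' zero). Deterministic given the seed.
#'
#' @param tags the sample's aligned tags.
#' @param genome DNAStringSet.
#' @param nPerm number of permutation rounds (default 100).
#' @param cutoffs integer score cutoffs (default -10..10).
#' @param seed integer seed driving the permutations and score shuffles.
#' @param window,minStackCount excision parameters.
#' @param nShuffle shuffled refolds per candidate score.
#' @return an \link{SNRProfile}.
#' @export
signalToNoise <- function(tags, genome, nPerm = 100L, cutoffs = -10:10,
                          seed = 1L, window = 70L, minStackCount = 5L,
                          nShuffle = 20L) {
    stopifnot(nPerm >= 1)
    cutoffs <- as.integer(cutoffs)
    countAt <- function(tg) {
        cands <- exciseCandidates(tg, genome, window = window,
                                  minStackCount = minStackCount)
        sc <- vapply(seq_along(cands), function(i)
            as.numeric(scoreCandidate(cands[i], tg, nShuffle = nShuffle,
                                      seed = seed)), numeric(1))
        vapply(cutoffs, function(ct) sum(sc >= ct), integer(1))
    }
    real <- countAt(tags)
    perm <- matrix(0L, nPerm, length(cutoffs))
    for (p in seq_len(nPerm))
        perm[p, ] <- countAt(permuteTags(tags, genome, seed = seed + p))
    snr <- real / colMeans(perm)
    new("SNRProfile", cutoffs = cutoffs, realCounts = real,
        permCounts = perm, snr = as.numeric(snr))
}
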