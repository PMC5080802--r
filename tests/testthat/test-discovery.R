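cleanProfile <- function(depth = 50L)
    StackProfile(depth = depth, fivePrimeJitterSd = 0)

test_that("planted loci are excised with exact mature intervals", {
    fx <- fixtureStacks(nLoci = 2, nBackground = 0,
                        lengths = c(20000, 20000))
    cands <- exciseCandidates(fx$tags, fx$genome)
    expect_length(cands, 2)
    cm <- GRanges(seqnames(cands), mcols(cands)$mature,
                  strand = strand(cands))
    expect_setequal(grKey(cm), grKey(plantedMature(fx$loci)))
    # star and loop are disjoint from the mature, inside the hairpin
    for (i in seq_along(cands)) {
        m <- mcols(cands)$mature[i]; st <- mcols(cands)$star[i]
        expect_equal(width(st), width(m))
        expect_true(end(st) < start(m) || start(st) > end(m))
    }
})

test_that("sparse uniform tags produce no candidates", {
    gen <- makeToyGenome(1, 30000, seed = 31)
    set.seed(32)
    starts <- sample(29000L, 300)
    tags <- alignedTags("chr1", starts, starts + 21L, "+",
                        substring(as.character(gen[[1]]), starts,
                                  starts + 21L))
    expect_length(exciseCandidates(tags, gen, minStackCount = 5), 0)
})

test_that("candidate evaluation reports the ten criteria faithfully", {
    fx <- fixtureStacks(nLoci = 3, nBackground = 0,
                        profile = StackProfile(matureFraction = 0.8,
                                               starFraction = 0.2,
                                               loopFraction = 0,
                                               fivePrimeJitterSd = 0),
                        lengths = c(30000, 10000))
    cands <- exciseCandidates(fx$tags, fx$genome)
    ev <- evaluateCandidate(cands[1], fx$tags)
    expect_true(ev$overhangOk)
    expect_equal(ev$fivePrimeHeterogeneity, 0)
    expect_lte(ev$duplexMfe, -30)
    expect_gte(ev$nucleotideEntropy, 1.5)
    expect_equal(ev$multimapFactor, 1)

    # a single heavy multimapper among the support forces a fail
    bad <- fx$tags
    m <- mcols(cands)$mature[1]
    onM <- which(start(bad) >= start(m) - 2 & end(bad) <= end(m) + 2 &
                 as.character(seqnames(bad)) ==
                 as.character(seqnames(cands[1])))
    mcols(bad)$nHits[onM[1]] <- 5L
    ev2 <- evaluateCandidate(cands[1], bad)
    expect_equal(ev2$multimapFactor, 5)
    expect_false(ev2$pass)

    expect_error(evaluateCandidate(cands[1], fx$tags[0]),
                 "supporting reads")
})

test_that("the score is the sum of its four documented terms", {
    # five-read worked fixture on one planted locus
    fx <- fixtureStacks(nLoci = 1, nBackground = 0, depth = 5L,
                        profile = StackProfile(depth = 5L,
                                               matureFraction = 0.6,
                                               starFraction = 0.4,
                                               loopFraction = 0,
                                               fivePrimeJitterSd = 0,
                                               tailAuFraction = 0),
                        lengths = c(20000, 5000))
    cand <- exciseCandidates(fx$tags, fx$genome, minStackCount = 2)
    expect_length(cand, 1)
    sc <- scoreCandidate(cand, fx$tags, nShuffle = 20, seed = 9)
    tm <- attr(sc, "terms")
    expect_equal(as.numeric(sc), sum(tm) - 10)

    # recompute the read-derived terms by hand
    m <- mcols(cand)$mature; st <- mcols(cand)$star
    onM <- start(fx$tags) >= start(m) - 2 & end(fx$tags) <= end(m) + 2
    onS <- start(fx$tags) >= start(st) - 2 & end(fx$tags) <= end(st) + 2
    cnt <- mcols(fx$tags)$count
    total <- sum(cnt); mc <- sum(cnt[onM]); stc <- sum(cnt[onS])
    expect_equal(unname(tm["position"]),
                 log2(((mc + 1) / (total + 2)) / (width(m) / width(cand))))
    expect_equal(unname(tm["star"]), min(log2(1 + stc), 4))
    expect_equal(unname(tm["consistency"]),
                 log2(((mc + 1) / (mc + 2)) * width(m)))
    expect_gte(unname(tm["structure"]), 0)
})

test_that("scores reward concentrated stacks and are monotone in support", {
    fx <- fixtureStacks(nLoci = 1, nBackground = 0,
                        profile = cleanProfile(),
                        lengths = c(20000, 5000))
    cand <- exciseCandidates(fx$tags, fx$genome)
    base <- as.numeric(scoreCandidate(cand, fx$tags, seed = 5))
    expect_gte(base, 1)

    # scattering the same reads uniformly over the hairpin lowers the score
    set.seed(33)
    n <- sum(mcols(fx$tags)$count)
    starts <- sample(seq(start(cand), end(cand) - 21L), n, replace = TRUE)
    scat <- alignedTags(as.character(seqnames(cand)), starts,
                        starts + 21L, as.character(strand(cand)),
                        vapply(starts, function(s) substring(
                            as.character(fx$genome[[
                                as.character(seqnames(cand))]]),
                            s, s + 21L), character(1)))
    expect_lt(as.numeric(scoreCandidate(cand, scat, seed = 5)), base)

    # adding mature-modal reads never decreases the score
    m <- mcols(cand)$mature
    extra <- alignedTags(as.character(seqnames(cand)), start(m), end(m),
                         as.character(strand(cand)),
                         mcols(fx$tags)$seq[which(
                             start(fx$tags) == start(m) &
                             end(fx$tags) == end(m))[1]], count = 25L)
    boosted <- collapseReads(c(fx$tags, extra))
    expect_gte(as.numeric(scoreCandidate(cand, boosted, seed = 5)), base)
})

test_that("deep calls recover planted loci; dentify is a stringent subset", {
    fx <- fixtureStacks(nLoci = 10, nBackground = 1000,
                        profile = cleanProfile(),
                        lengths = c(40000, 20000))
    deep <- callMirnas(fx$tags, fx$genome, "deep", sampleId = "s1")
    planted <- plantedMature(fx$loci)
    expect_equal(sum(grKey(planted) %in% grKey(deep)), 10)
    expect_length(callMirnas(fx$tags, fx$genome, "deep",
                             scoreCutoff = Inf), 0)
    dent <- callMirnas(fx$tags, fx$genome, "dentify", sampleId = "s1")
    expect_true(all(grKey(dent) %in% grKey(deep)))
    expect_true(all(mcols(dent)$tool == "dentify"))
})

test_that("position permutation preserves tag structure and is seeded", {
    fx <- fixtureStacks(nLoci = 2, nBackground = 500,
                        lengths = c(20000, 10000))
    p1 <- permuteTags(fx$tags, fx$genome, seed = 4)
    p2 <- permuteTags(fx$tags, fx$genome, seed = 4)
    expect_identical(as.data.frame(p1), as.data.frame(p2))
    expect_equal(width(p1), width(fx$tags))
    expect_equal(mcols(p1)$count, mcols(fx$tags)$count)
    expect_equal(as.character(seqnames(p1)),
                 as.character(seqnames(fx$tags)))
    expect_false(identical(start(p1), start(fx$tags)))
})

test_that("a single-round SNR equals the equivalent manual permutation", {
    gen <- makeToyGenome(1, 3000, seed = 41)
    tags <- simulateReadStacks(gen, plantMirnaLoci(gen, 0)$loci,
                               nBackground = 3000, seed = 42)
    tags <- filterTags(tags)
    prof <- signalToNoise(tags, gen, nPerm = 1, seed = 7)
    perm <- permuteTags(tags, gen, seed = 8)  # nPerm round p uses seed + p
    cands <- exciseCandidates(perm, gen)
    sc <- vapply(seq_along(cands), function(i)
        as.numeric(scoreCandidate(cands[i], perm, seed = 7)), numeric(1))
    manual <- vapply(-10:10, function(ct) sum(sc >= ct), integer(1))
    expect_equal(as.integer(prof@permCounts[1, ]), manual)
    expect_length(prof@snr, 21)
})

test_that("planted signal dominates the SNR at the score-1 cutoff", {
    fx <- fixtureStacks(nLoci = 8, nBackground = 1500,
                        profile = cleanProfile(),
                        lengths = c(30000, 10000))
    prof <- signalToNoise(fx$tags, fx$genome, nPerm = 5, seed = 3)
    tab <- snrTable(prof)
    s1 <- tab$snr[tab$cutoff == 1]
    sLow <- tab$snr[tab$cutoff == -10]
    expect_gte(tab$real[tab$cutoff == 1], 8)
    expect_true(is.nan(s1) || s1 > sLow || is.nan(sLow))
})
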