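test_that("the 2-nt merge rule applies at its boundaries", {
    two <- mkCalls(data.frame(chrom = "chr1", start = c(100, 98),
                              end = c(121, 121), strand = "+",
                              sample = c("s1", "s2")))
    expect_length(mergeCalls(two), 1)
    apart <- mkCalls(data.frame(chrom = "chr1", start = c(100, 97),
                                end = c(121, 121), strand = "+",
                                sample = c("s1", "s2")))
    expect_length(mergeCalls(apart), 2)
    opp <- mkCalls(data.frame(chrom = "chr1", start = c(100, 100),
                              end = c(121, 121), strand = c("+", "-"),
                              sample = c("s1", "s2")))
    expect_length(mergeCalls(opp), 2)
})

test_that("merging is a transitive closure, invariant to input order", {
    set.seed(51)
    for (rep in 1:25) {
        n <- sample(8:30, 1)
        anchors <- sample(seq(100, 5000, by = 60), 6)
        st <- sample(anchors, n, replace = TRUE) + sample(-2:2, n, TRUE)
        calls <- mkCalls(data.frame(chrom = "chr1", start = st,
                                    end = st + 21L +
                                        sample(-1:1, n, TRUE),
                                    strand = sample(c("+", "-"), n, TRUE),
                                    sample = paste0("s", sample(5, n,
                                                                TRUE))))
        g1 <- mergeCalls(calls)
        g2 <- mergeCalls(calls[sample(n)])
        key <- function(gr) sort(vapply(gr, function(g)
            paste(sort(grKey(g)), collapse = "|"), character(1)))
        expect_identical(key(g1), key(g2))
        # idempotence: representatives of closed groups never re-merge
        reps <- do.call(c, unname(lapply(as.list(g1),
                                         pickRepresentative)))
        expect_length(mergeCalls(reps), length(g1))
    }
})

test_that("representative selection prefers support, then score", {
    g <- mkCalls(data.frame(chrom = "chr1",
                            start = c(100, 100, 100, 100, 100, 102, 102),
                            end = c(121, 121, 121, 121, 121, 123, 123),
                            strand = "+",
                            sample = c("s1", "s2", "s3", "s4", "s5",
                                       "s6", "s7"),
                            score = 2))
    rep1 <- pickRepresentative(g)
    expect_equal(start(rep1), 100)
    expect_equal(mcols(rep1)$supportSamples, 7)

    tie <- mkCalls(data.frame(chrom = "chr1",
                              start = c(100, 100, 100, 102, 102, 102),
                              end = c(121, 121, 121, 123, 123, 123),
                              strand = "+",
                              sample = paste0("s", 1:6),
                              score = c(2, 2, 2, 4.1, 4.1, 2)))
    rep2 <- pickRepresentative(tie)
    expect_equal(start(rep2), 102)  # 3-3 tie broken by score 4.1
    expect_equal(mcols(rep2)$bestScore, 4.1)

    single <- mkCalls(data.frame(chrom = "chr1", start = 10, end = 31,
                                 strand = "+", sample = "s1"))
    expect_equal(grKey(pickRepresentative(single)), grKey(single))
})

test_that("the singleton filter counts distinct samples, not calls", {
    one <- mergeCalls(mkCalls(data.frame(chrom = "chr1", start = 100,
                                         end = 121, strand = "+",
                                         sample = "s1")))
    expect_length(filterSingletons(one), 0)
    sameSample <- mergeCalls(mkCalls(data.frame(chrom = "chr1",
                                                start = c(100, 101),
                                                end = c(121, 122),
                                                strand = "+",
                                                sample = c("s1", "s1"))))
    expect_length(filterSingletons(sameSample), 0)
    two <- mergeCalls(mkCalls(data.frame(chrom = "chr1",
                                         start = c(100, 101),
                                         end = c(121, 122),
                                         strand = "+",
                                         sample = c("s1", "s2"))))
    expect_length(filterSingletons(two), 1)
})

knownSet <- function() {
    k <- GRanges("chr1", IRanges(c(1000, 2000), c(1021, 2021)),
                 strand = "+")
    mcols(k)$id <- c("eca-mir-744", "eca-mir-486")
    k
}

groupsAt <- function(start, end, strand = "+") {
    filterSingletons(mergeCalls(mkCalls(data.frame(
        chrom = "chr1", start = c(start, start), end = c(end, end),
        strand = strand, sample = c("s1", "s2")))))
}

test_that("known-miRNA annotation distinguishes exact, shifted and antisense", {
    empty <- GenomicRanges::GRangesList()
    # exact same-strand match: known, not novel
    cat1 <- combineAndAnnotate(groupsAt(1000, 1021), empty, knownSet())
    e1 <- catalogEntries(cat1)
    expect_false(mcols(e1)$novelty)
    expect_equal(mcols(e1)$knownOverlap, "same-strand")
    expect_equal(mcols(e1)$id, "eca-mir-744")

    # two nucleotides shorter at one end: near-identical, still novel
    cat2 <- combineAndAnnotate(groupsAt(1000, 1019), empty, knownSet())
    e2 <- catalogEntries(cat2)
    expect_true(mcols(e2)$novelty)
    expect_equal(mcols(e2)$knownOverlap, "near-identical")
    expect_equal(mcols(e2)$knownPartner, "eca-mir-744")

    # exactly antisense to a known mature: novel, opposite-strand
    cat3 <- combineAndAnnotate(groupsAt(2000, 2021, strand = "-"), empty,
                               knownSet())
    e3 <- catalogEntries(cat3)
    expect_true(mcols(e3)$novelty)
    expect_equal(mcols(e3)$knownOverlap, "opposite-strand")

    # no overlap at all
    cat4 <- combineAndAnnotate(groupsAt(5000, 5021), empty, knownSet())
    expect_equal(mcols(catalogEntries(cat4))$knownOverlap, "none")
    expect_true(mcols(catalogEntries(cat4))$novelty)

    # an entry is never both known and novel
    for (cc in list(cat1, cat2, cat3, cat4)) {
        e <- catalogEntries(cc)
        expect_false(any(mcols(e)$novelty &
                         mcols(e)$knownOverlap == "same-strand"))
    }
})

test_that("cross-tool union keeps provenance without duplicating entries", {
    deep <- groupsAt(3000, 3021)
    dent <- filterSingletons(mergeCalls(mkCalls(data.frame(
        chrom = "chr1", start = c(3001, 3001), end = c(3022, 3022),
        strand = "+", sample = c("s1", "s3"), tool = "dentify"))))
    catal <- combineAndAnnotate(deep, dent, GRanges())
    e <- catalogEntries(catal)
    expect_length(e, 1)
    expect_equal(mcols(e)$tools, "deep,dentify")
})

test_that("cluster chaining respects the 3000-nt boundary", {
    mk <- function(starts) mkCatalog(data.frame(
        chrom = "chr1", start = starts + 20, end = starts + 41,
        strand = "+", id = paste0("m", seq_along(starts)),
        hpStart = starts, hpEnd = starts + 62))
    close <- findClusters(mk(c(1000, 4000)))      # 3000 apart
    expect_equal(nrow(close), 1)
    expect_equal(close$n, 2)
    far <- findClusters(mk(c(1000, 4001)))        # 3001 apart
    expect_equal(nrow(far), 0)
    expect_equal(nrow(findClusters(mk(1000))), 0)  # singletons never cluster
    chain <- findClusters(mk(c(1000, 3500, 6000, 20000)))
    expect_equal(chain$n, 3)                      # single-linkage chaining
})

test_that("chromosome summaries pool scaffolds and conserve counts", {
    catal <- mkCatalog(data.frame(
        chrom = c(rep("chr1", 5), rep("scaffold_x", 2)),
        start = 101:107 * 100, end = 101:107 * 100 + 21,
        strand = c("+", "+", "-", "+", "-", "+", "-"),
        id = paste0("m", 1:7),
        hpStart = 101:107 * 100 - 40, hpEnd = 101:107 * 100 + 61))
    cs <- chromosomeSummary(catal)
    expect_setequal(cs$chrom, c("chr1", "Unplaced"))
    expect_equal(cs$n[cs$chrom == "chr1"], 5)
    expect_equal(cs$n[cs$chrom == "Unplaced"], 2)
    expect_equal(sum(cs$n), length(catal))
    empty <- chromosomeSummary(mkCatalog(data.frame(
        chrom = character(0), start = integer(0), end = integer(0),
        strand = character(0), id = character(0), hpStart = integer(0),
        hpEnd = integer(0))))
    expect_equal(nrow(empty), 0)
})
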