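## Shared fixtures, all generated in code under fixed seeds.

fixtureStacks <- function(nLoci = 20, depth = 50L, nBackground = 3000,
                          genomeSeed = 7, locusSeed = 11, stackSeed = 21,
                          clusterFraction = 0, profile = NULL,
                          lengths = c(60000, 40000)) {
    gen <- makeToyGenome(length(lengths), lengths, seed = genomeSeed)
    pl <- plantMirnaLoci(gen, nLoci, clusterFraction = clusterFraction,
                         minGap = 2000, seed = locusSeed)
    if (is.null(profile)) profile <- StackProfile(depth = depth)
    tags <- simulateReadStacks(pl$genome, pl$loci, profile,
                               nBackground = nBackground, seed = stackSeed)
    list(genome = pl$genome, loci = pl$loci, tags = filterTags(tags),
         rawTags = tags)
}

plantedMature <- function(loci) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(loci),
                           S4Vectors::mcols(loci)$mature,
                           strand = GenomicRanges::strand(loci))
}

grKey <- function(g) paste(GenomicRanges::seqnames(g),
                           IRanges::start(g), IRanges::end(g),
                           GenomicRanges::strand(g))

# minimal call constructor for catalog tests
mkCalls <- function(df) {
    g <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = df$strand)
    S4Vectors::mcols(g)$sample <- df$sample
    S4Vectors::mcols(g)$tool <- if (!is.null(df$tool)) df$tool else "deep"
    S4Vectors::mcols(g)$score <- if (!is.null(df$score)) df$score else 1
    S4Vectors::mcols(g)$pass <- NA
    S4Vectors::mcols(g)$hairpin <- IRanges::IRanges(df$start - 40L,
                                                    df$end + 40L)
    S4Vectors::mcols(g)$matureSeq <- strrep("A", df$end - df$start + 1L)
    g
}

# catalog built directly from entry coordinates (for expression tests)
mkCatalog <- function(df) {
    g <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = df$strand)
    S4Vectors::mcols(g)$id <- df$id
    S4Vectors::mcols(g)$hairpin <- IRanges::IRanges(df$hpStart, df$hpEnd)
    S4Vectors::mcols(g)$supportSamples <- rep(2L, length(g))
    S4Vectors::mcols(g)$bestScore <- rep(1, length(g))
    S4Vectors::mcols(g)$tools <- rep("deep", length(g))
    S4Vectors::mcols(g)$novelty <- rep(TRUE, length(g))
    S4Vectors::mcols(g)$knownOverlap <- rep("none", length(g))
    S4Vectors::mcols(g)$knownPartner <- rep(NA_character_, length(g))
    new("MirnaCatalog", entries = g)
}
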