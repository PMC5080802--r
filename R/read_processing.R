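## Post-alignment tag hygiene and descriptive read-context statistics.
## Tags are GRanges with mcols seq, count, nHits (and optionally tail).

.checkTags <- function(tags) {
    stopifnot(is(tags, "GRanges"))
    need <- c("seq", "count", "nHits")
    if (!all(need %in% colnames(mcols(tags))))
        stop("tags must carry mcols: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (length(tags)) {
        if (any(width(tags) != nchar(mcols(tags)$seq)))
            stop("tag width must equal sequence length", call. = FALSE)
        if (any(mcols(tags)$count < 1) || any(mcols(tags)$nHits < 1))
            stop("tag count and nHits must be >= 1", call. = FALSE)
    }
    invisible(tags)
}

#' Construct an aligned-tag GRanges
#'
#' One row per collapsed unique read: genomic interval, strand, sequence,
#' collapsed multiplicity and number of genomic placements.
#'
#' @param chrom,start,end,strand interval columns (1-based closed).
#' @param seq templated read sequence (width must equal end - start + 1).
#' @param count collapsed read multiplicity (>= 1).
#' @param nHits genomic placements of the read (>= 1).
#' @param tail untemplated 3' addition, "" if none.
#' @return a GRanges with mcols seq, count, nHits, tail.
#' @export
alignedTags <- function(chrom, start, end, strand = "+", seq,
                        count = 1L, nHits = 1L, tail = "") {
    g <- GRanges(chrom, IRanges(start, end), strand = strand)
    mcols(g)$seq <- seq
    mcols(g)$count <- rep_len(as.integer(count), length(g))
    mcols(g)$nHits <- rep_len(as.integer(nHits), length(g))
    mcols(g)$tail <- rep_len(tail, length(g))
    .checkTags(g)
}

#' Filter tags by length and multimapping
#'
#' Retains tags no longer than \code{maxLen} nt (long fragments are likely
#' degraded mRNA) and placed at no more than \code{maxHits} genomic
#' positions. Order is preserved; boundary values are kept.
#'
#' @param tags an aligned-tag GRanges.
#' @param maxLen maximum tag length in nt (default 30).
#' @param maxHits maximum number of genomic hits (default 5).
#' @return the retained tags.
#' @export
filterTags <- function(tags, maxLen = 30L, maxHits = 5L) {
    .checkTags(tags)
    if (maxLen < 1) stop("maxLen must be >= 1", call. = FALSE)
    if (maxHits < 1) stop("maxHits must be >= 1", call. = FALSE)
    tags[width(tags) <= maxLen & mcols(tags)$nHits <= maxHits]
}

#' Collapse placed reads with identical sequence and placement
#'
#' One tag per (placement, sequence, tail) with count equal to the
#' multiplicity; total counts are conserved and the operation is idempotent.
#'
#' @param reads a GRanges with mcols seq, count, nHits (tail optional).
#' @return collapsed tags sorted by position.
#' @export
collapseReads <- function(reads) {
    stopifnot(is(reads, "GRanges"))
    if (!length(reads)) return(.emptyTags())
    tail <- if ("tail" %in% colnames(mcols(reads))) mcols(reads)$tail
            else rep("", length(reads))
    key <- paste(seqnames(reads), start(reads), end(reads), strand(reads),
                 mcols(reads)$seq, tail, sep = "\r")
    idx <- split(seq_along(reads), key)
    first <- vapply(idx, `[`, integer(1), 1L)
    out <- reads[first]
    mcols(out)$count <- unname(vapply(idx, function(i)
        sum(mcols(reads)$count[i]), integer(1)))
    mcols(out)$nHits <- unname(vapply(idx, function(i)
        max(mcols(reads)$nHits[i]), integer(1)))
    mcols(out)$tail <- tail[first]
    sort(out, ignore.strand = TRUE)
}

#' Count-weighted tag length histogram
#'
#' @param tags aligned tags.
#' @return list with \code{histogram} (data.frame length/reads) and the
#'   read fractions in the mature miRNA (22-23 nt) and piRNA-sized
#'   (30-32 nt) length bins.
#' @export
lengthHistogram <- function(tags) {
    .checkTags(tags)
    if (!length(tags))
        return(list(histogram = data.frame(length = integer(0),
                                           reads = numeric(0)),
                    mirFraction = NA_real_, piFraction = NA_real_))
    w <- width(tags); cnt <- mcols(tags)$count
    tab <- tapply(cnt, w, sum)
    total <- sum(cnt)
    list(histogram = data.frame(length = as.integer(names(tab)),
                                reads = as.numeric(tab)),
         mirFraction = sum(cnt[w %in% 22:23]) / total,
         piFraction = sum(cnt[w %in% 30:32]) / total)
}

# Disjoint priority categories around protein-coding genes. The nested
# upstream/downstream windows are reported as rings (1k, 1-5k, 5-10k) so the
# fractions partition.
.contextCategories <- function(annotation) {
    type <- mcols(annotation)$type
    genes <- annotation[type == "gene"]
    cds <- annotation[type == "CDS"]
    utr5 <- annotation[type == "five_prime_UTR"]
    utr3 <- annotation[type == "three_prime_UTR"]
    exonic <- reduce(c(granges(cds), granges(utr5), granges(utr3)),
                     ignore.strand = TRUE)
    intron <- GenomicRanges::setdiff(reduce(granges(genes),
                                            ignore.strand = TRUE),
                                     exonic, ignore.strand = TRUE)
    up <- function(k) suppressWarnings(trim(flank(genes, k, start = TRUE)))
    dn <- function(k) suppressWarnings(trim(flank(genes, k, start = FALSE)))
    list(CDS = granges(cds),
         utr5 = granges(utr5),
         utr3 = granges(utr3),
         intron = intron,
         upstream1k = granges(up(1000)),
         downstream1k = granges(dn(1000)),
         upstream5k = GenomicRanges::setdiff(granges(up(5000)),
             granges(up(1000)), ignore.strand = TRUE),
         downstream5k = GenomicRanges::setdiff(granges(dn(5000)),
             granges(dn(1000)), ignore.strand = TRUE),
         upstream10k = GenomicRanges::setdiff(granges(up(10000)),
             granges(up(5000)), ignore.strand = TRUE),
         downstream10k = GenomicRanges::setdiff(granges(dn(10000)),
             granges(dn(5000)), ignore.strand = TRUE))
}

#' Genomic context distribution of mapped tags
#'
#' Tags overlapping known miRNA genes are excluded first; every remaining
#' tag is assigned a single category by the fixed priority CDS > 5'UTR >
#' 3'UTR > intron > upstream 1k > downstream 1k > upstream 1-5k ring >
#' downstream 1-5k ring > upstream 5-10k ring > downstream 5-10k ring >
#' intergenic. Overlap is >= 1 shared base and strand-agnostic; fractions
#' are count-weighted and sum to 1 over the partition.
#'
#' @param tags aligned tags.
#' @param annotation GRanges gene model with mcol \code{type} in
#'   \{gene, CDS, five_prime_UTR, three_prime_UTR\}; upstream/downstream
#'   windows are taken strand-aware from the gene ranges.
#' @param knownMirna GRanges of known miRNA genes to exclude.
#' @return named numeric vector of read fractions per category (plus
#'   \code{intergenic}), and attribute \code{excludedFraction} for the
#'   known-miRNA reads removed before the partition.
#' @export
annotateGenomicContext <- function(tags, annotation, knownMirna = GRanges()) {
    .checkTags(tags)
    stopifnot(is(annotation, "GRanges"),
              "type" %in% colnames(mcols(annotation)))
    bad <- !(as.character(seqnames(tags)) %in%
             unique(c(as.character(seqnames(annotation)),
                      as.character(seqnames(knownMirna)))))
    if (any(bad))
        warning(sum(bad), " tag(s) on chromosomes absent from the ",
                "annotation; counted as intergenic")
    total <- sum(mcols(tags)$count)
    excl <- overlapsAny(tags, knownMirna, ignore.strand = TRUE)
    excludedFraction <- if (total > 0)
        sum(mcols(tags)$count[excl]) / total else 0
    tags <- tags[!excl]
    cats <- .contextCategories(annotation)
    remaining <- rep(TRUE, length(tags))
    cnt <- mcols(tags)$count
    denom <- sum(cnt)
    out <- setNames(numeric(length(cats) + 1L),
                    c(names(cats), "intergenic"))
    for (nm in names(cats)) {
        hit <- remaining & suppressWarnings(
            overlapsAny(tags, cats[[nm]], ignore.strand = TRUE))
        out[nm] <- if (denom > 0) sum(cnt[hit]) / denom else 0
        remaining <- remaining & !hit
    }
    out["intergenic"] <- if (denom > 0) sum(cnt[remaining]) / denom else 0
    attr(out, "excludedFraction") <- excludedFraction
    out
}
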