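## Interchange formats: BED-like tag TSV (0-based half-open starts),
## miRBase-dialect GFF3 for loci/catalogs, plain TSV count matrices.
## Coordinate conversion to/from the internal 1-based closed convention
## happens here and only here.

#' Write aligned tags as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end (half-open), seq, count, strand,
#' nHits, tail.
#'
#' @param tags aligned tags.
#' @param path output file.
#' @export
writeTagsTsv <- function(tags, path) {
    .checkTags(tags)
    tail <- if ("tail" %in% colnames(mcols(tags))) mcols(tags)$tail else ""
    df <- data.frame(chrom = as.character(seqnames(tags)),
                     start = start(tags) - 1L, end = end(tags),
                     seq = mcols(tags)$seq, count = mcols(tags)$count,
                     strand = as.character(strand(tags)),
                     nHits = mcols(tags)$nHits, tail = tail)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a BED-like tag TSV
#'
#' @param path file written by \code{\link{writeTagsTsv}}.
#' @return aligned-tag GRanges (1-based closed internally).
#' @export
readTagsTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(tail = "character"))
    df$tail[is.na(df$tail)] <- ""
    alignedTags(df$chrom, df$start + 1L, df$end, df$strand, df$seq,
                df$count, df$nHits, df$tail)
}

#' Write a miRNA catalog (or planted loci) as miRBase-dialect GFF3
#'
#' One \code{pre_miRNA} feature per hairpin with a \code{miRNA} child for
#' the mature sequence (GFF3 is 1-based closed, matching the internal
#' convention, so no coordinate shift applies).
#'
#' @param catalog a \link{MirnaCatalog}.
#' @param path output file.
#' @export
writeCatalogGff3 <- function(catalog, path) {
    e <- catalogEntries(catalog)
    hp <- mcols(e)$hairpin
    pre <- GRanges(seqnames(e), hp, strand = strand(e))
    mcols(pre)$type <- "pre_miRNA"
    mcols(pre)$ID <- paste0(mcols(e)$id, "_hairpin")
    mcols(pre)$Name <- paste0(mcols(e)$id, "_hairpin")
    mcols(pre)$Parent <- NA_character_
    mat <- granges(e)
    mcols(mat)$type <- "miRNA"
    mcols(mat)$ID <- mcols(e)$id
    mcols(mat)$Name <- mcols(e)$id
    mcols(mat)$Parent <- mcols(pre)$ID
    out <- c(pre, mat)
    mcols(out)$source <- "equimir"
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}

#' Read mature miRNAs from a miRBase-dialect GFF3
#'
#' @param path GFF3 file with \code{miRNA} (mature) features.
#' @return GRanges of mature miRNAs with mcol \code{id}.
#' @export
readMirnaGff3 <- function(path) {
    g <- rtracklayer::import(path, format = "GFF3")
    g <- g[mcols(g)$type == "miRNA"]
    id <- mcols(g)$Name
    if (is.null(id)) id <- mcols(g)$ID
    out <- granges(g)
    mcols(out)$id <- as.character(id)
    out
}

#' Write a count matrix with sample metadata as TSV
#'
#' @param se SummarizedExperiment with assay \code{counts}.
#' @param countsPath,metadataPath output files.
#' @export
writeCountsTsv <- function(se, countsPath, metadataPath = NULL) {
    x <- assay(se, "counts")
    write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metadataPath))
        write.table(as.data.frame(colData(se)), metadataPath, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}
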