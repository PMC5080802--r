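## Cross-sample consolidation of per-sample calls into a non-redundant
## catalog: 2-nt merge rule, representative selection, singleton filter,
## known-miRNA annotation, genomic clustering and per-chromosome summaries.

#' Merge near-identical calls across samples
#'
#' Two calls merge iff they lie on the same chromosome and strand and both
#' their start and end positions differ by at most \code{tol} nt (isomiR
#' end variation); merging is the transitive closure of that relation, so
#' the grouping is independent of input order.
#'
#' @param calls combined calls from \code{\link{callMirnas}} (mature
#'   intervals with mcols sample, tool, score, hairpin).
#' @param tol maximum per-end offset in nt (default 2).
#' @return a \link[GenomicRanges]{GRangesList}, one element per merge
#'   group, ordered by position.
#' @export
mergeCalls <- function(calls, tol = 2L) {
    stopifnot(is(calls, "GRanges"))
    n <- length(calls)
    if (!n) return(GenomicRanges::GRangesList())
    # canonical element order makes the grouping input-order independent
    ord <- order(as.character(seqnames(calls)), start(calls), end(calls),
                 as.character(strand(calls)), mcols(calls)$sample)
    calls <- calls[ord]
    chrom <- as.character(seqnames(calls))
    str <- as.character(strand(calls))
    stv <- start(calls); env <- end(calls)
    okey <- paste(chrom, str)
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    # direct pairwise scan (calls are start-sorted, so partners are near)
    for (i in seq_len(max(n - 1L, 0L))) {
        j <- seq(i + 1L, n)
        j <- j[stv[j] - stv[i] <= tol]  # sorted: later starts only grow
        if (!length(j)) next
        hit <- j[okey[j] == okey[i] & abs(env[j] - env[i]) <= tol]
        for (h in hit) {
            a <- find(i); b <- find(h)
            if (a != b) parent[max(a, b)] <- min(a, b)
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    # groups appear in order of their first (lowest-coordinate) member
    gid <- match(root, unique(root))
    unname(S4Vectors::split(calls, gid))
}

#' Pick the representative call of a merge group
#'
#' The variant (distinct interval) seen in the most samples wins; ties go
#' to the higher score, then to the lexicographically smallest
#' (chrom, start, end).
#'
#' @param group one element of \code{\link{mergeCalls}}'s output.
#' @return a one-row GRanges with mcols supportSamples (distinct samples in
#'   the whole group), bestScore (max score in the group) and tools.
#' @export
pickRepresentative <- function(group) {
    stopifnot(is(group, "GRanges"), length(group) > 0)
    key <- paste(seqnames(group), start(group), end(group), strand(group))
    nSamp <- tapply(mcols(group)$sample, key,
                    function(s) length(unique(s)))
    topScore <- tapply(mcols(group)$score, key, max)
    ord <- order(-nSamp, -topScore, names(nSamp))
    winner <- names(nSamp)[ord[1]]
    rep <- group[match(winner, key)]
    mcols(rep)$supportSamples <-
        length(unique(mcols(group)$sample))
    mcols(rep)$bestScore <- max(mcols(group)$score)
    mcols(rep)$tools <- paste(sort(unique(mcols(group)$tool)),
                              collapse = ",")
    rep
}

#' Drop groups supported by a single sample
#'
#' Support counts distinct sample ids, not calls: a group with several
#' calls from one library is still a singleton.
#'
#' @param groups a GRangesList from \code{\link{mergeCalls}}.
#' @return the groups seen in at least two samples.
#' @export
filterSingletons <- function(groups) {
    keep <- vapply(groups, function(g)
        length(unique(mcols(g)$sample)) >= 2L, logical(1))
    groups[keep]
}

# classify one representative against known mature miRNAs
.knownOverlapClass <- function(rep, known, tol) {
    if (!length(known))
        return(list(class = "none", partner = NA_character_))
    ids <- if (!is.null(mcols(known)$id)) mcols(known)$id
           else if (!is.null(names(known))) names(known)
           else paste0("known-", seq_along(known))
    same <- findOverlaps(rep, known)  # strand-aware
    opp <- findOverlaps(rep, known, ignore.strand = TRUE)
    oppOnly <- setdiff(subjectHits(opp), subjectHits(same))
    if (length(subjectHits(same))) {
        j <- subjectHits(same)
        ds <- abs(start(rep) - start(known)[j])
        de <- abs(end(rep) - end(known)[j])
        exact <- ds == 0 & de == 0
        near <- !exact & ds <= tol & de <= tol
        if (any(exact))
            return(list(class = "same-strand",
                        partner = ids[j[which(exact)[1]]]))
        if (any(near))
            return(list(class = "near-identical",
                        partner = ids[j[which(near)[1]]]))
        return(list(class = "same-strand", partner = ids[j[1]]))
    }
    if (length(oppOnly))
        return(list(class = "opposite-strand", partner = ids[oppOnly[1]]))
    list(class = "none", partner = NA_character_)
}

#' Combine per-tool groups into an annotated catalog
#'
#' Takes the post-singleton merge groups of the score-based ("deep") and
#' criteria-based ("dentify") discovery runs, merges their representatives
#' across tools with the same 2-nt rule (union with tool provenance), and
#' annotates each entry against known mature miRNAs: an exact same-strand
#' match is known (not novel); a same-strand match shifted by at most
#' \code{tol} nt at the ends is flagged near-identical but remains novel;
#' any other same-strand overlap counts as a known match; an antisense
#' overlap stays novel and is flagged opposite-strand.
#'
#' @param deepGroups,dentifyGroups GRangesLists from
#'   \code{\link{filterSingletons}} (either may be empty).
#' @param known GRanges of known mature miRNAs (optionally with mcol
#'   \code{id}).
#' @param tol merge/annotation end tolerance in nt.
#' @return a \link{MirnaCatalog}.
#' @export
combineAndAnnotate <- function(deepGroups, dentifyGroups,
                               known = GRanges(), tol = 2L) {
    reps <- list()
    for (g in as.list(deepGroups)) reps[[length(reps) + 1L]] <-
        pickRepresentative(g)
    for (g in as.list(dentifyGroups)) reps[[length(reps) + 1L]] <-
        pickRepresentative(g)
    if (!length(reps)) return(.emptyCatalog())
    reps <- do.call(c, reps)
    # cross-tool union with the same end-tolerance rule
    fake <- reps
    mcols(fake)$sample <- seq_along(fake)  # keep every rep distinct
    mcols(fake)$score <- mcols(reps)$bestScore
    regroup <- mergeCalls(fake, tol = tol)
    entries <- list()
    for (g in as.list(regroup)) {
        i <- mcols(g)$sample  # indices into reps
        sub <- reps[i]
        lead <- sub[order(-mcols(sub)$supportSamples,
                          -mcols(sub)$bestScore)][1]
        mcols(lead)$supportSamples <- max(mcols(sub)$supportSamples)
        mcols(lead)$bestScore <- max(mcols(sub)$bestScore)
        mcols(lead)$tools <- paste(sort(unique(unlist(
            strsplit(mcols(sub)$tools, ",")))), collapse = ",")
        entries[[length(entries) + 1L]] <- lead
    }
    entries <- do.call(c, entries)
    entries <- sort(entries, ignore.strand = TRUE)
    ann <- lapply(seq_along(entries), function(i)
        .knownOverlapClass(entries[i], known, tol))
    cls <- vapply(ann, `[[`, character(1), "class")
    e <- GRanges(seqnames(entries), ranges(entries),
                 strand = strand(entries))
    mcols(e)$id <- paste0("novel-mir-", seq_along(entries))
    mcols(e)$hairpin <- mcols(entries)$hairpin
    mcols(e)$supportSamples <- mcols(entries)$supportSamples
    mcols(e)$bestScore <- mcols(entries)$bestScore
    mcols(e)$tools <- mcols(entries)$tools
    mcols(e)$novelty <- !(cls == "same-strand")
    mcols(e)$knownOverlap <- cls
    mcols(e)$knownPartner <- vapply(ann, `[[`, character(1), "partner")
    mcols(e)$matureSeq <- mcols(entries)$matureSeq
    known_ids <- mcols(e)$knownPartner[!mcols(e)$novelty]
    mcols(e)$id[!mcols(e)$novelty] <- ifelse(is.na(known_ids),
        mcols(e)$id[!mcols(e)$novelty], known_ids)
    new("MirnaCatalog", entries = e)
}

.emptyCatalog <- function() {
    g <- GRanges()
    mcols(g)$id <- character(0)
    mcols(g)$hairpin <- IRanges()
    mcols(g)$supportSamples <- integer(0)
    mcols(g)$bestScore <- numeric(0)
    mcols(g)$tools <- character(0)
    mcols(g)$novelty <- logical(0)
    mcols(g)$knownOverlap <- character(0)
    mcols(g)$knownPartner <- character(0)
    mcols(g)$matureSeq <- character(0)
    new("MirnaCatalog", entries = g)
}

#' Find genomic miRNA clusters
#'
#' Single-linkage chaining of catalog entries whose hairpin start-to-start
#' distance is at most \code{maxGap} nt on the same chromosome
#' (strand-agnostic); a cluster needs at least two members.
#'
#' @param catalog a \link{MirnaCatalog}.
#' @param maxGap maximum start-to-start distance (default 3000).
#' @return \link[S4Vectors]{DataFrame} with chrom, start, end, n and a
#'   comma-separated member id list per cluster.
#' @export
findClusters <- function(catalog, maxGap = 3000L) {
    e <- catalogEntries(catalog)
    if (!length(e))
        return(DataFrame(chrom = character(0), start = integer(0),
                         end = integer(0), n = integer(0),
                         members = character(0)))
    hp <- mcols(e)$hairpin
    df <- data.frame(chrom = as.character(seqnames(e)), start = start(hp),
                     end = end(hp), id = mcols(e)$id,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), ]
    newChain <- c(TRUE, diff(df$start) > maxGap |
                  df$chrom[-1] != df$chrom[-nrow(df)])
    chain <- cumsum(newChain)
    out <- lapply(split(df, chain), function(d) {
        if (nrow(d) < 2) return(NULL)
        DataFrame(chrom = d$chrom[1], start = min(d$start),
                  end = max(d$end), n = nrow(d),
                  members = paste(d$id, collapse = ","))
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
        return(DataFrame(chrom = character(0), start = integer(0),
                         end = integer(0), n = integer(0),
                         members = character(0)))
    do.call(rbind, out)
}

#' Per-chromosome catalog summary
#'
#' Counts entries per chromosome, pooling scaffold-like names (anything not
#' matching \code{placedPattern}) as "Unplaced", with a sense-strand tally.
#'
#' @param catalog a \link{MirnaCatalog}.
#' @param placedPattern regexp identifying placed chromosome names.
#' @return data.frame with chrom, n, nSense; counts sum to the catalog
#'   size.
#' @export
chromosomeSummary <- function(catalog,
                              placedPattern = "^(chr)?([0-9]+|[XY]|MT?)$") {
    e <- catalogEntries(catalog)
    chrom <- as.character(seqnames(e))
    chrom[!grepl(placedPattern, chrom)] <- "Unplaced"
    if (!length(e))
        return(data.frame(chrom = character(0), n = integer(0),
                          nSense = integer(0)))
    tab <- table(chrom)
    sense <- tapply(as.character(strand(e)) == "+", chrom, sum)
    data.frame(chrom = names(tab), n = as.integer(tab),
               nSense = as.integer(sense[names(tab)]),
               stringsAsFactors = FALSE)
}
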