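#' Fold an RNA sequence with a self-contained pair-maximization model
#'
#' Non-crossing secondary structure by dynamic programming over a simple
#' energy model: pair weights GC = 3, AU = 2, GU = 1 and a minimum hairpin
#' loop of \code{minloop} unpaired bases. The returned "MFE" is the negated
#' optimal pair weight (<= 0), so lower means more stably paired; it is a
#' model score, not a thermodynamic free energy. Deterministic.
#'
#' @param sequence a single RNA/DNA string over \{A, C, G, U/T\}.
#' @param minloop minimum number of unpaired bases enclosed by a pair.
#' @return list with \code{structure} (dot-bracket) and \code{mfe}.
#' @export
foldHairpin <- function(sequence, minloop = 3L) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    s <- toupper(sequence)
    if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
    if (grepl("[^ACGUT]", s))
        stop("sequence contains characters outside {A,C,G,U,T}",
             call. = FALSE)
    res <- .nussinovFold(s, as.integer(minloop))
    list(structure = res$structure, mfe = res$energy)
}

#' Pairing partners from a dot-bracket string
#'
#' @param structure dot-bracket string with balanced brackets.
#' @return integer vector; position i holds the partner of base i, 0 if
#'   unpaired.
#' @export
pairTable <- function(structure) {
    ch <- strsplit(structure, "")[[1]]
    pt <- integer(length(ch))
    stack <- integer(0)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            if (!length(stack)) stop("unbalanced brackets", call. = FALSE)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pt[i] <- j; pt[j] <- i
        }
    }
    if (length(stack)) stop("unbalanced brackets", call. = FALSE)
    pt
}

# pair weight lookup used for duplex/flanking energies
.pairWeight <- function(a, b) {
    key <- paste0(a, b)
    w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
    out <- unname(w[key])
    out[is.na(out)] <- 0
    out
}

# energy (negated weight sum) of the pairs in `pt` selected by `keep`
# (logical over pair tuples i < pt[i])
.structureEnergy <- function(seq, pt, keep = NULL) {
    s <- chartr("T", "U", toupper(seq))
    ch <- strsplit(s, "")[[1]]
    i <- which(pt > seq_along(pt))
    if (!is.null(keep)) i <- i[keep(i, pt[i])]
    if (!length(i)) return(0)
    -sum(.pairWeight(ch[i], ch[pt[i]]))
}
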