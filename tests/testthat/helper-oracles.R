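## Independent oracles kept deliberately separate from the package's code
## paths.

# Exhaustive base-pair maximization by top-down memoized recursion with a
# first-position decomposition (the package folds bottom-up over the last
# position): same energy model, independent implementation.
oracleFoldEnergy <- function(seq, minloop = 3L) {
    s <- chartr("T", "U", toupper(seq))
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    w <- function(a, b) {
        key <- paste0(a, b)
        if (key %in% c("GC", "CG")) 3
        else if (key %in% c("AU", "UA")) 2
        else if (key %in% c("GU", "UG")) 1
        else 0
    }
    memo <- new.env(hash = TRUE)
    E <- function(i, j) {
        if (j - i < minloop + 1L) return(0)
        key <- paste(i, j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        best <- E(i + 1L, j)  # i unpaired
        for (k in seq(i + minloop + 1L, j)) {
            wik <- w(ch[i], ch[k])
            if (wik == 0) next
            cand <- wik + E(i + 1L, k - 1L) + E(k + 1L, j)
            if (cand > best) best <- cand
        }
        memo[[key]] <- best
        best
    }
    if (n < minloop + 2L) return(0)
    E(1L, n)
}

# Exact-test oracle: brute-force enumeration of all splits of the total,
# with probabilities from dnbinom/dpois at an arbitrary common mean (the
# conditional law must not depend on it).
oracleExactP <- function(a, b, nA, nB, phi, mu = 1.7) {
    t <- a + b
    if (t == 0) return(1)
    k <- 0:t
    if (phi == 0) {
        pk <- dpois(k, nA * mu) * dpois(t - k, nB * mu)
    } else {
        pk <- dnbinom(k, size = nA / phi, mu = nA * mu) *
              dnbinom(t - k, size = nB / phi, mu = nB * mu)
    }
    pk <- pk / sum(pk)
    sum(pk[pk <= pk[a + 1] * (1 + 1e-10)])
}

# Closed-form doubly trimmed, precision-weighted mean of M values,
# written as plain loops (brute-force TMM oracle for one sample vs ref).
oracleTmmFactor <- function(y, r, Ny, Nr, trimM = 0.3, trimA = 0.05) {
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    py <- y / Ny; pr <- r / Nr
    M <- log2(py / pr)
    A <- 0.5 * (log2(py) + log2(pr))
    w <- (1 - py) / py + (1 - pr) / pr
    n <- length(M)
    rkM <- rank(M, ties.method = "first")
    rkA <- rank(A, ties.method = "first")
    sel <- rkM >= floor(n * trimM) + 1 & rkM <= n - floor(n * trimM) &
           rkA >= floor(n * trimA) + 1 & rkA <= n - floor(n * trimA)
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}
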