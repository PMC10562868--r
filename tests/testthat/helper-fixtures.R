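# Shared in-code fixtures and independent oracles.

# Tiny paired experiment from explicit counts: one factor, nPairs replicates.
makePairedExperiment <- function(counts, factorName = "Fx") {
    nPairs <- ncol(counts) / 2
    ids <- as.vector(vapply(seq_len(nPairs), function(r)
        sprintf("%s_rep%d_%s", factorName, r, c("total", "IP")), c("", "")))
    colnames(counts) <- ids
    smp <- data.frame(factor = factorName,
                      replicate = rep(seq_len(nPairs), each = 2),
                      role = rep(c("total", "IP"), nPairs),
                      row.names = ids)
    RipExperiment(counts, smp)
}

# Independent TMM reimplementation (30% M-trim, 5% A-trim), reference column
# the one whose log library size is closest to the mean log size.
oracleTMM <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
    libs <- colSums(counts)
    ref <- which.min(abs(log(libs) - mean(log(libs))))
    oneFactor <- function(j) {
        x <- counts[, j]; r <- counts[, ref]
        keep <- x > 0 & r > 0
        x <- x[keep]; r <- r[keep]
        N <- libs[j]; Nr <- libs[ref]
        M <- log2((x / N) / (r / Nr))
        A <- 0.5 * log2((x / N) * (r / Nr))
        w <- (N - x) / (N * x) + (Nr - r) / (Nr * r)
        n <- length(M)
        loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
        loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
        keep2 <- rank(M, ties.method = "first") >= loM &
            rank(M, ties.method = "first") <= hiM &
            rank(A, ties.method = "first") >= loA &
            rank(A, ties.method = "first") <= hiA
        2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
    }
    f <- vapply(seq_len(ncol(counts)), oneFactor, 0)
    f / exp(mean(log(f)))
}

# Exhaustive hypergeometric upper tail: enumerate all size-n draws.
oracleHyperUpper <- function(N, K, n, x) {
    draws <- utils::combn(N, n)
    inK <- colSums(draws <= K)      # first K elements form the marked set
    mean(inK >= x)
}

# Exact two-sided Mann-Whitney p by enumerating all rank assignments of the
# group memberships (values may tie; midranks used throughout).
oracleMWExact <- function(x, y) {
    all <- c(x, y)
    n1 <- length(x)
    r <- rank(all)
    Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * length(y) / 2
    draws <- utils::combn(length(all), n1)
    Us <- apply(draws, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
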