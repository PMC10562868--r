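#' Notched box summary of a numeric vector
#'
#' Quartiles by linear interpolation (quantile position 1 + (n-1)q) and the
#' notch, the 95% confidence interval of the median:
#' median +/- 1.58 * IQR / sqrt(n).
#'
#' @param values numeric vector (NAs dropped).
#' @return named numeric vector: n, median, q1, q3, notchLow, notchHigh.
#' @examples
#' summarizeBox(1:9)  # notch [2.8933, 7.1067]
#' @export
summarizeBox <- function(values) {
    x <- values[!is.na(values)]
    n <- length(x)
    if (n < 1) stop("at least one value is required")
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    c(n = n, median = q[2], q1 = q[1], q3 = q[3],
      notchLow = q[2] - 1.58 * iqr / sqrt(n),
      notchHigh = q[2] + 1.58 * iqr / sqrt(n))
}

.mwU <- function(x, y) {
    # Mann-Whitney U of x against y with midranks for ties
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

.mwTest <- function(x, y, exactLimit = 400) {
    n1 <- length(x); n2 <- length(y)
    exact <- n1 * n2 <= exactLimit
    ht <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE))
    p <- ht$p.value
    if (is.na(p)) p <- 1  # fully tied data carry no evidence
    min(p, 1)
}

#' Compare a property's distribution per cluster against the reference
#'
#' Each cluster's values are compared with the all-gene ("all-data")
#' distribution by a two-sided Mann-Whitney U test, the reference including
#' the cluster's own members; \code{reference = "complement"} compares
#' against the remaining genes instead. P-values are exact when
#' n1 * n2 <= 400 (and tie-free), otherwise a normal approximation with
#' continuity and tie correction is used. BH adjustment is applied across
#' the returned rows; to adjust jointly across several properties use
#' \code{\link{comparePropertyTable}}.
#'
#' @param values named numeric vector of the property (NA = missing).
#' @param labels named integer vector, gene -> cluster.
#' @param propertyName label carried into the output.
#' @param reference "all" (default) or "complement".
#' @param adjust apply BH across the rows (default TRUE; turned off by the
#'   joint multi-property wrapper).
#' @return data.frame, one row per cluster: property, cluster, n, U, p,
#'   pAdj, median, q1, q3, notchLow, notchHigh, stars.
#' @export
compareProperty <- function(values, labels, propertyName = "property",
                            reference = c("all", "complement"),
                            adjust = TRUE) {
    reference <- match.arg(reference)
    if (all(is.na(values)))
        stop("property '", propertyName, "' has no non-missing values")
    common <- intersect(names(values), names(labels))
    values <- values[common]; labels <- labels[common]
    ok <- !is.na(values)
    rows <- lapply(sort(unique(labels)), function(cl) {
        x <- values[ok & labels == cl]
        y <- if (reference == "all") values[ok] else values[ok & labels != cl]
        if (length(x) < 2 || length(y) < 2) {
            U <- p <- NA_real_
            bx <- setNames(rep(NA_real_, 6),
                           c("n", "median", "q1", "q3", "notchLow", "notchHigh"))
            if (length(x) >= 1) bx <- summarizeBox(x)
        } else {
            U <- .mwU(x, y)
            p <- .mwTest(x, y)
            bx <- summarizeBox(x)
        }
        data.frame(property = propertyName, cluster = cl,
                   n = length(x), U = U, p = p,
                   median = bx[["median"]], q1 = bx[["q1"]], q3 = bx[["q3"]],
                   notchLow = bx[["notchLow"]], notchHigh = bx[["notchHigh"]])
    })
    out <- do.call(rbind, rows)
    if (adjust) {
        out$pAdj <- p.adjust(out$p, method = "BH")
        out$stars <- .stars(out$pAdj)
    }
    out
}

.stars <- function(p) {
    ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Compare every property of a table across clusters, with joint FDR
#'
#' Runs \code{\link{compareProperty}} for each column and applies BH
#' correction jointly across all (cluster, property) tests of the run, the
#' multiplicity convention of the pipeline; adjusted p < 0.05 is flagged
#' significant (stars at 0.05 / 0.01 / 0.001).
#'
#' @param properties data.frame, rownames = genes, one column per property.
#' @param labels named integer vector, gene -> cluster.
#' @param reference as in \code{\link{compareProperty}}.
#' @return data.frame of all comparison rows with joint \code{pAdj}.
#' @export
comparePropertyTable <- function(properties, labels,
                                 reference = "all") {
    rows <- lapply(colnames(properties), function(pn)
        compareProperty(setNames(properties[[pn]], rownames(properties)),
                        labels, pn, reference = reference, adjust = FALSE))
    out <- do.call(rbind, rows)
    out$pAdj <- p.adjust(out$p, method = "BH")
    out$stars <- .stars(out$pAdj)
    rownames(out) <- NULL
    out
}

#' Per-cluster sum of a property (PaxDB-style protein fractions)
#'
#' @param values named numeric vector (e.g. proportion of cellular protein).
#' @param labels named integer vector, gene -> cluster.
#' @return data.frame with cluster, total and share of the global sum.
#' @export
clusterPropertySum <- function(values, labels) {
    common <- intersect(names(values), names(labels))
    v <- values[common]; l <- labels[common]
    tot <- tapply(v, l, sum, na.rm = TRUE)
    data.frame(cluster = as.integer(names(tot)), total = as.numeric(tot),
               share = as.numeric(tot) / sum(v, na.rm = TRUE))
}

.checkACGT <- function(seqs, what) {
    af <- Biostrings::alphabetFrequency(seqs)
    other <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    if (any(other > 0)) {
        g <- names(seqs)[which(other > 0)[1]]
        s <- as.character(seqs[[which(other > 0)[1]]])
        pos <- regexpr("[^ACGT]", s)
        stop("non-ACGT character in ", what, " of gene '", g,
             "' at position ", as.integer(pos))
    }
}

#' Per-gene 5'UTR adenosine proportion
#'
#' Count of A divided by 5'UTR length; genes with zero-length UTRs are
#' excluded.
#'
#' @param annotation a \linkS4class{TranscriptAnnotation}, or a named
#'   \code{DNAStringSet} of 5'UTR sequences.
#' @return named numeric vector over genes with non-empty UTRs.
#' @export
utrAFraction <- function(annotation) {
    u5 <- if (methods::is(annotation, "TranscriptAnnotation"))
        annotation@utr5 else annotation
    u5 <- u5[Biostrings::width(u5) > 0]
    .checkACGT(u5, "5'UTR")
    a <- Biostrings::letterFrequency(u5, "A")[, 1]
    setNames(a / Biostrings::width(u5), names(u5))
}

#' Positional adenosine enrichment over the 5'UTR, per cluster
#'
#' Positions are counted from the base immediately 5' of the start codon
#' (position -1) toward the cap; only UTRs long enough to span a position
#' contribute to it. The enrichment at a position is the cluster's adenosine
#' frequency divided by the all-gene frequency; rows with fewer than
#' \code{minCoverage} contributing UTRs, or with zero all-gene frequency,
#' are reported as missing.
#'
#' @param annotation \linkS4class{TranscriptAnnotation} or named 5'UTR
#'   \code{DNAStringSet}.
#' @param labels named integer vector, gene -> cluster.
#' @param maxDepth how far upstream to look (nt).
#' @param minCoverage minimum UTRs spanning a position (default 25).
#' @return data.frame: cluster, position (negative), fCluster, fAll,
#'   enrichment, nCovered.
#' @export
positionalAEnrichment <- function(annotation, labels, maxDepth = 50,
                                  minCoverage = 25) {
    u5 <- if (methods::is(annotation, "TranscriptAnnotation"))
        annotation@utr5 else annotation
    u5 <- u5[intersect(names(u5), names(labels))]
    .checkACGT(u5, "5'UTR")
    w <- Biostrings::width(u5)
    chars <- strsplit(as.character(u5), "")
    nG <- length(u5)
    isA <- matrix(NA, nG, maxDepth)       # [gene, upstream offset]
    for (i in seq_len(nG)) {
        depth <- min(w[i], maxDepth)
        if (depth > 0)
            isA[i, seq_len(depth)] <- rev(chars[[i]])[seq_len(depth)] == "A"
    }
    lab <- labels[names(u5)]
    fAll <- colMeans(isA, na.rm = TRUE)
    nAll <- colSums(!is.na(isA))
    rows <- lapply(sort(unique(lab)), function(cl) {
        sub <- isA[lab == cl, , drop = FALSE]
        fCl <- colMeans(sub, na.rm = TRUE)
        nCl <- colSums(!is.na(sub))
        enr <- ifelse(nCl >= minCoverage & nAll >= minCoverage & fAll > 0,
                      fCl / fAll, NA_real_)
        data.frame(cluster = cl, position = -seq_len(maxDepth),
                   fCluster = fCl, fAll = fAll, enrichment = enr,
                   nCovered = nCl)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
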