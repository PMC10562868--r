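.checkUniverse <- function(sets, universe) {
    for (nm in names(sets)) {
        out <- setdiff(sets[[nm]], universe)
        if (length(out))
            stop("set '", nm, "' has element(s) outside the universe: ",
                 paste(head(out, 5), collapse = ", "))
    }
}

#' Exact hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability P(X >= x) of observing at least the seen overlap
#' when a query of size n is drawn without replacement from a universe of
#' size N containing K members of the other set.
#'
#' @param setA,setB character vectors of gene ids (query = A, reference = B).
#' @param universe character vector; both sets must be subsets of it.
#' @return one-row data.frame: N, K, n, x, p, enrichmentRatio, method.
#' @examples
#' u <- letters[1:10]
#' hypergeomOverlap(letters[1:4], letters[1:5], u)$p  # 5/210
#' @export
hypergeomOverlap <- function(setA, setB, universe) {
    sets <- list(A = unique(setA), B = unique(setB))
    .checkUniverse(sets, universe)
    N <- length(unique(universe))
    K <- length(sets$B); n <- length(sets$A)
    x <- length(intersect(sets$A, sets$B))
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    er <- if (n > 0 && K > 0) (x / n) / (K / N) else NA_real_
    data.frame(N = N, K = K, n = n, x = x, p = p,
               enrichmentRatio = er, method = "hypergeometric")
}

#' Monte-Carlo significance of a multi-way gene-set overlap
#'
#' Each draw resamples every set uniformly without replacement from the
#' universe at its observed size; the statistic is the size of the full
#' intersection. The p-value uses the add-one estimator
#' (#draws >= observed + 1) / (nDraws + 1), so p > 0, with its binomial
#' standard error reported.
#'
#' @param sets named list of >= 2 character vectors (three for the
#'   pipeline's three-way comparisons).
#' @param universe character vector containing every set.
#' @param nDraws number of random draws (default 1e6, the pipeline's
#'   convention for three-way overlaps).
#' @param seed integer seed.
#' @return one-row data.frame: N, sizes, x, p, mcSe, nDraws, seed, method.
#' @export
mcMultiwayOverlap <- function(sets, universe, nDraws = 1e6, seed = 1) {
    stopifnot(length(sets) >= 2)
    sets <- lapply(sets, unique)
    .checkUniverse(sets, universe)
    universe <- unique(universe)
    N <- length(universe)
    sizes <- lengths(sets)
    if (any(sizes > N)) stop("a set is larger than the universe")
    obs <- length(Reduce(intersect, sets))
    nSets <- length(sets)
    set.seed(seed)
    hits <- 0L
    for (d in seq_len(nDraws)) {
        draw <- unlist(lapply(sizes, function(sz) sample.int(N, sz)))
        stat <- sum(tabulate(draw, N) == nSets)
        if (stat >= obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (nDraws + 1)
    mcSe <- sqrt(p * (1 - p) / nDraws)
    data.frame(N = N, sizes = paste(sizes, collapse = ","), x = obs,
               p = p, mcSe = mcSe, nDraws = nDraws, seed = seed,
               method = "monte_carlo")
}

#' Term over-representation for query gene sets
#'
#' Hypergeometric upper-tail test of each (query set, term) pair over a
#' declared universe, the custom-list enrichment used to relate clusters to
#' annotation terms or published RBP target lists. Terms with fewer than
#' \code{minSize} or more than \code{maxSize} universe genes are skipped.
#' BH adjustment is applied across all tested terms within each query set;
#' the enrichment ratio (x/n)/(K/N) is the dot-plot spot size, the adjusted
#' p its color.
#'
#' @param querySets named list of character vectors (e.g. cluster members).
#' @param term2gene data.frame with columns \code{term}, \code{gene}, or a
#'   named list term -> genes.
#' @param universe character vector (non-empty).
#' @param minSize,maxSize term size bounds within the universe.
#' @return data.frame, one row per tested (query, term) pair: query, term,
#'   N, K, n, x, p, pAdj, enrichmentRatio.
#' @export
termEnrichment <- function(querySets, term2gene, universe,
                           minSize = 3, maxSize = 2000) {
    if (!length(universe)) stop("the universe is empty")
    universe <- unique(universe)
    if (is.data.frame(term2gene))
        term2gene <- split(as.character(term2gene$gene),
                           as.character(term2gene$term))
    term2gene <- lapply(term2gene, function(g) intersect(unique(g), universe))
    keep <- lengths(term2gene) >= minSize & lengths(term2gene) <= maxSize
    term2gene <- term2gene[keep]
    N <- length(universe)
    rows <- list()
    for (qn in names(querySets)) {
        q <- intersect(unique(querySets[[qn]]), universe)
        n <- length(q)
        block <- lapply(names(term2gene), function(tn) {
            tg <- term2gene[[tn]]
            K <- length(tg)
            x <- length(intersect(q, tg))
            p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
            data.frame(query = qn, term = tn, N = N, K = K, n = n, x = x,
                       p = p,
                       enrichmentRatio = if (n > 0) (x / n) / (K / N)
                                         else NA_real_)
        })
        block <- do.call(rbind, block)
        if (!is.null(block)) {
            block$pAdj <- p.adjust(block$p, method = "BH")
            rows[[qn]] <- block
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("query", "term", "N", "K", "n", "x", "p", "pAdj",
            "enrichmentRatio")]
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    setNames(lapply(parts, function(p) unique(p[-(1:2)])),
             vapply(parts, `[`, "", 1))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default the set names).
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
        "")
    writeLines(lines, path)
}
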