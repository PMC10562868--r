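#' Effective library sizes by trimmed mean of M-values
#'
#' Raw column sums scaled by TMM normalization factors (30% M-trim, 5%
#' A-trim) computed against the column whose log-size is closest to the mean,
#' the convention of the count-based GLM stack the enrichment test uses.
#'
#' @param x a \linkS4class{RipExperiment} or a count matrix.
#' @return named numeric vector of effective library sizes; the TMM factors
#'   themselves are attached as attribute \code{"normFactors"}.
#' @examples
#' cnt <- matrix(rpois(200, 100), 50, 4,
#'               dimnames = list(NULL, paste0("s", 1:4)))
#' normalizeLibSizes(cnt)
#' @export
normalizeLibSizes <- function(x) {
    cnt <- if (methods::is(x, "RipExperiment")) ripCounts(x) else as.matrix(x)
    if (ncol(cnt) < 2) stop("at least 2 samples are required")
    zero <- colSums(cnt) == 0
    if (any(zero))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(cnt)[zero], collapse = ", "))
    nf <- edgeR::calcNormFactors(cnt, method = "TMM",
                                 logratioTrim = 0.3, sumTrim = 0.05)
    out <- colSums(cnt) * nf
    names(out) <- colnames(cnt)
    attr(out, "normFactors") <- setNames(nf, colnames(cnt))
    out
}

.factorSubset <- function(experiment, factorName) {
    cd <- SummarizedExperiment::colData(experiment)
    sel <- which(as.character(cd$factor) == factorName)
    if (!length(sel))
        stop("factor '", factorName, "' absent from the sample metadata")
    cnt <- ripCounts(experiment)[, sel, drop = FALSE]
    meta <- as.data.frame(cd[sel, , drop = FALSE])
    ord <- order(meta$replicate, meta$role)  # total before IP within replicate
    list(counts = cnt[, ord, drop = FALSE], meta = meta[ord, , drop = FALSE])
}

.pairedDesign <- function(meta) {
    repl <- factor(meta$replicate)
    ip <- as.integer(meta$role == "IP")
    design <- model.matrix(~repl + ip)
    colnames(design)[ncol(design)] <- "IP"
    design
}

#' Estimate negative-binomial dispersions for one factor's paired design
#'
#' Common dispersion by maximizing the adjusted profile likelihood over
#' genes, then tagwise dispersions moderated toward the common value with
#' weight \code{priorDf} (prior degrees of freedom); tagwise values are
#' clipped to [0, 10]. Requires at least two replicate IP/total pairs.
#'
#' @param experiment a \linkS4class{RipExperiment}.
#' @param factorName which factor's samples to fit.
#' @param priorDf shrinkage weight; \code{Inf} forces every tagwise
#'   dispersion to the common value.
#' @param expressionFloor genes with average count below this are excluded
#'   from the fit (and from testing downstream).
#' @return An \linkS4class{NBFit}.
#' @export
estimateDispersion <- function(experiment, factorName, priorDf = 10,
                               expressionFloor = 1) {
    sub <- .factorSubset(experiment, factorName)
    nPairs <- sum(sub$meta$role == "IP")
    if (nPairs < 2)
        stop("dispersion is unidentifiable with a single replicate pair")
    design <- .pairedDesign(sub$meta)
    keep <- rowMeans(sub$counts) >= expressionFloor
    y <- edgeR::DGEList(counts = sub$counts[keep, , drop = FALSE])
    y <- edgeR::calcNormFactors(y, method = "TMM",
                                logratioTrim = 0.3, sumTrim = 0.05)
    y <- edgeR::estimateDisp(y, design, prior.df = priorDf, trend.method = "none")
    tag <- pmin(pmax(y$tagwise.dispersion, 0), 10)
    methods::new("NBFit", factorName = factorName, design = design,
                 dispersionCommon = y$common.dispersion,
                 dispersionTagwise = setNames(tag, rownames(y)),
                 priorDf = as.numeric(priorDf),
                 normFactors = setNames(y$samples$norm.factors, rownames(y$samples)),
                 libSizes = setNames(y$samples$lib.size, rownames(y$samples)),
                 fit = list(dge = y, keep = keep))
}

#' Paired IP-versus-total enrichment test for one factor
#'
#' Fits the NB GLM with replicate block effects plus one IP-role coefficient
#' and tests that coefficient with a likelihood-ratio test. The coefficient
#' is the per-gene log2(IP/total) enrichment (LFC); p-values are BH-adjusted
#' within the factor. Genes below the expression floor are reported with
#' \code{NA} estimates and \code{tested = FALSE}.
#'
#' @param experiment a \linkS4class{RipExperiment}.
#' @param factorName factor to test.
#' @param fit optional \linkS4class{NBFit} from
#'   \code{\link{estimateDispersion}} (computed if missing).
#' @param priorDf,expressionFloor passed to \code{\link{estimateDispersion}}
#'   when \code{fit} is NULL.
#' @return An \linkS4class{EnrichmentResult} whose table preserves the
#'   experiment's gene order.
#' @export
testEnrichment <- function(experiment, factorName, fit = NULL,
                           priorDf = 10, expressionFloor = 1) {
    if (is.null(fit))
        fit <- estimateDispersion(experiment, factorName,
                                  priorDf = priorDf,
                                  expressionFloor = expressionFloor)
    stopifnot(methods::is(fit, "NBFit"), fit@factorName == factorName)
    y <- fit@fit$dge
    design <- fit@design
    gf <- edgeR::glmFit(y, design)
    lrt <- edgeR::glmLRT(gf, coef = "IP")
    tt <- lrt$table
    genes <- rownames(ripCounts(experiment))
    lfc <- p <- fdr <- rep(NA_real_, length(genes))
    names(lfc) <- names(p) <- names(fdr) <- genes
    lfc[rownames(tt)] <- tt$logFC
    p[rownames(tt)] <- tt$PValue
    fdr[rownames(tt)] <- p.adjust(tt$PValue, method = "BH")
    tested <- genes %in% rownames(tt)
    tb <- S4Vectors::DataFrame(gene = genes, lfc = lfc, p = p, fdr = fdr,
                               tested = tested)
    methods::new("EnrichmentResult", factorName = factorName, table = tb)
}

#' Run the enrichment test for every factor of an experiment
#'
#' @inheritParams testEnrichment
#' @return named list of \linkS4class{EnrichmentResult}, one per factor,
#'   in the order the factors appear in the sample metadata.
#' @export
testAllFactors <- function(experiment, priorDf = 10, expressionFloor = 1) {
    facs <- factorNames(experiment)
    out <- lapply(facs, function(f)
        testEnrichment(experiment, f, priorDf = priorDf,
                       expressionFloor = expressionFloor))
    setNames(out, facs)
}

#' Filter transcripts to the analysis universe
#'
#' A gene is kept iff it shows FDR below \code{fdrMax} in at least one factor
#' (enriched or depleted) and its raw count exceeds \code{minTotalReads}
#' (strictly) in every total-extract sample of every factor under analysis.
#' Genes untested in a factor count as non-significant there but remain
#' subject to the total-reads clause. Output order follows the experiment's
#' gene order.
#'
#' @param results named list of \linkS4class{EnrichmentResult}.
#' @param experiment the \linkS4class{RipExperiment} the results came from.
#' @param fdrMax FDR threshold (default 0.01).
#' @param minTotalReads strict lower bound on total-sample counts
#'   (default 20: a count of exactly 20 fails).
#' @return character vector of gene identifiers (possibly empty).
#' @export
filterTranscripts <- function(results, experiment, fdrMax = 0.01,
                              minTotalReads = 20) {
    stopifnot(length(results) >= 1)
    genes <- rownames(ripCounts(experiment))
    sig <- rep(FALSE, length(genes))
    for (res in results) {
        tb <- res@table
        stopifnot(identical(as.character(tb$gene), genes))
        sig <- sig | (!is.na(tb$fdr) & tb$fdr < fdrMax)
    }
    cd <- SummarizedExperiment::colData(experiment)
    facs <- vapply(results, function(r) r@factorName, "")
    totCols <- which(cd$role == "total" & as.character(cd$factor) %in% facs)
    tot <- ripCounts(experiment)[, totCols, drop = FALSE]
    deep <- rowSums(tot > minTotalReads) == ncol(tot)
    genes[sig & deep]
}
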