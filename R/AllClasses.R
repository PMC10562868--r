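#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats cor dist rnorm rpois rnbinom rlnorm runif median quantile
#'   sd p.adjust phyper wilcox.test ks.test setNames cophenetic as.dist
#'   model.matrix ave
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' RipExperiment: paired IP/total RIP-seq count container
#'
#' A \linkS4class{SummarizedExperiment} holding a gene x sample matrix of raw
#' read counts (assay \code{"counts"}) together with the sample metadata the
#' paired enrichment test requires: for every immunoprecipitated factor and
#' replicate there must be exactly one IP sample and one matched total-extract
#' sample. Column data must contain \code{factor}, \code{replicate} and
#' \code{role} (one of \code{"IP"}, \code{"total"}).
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @export
setClass("RipExperiment", contains = "SummarizedExperiment")

.validRipExperiment <- function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    need <- c("factor", "replicate", "role")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
    if (!all(cd$role %in% c("IP", "total")))
        msg <- c(msg, "role must be 'IP' or 'total'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    key <- paste(cd$factor, cd$replicate)
    for (kk in unique(key)) {
        r <- cd$role[key == kk]
        if (sum(r == "IP") != 1L || sum(r == "total") != 1L)
            msg <- c(msg, paste0("factor/replicate pair '", kk,
                                 "' must have exactly one IP and one total sample"))
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("RipExperiment", .validRipExperiment)

#' Construct a RipExperiment from a count matrix and sample table
#'
#' @param counts gene x sample matrix of non-negative integer read counts;
#'   rownames are gene identifiers, colnames are sample identifiers.
#' @param samples data.frame with one row per column of \code{counts} and
#'   columns \code{factor}, \code{replicate}, \code{role}. Rownames (or a
#'   \code{sample_id} column) must match \code{colnames(counts)}.
#' @return A \linkS4class{RipExperiment}.
#' @examples
#' cnt <- matrix(rpois(40, 50), 10, 4,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' smp <- data.frame(factor = "Lsm1", replicate = rep(1:2, each = 2),
#'                   role = rep(c("IP", "total"), 2), row.names = paste0("s", 1:4))
#' re <- RipExperiment(cnt, smp)
#' @export
RipExperiment <- function(counts, samples) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    if (!is.null(samples$sample_id))
        rownames(samples) <- samples$sample_id
    if (!is.null(colnames(counts)))
        samples <- samples[colnames(counts), , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(samples))
    methods::new("RipExperiment", se)
}

#' @rdname RipExperiment
#' @param x a \code{RipExperiment}
#' @export
ripCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname RipExperiment
#' @export
factorNames <- function(x)
    unique(as.character(SummarizedExperiment::colData(x)$factor))

#' @rdname RipExperiment
#' @export
sampleRoles <- function(x) as.character(SummarizedExperiment::colData(x)$role)

#' SyntheticTruth: planted ground truth for a simulated RIP-seq study
#'
#' Holds the generative state of a simulation: which interaction-profile
#' cluster each gene belongs to, the cluster x factor matrix of planted mean
#' log2 fold changes, the per-gene realized LFCs (centers plus gene-level
#' Gaussian noise), and the expected total-extract abundance of each gene.
#'
#' @slot clusterLabels named integer vector, gene -> cluster in 1..k.
#' @slot centers numeric matrix, cluster x factor planted mean LFC (log2).
#' @slot geneLfc numeric matrix, gene x factor realized planted LFC (log2).
#' @slot baseline named numeric vector, expected total-sample mean count.
#' @slot seed integer seed the truth was generated from.
#' @export
setClass("SyntheticTruth",
    representation(clusterLabels = "integer", centers = "matrix",
                   geneLfc = "matrix", baseline = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- NULL
    k <- nrow(object@centers)
    if (any(is.na(object@clusterLabels)) ||
        any(object@clusterLabels < 1L) || any(object@clusterLabels > k))
        msg <- c(msg, "every gene must carry one cluster label in 1..k")
    if (k > 1 && anyDuplicated(apply(object@centers, 1, paste, collapse = ",")))
        msg <- c(msg, "center rows must be pairwise distinct")
    if (any(object@baseline <= 0))
        msg <- c(msg, "baseline abundances must be positive")
    if (nrow(object@geneLfc) != length(object@clusterLabels))
        msg <- c(msg, "geneLfc rows must match clusterLabels")
    if (is.null(msg)) TRUE else msg
})

#' TranscriptAnnotation: per-gene region lengths and sequences
#'
#' Stores 5'UTR, CDS and 3'UTR sequences for each synthetic transcript. The
#' CDS starts with ATG, ends with a stop codon and has length a multiple of 3.
#'
#' @slot utr5,cds,utr3 \code{DNAStringSet}s named by gene, parallel to each
#'   other.
#' @export
setClass("TranscriptAnnotation",
    representation(utr5 = "DNAStringSet", cds = "DNAStringSet",
                   utr3 = "DNAStringSet"))

setValidity("TranscriptAnnotation", function(object) {
    msg <- NULL
    n <- length(object@cds)
    if (length(object@utr5) != n || length(object@utr3) != n)
        msg <- c(msg, "utr5, cds and utr3 must be parallel")
    w <- Biostrings::width(object@cds)
    if (any(w %% 3L != 0L) || any(w < 6L))
        msg <- c(msg, "CDS lengths must be multiples of 3 and >= 6")
    if (n) {
        starts <- as.character(Biostrings::subseq(object@cds, 1L, 3L))
        stops <- as.character(Biostrings::subseq(object@cds, w - 2L, w))
        if (!all(starts == "ATG"))
            msg <- c(msg, "every CDS must begin with ATG")
        if (!all(stops %in% c("TAA", "TAG", "TGA")))
            msg <- c(msg, "every CDS must end with a stop codon")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname TranscriptAnnotation-class
#' @param x a \code{TranscriptAnnotation}
#' @return \code{regionLengths}: data.frame with per-gene utr5, cds, utr3 and
#'   total transcript lengths (nt).
#' @export
regionLengths <- function(x) {
    data.frame(gene = names(x@cds),
               utr5 = Biostrings::width(x@utr5),
               cds = Biostrings::width(x@cds),
               utr3 = Biostrings::width(x@utr3),
               transcript = Biostrings::width(x@utr5) +
                   Biostrings::width(x@cds) + Biostrings::width(x@utr3),
               row.names = NULL)
}

#' NBFit: negative-binomial dispersion fit for one factor's paired design
#'
#' @slot factorName factor the fit belongs to.
#' @slot design paired design matrix (replicate blocks + IP-role column).
#' @slot dispersionCommon common NB dispersion (phi, variance = mu + phi mu^2).
#' @slot dispersionTagwise per-gene moderated dispersions, clipped to [0, 10].
#' @slot priorDf shrinkage weight toward the common dispersion.
#' @slot normFactors,libSizes per-sample TMM factors and raw library sizes.
#' @slot fit internal model state reused by the enrichment test.
#' @export
setClass("NBFit",
    representation(factorName = "character", design = "matrix",
                   dispersionCommon = "numeric", dispersionTagwise = "numeric",
                   priorDf = "numeric", normFactors = "numeric",
                   libSizes = "numeric", fit = "ANY"))

#' EnrichmentResult: per-gene IP/total enrichment for one factor
#'
#' @slot factorName the immunoprecipitated factor.
#' @slot table \code{DataFrame} with columns \code{gene}, \code{lfc}
#'   (estimated log2(IP/total)), \code{p} (likelihood-ratio p-value),
#'   \code{fdr} (Benjamini-Hochberg within the factor), \code{tested}
#'   (whether the gene passed the expression floor).
#' @export
setClass("EnrichmentResult",
    representation(factorName = "character", table = "DataFrame"))

setValidity("EnrichmentResult", function(object) {
    tb <- object@table
    need <- c("gene", "lfc", "p", "fdr", "tested")
    if (!all(need %in% colnames(tb)))
        return(paste("table needs columns:", paste(need, collapse = ", ")))
    ok <- tb$tested & !is.na(tb$p)
    if (any(tb$fdr[ok] + 1e-12 < tb$p[ok]))
        return("FDR must be >= p")
    TRUE
})

#' ProfileMatrix: gene x factor LFC matrix over the filtered universe
#'
#' @slot lfc numeric matrix (log2 units); rownames = universe genes in filter
#'   order, colnames = factor names in declared order.
#' @export
setClass("ProfileMatrix", representation(lfc = "matrix"))

setValidity("ProfileMatrix", function(object) {
    if (is.null(rownames(object@lfc)) || is.null(colnames(object@lfc)))
        return("lfc must carry gene rownames and factor colnames")
    if (any(!is.finite(object@lfc)))
        return("lfc must be finite")
    TRUE
})

#' @rdname ProfileMatrix-class
#' @param x a \code{ProfileMatrix}
#' @export
lfcMatrix <- function(x) x@lfc

#' CorrelationMatrix: pairwise experiment similarity
#'
#' Pearson correlation R between factor LFC columns over the universe, its
#' elementwise square R2 (the quantity shown in pairwise heatmaps), and the
#' dissimilarity D = 1 - R used for hierarchical clustering of experiments.
#'
#' @slot R,R2,D factor x factor matrices.
#' @export
setClass("CorrelationMatrix",
    representation(R = "matrix", R2 = "matrix", D = "matrix"))

setValidity("CorrelationMatrix", function(object) {
    msg <- NULL
    if (max(abs(object@R - t(object@R))) > 1e-10)
        msg <- c(msg, "R must be symmetric")
    if (any(abs(diag(object@R) - 1) > 1e-10))
        msg <- c(msg, "R must have unit diagonal")
    if (any(object@R < -1 - 1e-10) || any(object@R > 1 + 1e-10))
        msg <- c(msg, "R must lie in [-1, 1]")
    if (max(abs(object@D - (1 - object@R))) > 1e-10)
        msg <- c(msg, "D must equal 1 - R")
    if (is.null(msg)) TRUE else msg
})

#' ClusterModel: k-means partition of interaction profiles
#'
#' @slot k number of clusters.
#' @slot labels named integer vector, gene -> cluster in 1..k; cluster IDs
#'   follow the UPGMA leaf order of the centers so numbering is reproducible.
#' @slot centers cluster x factor matrix of mean member LFCs.
#' @slot inertia total within-cluster sum of squares of the best start.
#' @slot tree UPGMA dendrogram (\code{hclust}) over 1 - Pearson(centers).
#' @slot seed,nStarts reproducibility record.
#' @export
setClass("ClusterModel",
    representation(k = "integer", labels = "integer", centers = "matrix",
                   inertia = "numeric", tree = "ANY", seed = "integer",
                   nStarts = "integer"))

#' TAIModel: tRNA adaptation index weights
#'
#' Absolute adaptiveness W_c = sum over codon-anticodon pairings of
#' (1 - s) * tGCN, relative weights w_c = W_c / max(W); codons with no
#' pairing receive the geometric mean of the nonzero weights.
#'
#' @slot tGCN named integer vector, anticodon (DNA, 5'->3') -> gene copies.
#' @slot s named numeric vector of wobble penalties per pairing class.
#' @slot W,w named numeric vectors over the 61 sense codons.
#' @slot wGeo geometric mean of nonzero relative weights.
#' @export
setClass("TAIModel",
    representation(tGCN = "numeric", s = "numeric", W = "numeric",
                   w = "numeric", wGeo = "numeric"))

setValidity("TAIModel", function(object) {
    if (any(object@w <= 0) || any(object@w > 1 + 1e-12))
        return("relative weights must lie in (0, 1] after zero replacement")
    if (any(names(object@w) %in% c("TAA", "TAG", "TGA")))
        return("stop codons must be excluded")
    TRUE
})

setMethod("show", "RipExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("RipExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  factors:", paste(unique(cd$factor), collapse = ", "), "\n")
    cat("  replicate pairs per factor:",
        paste(table(cd$factor[cd$role == "IP"]), collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@clusterLabels), "genes,",
        nrow(object@centers), "planted clusters,",
        ncol(object@centers), "factors (seed", object@seed, ")\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    tb <- object@table
    cat("EnrichmentResult for", object@factorName, "-",
        sum(tb$tested), "of", nrow(tb), "genes tested;",
        sum(tb$fdr < 0.01, na.rm = TRUE), "at FDR < 0.01\n")
})

setMethod("show", "ClusterModel", function(object) {
    cat("ClusterModel: k =", object@k, "over", length(object@labels),
        "genes; inertia", format(object@inertia, digits = 6), "\n")
    print(table(cluster = object@labels))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix over", nrow(object@R), "factors; R2 range [",
        format(min(object@R2), digits = 3), ",",
        format(max(object@R2[upper.tri(object@R2)]), digits = 3), "]\n")
})

setMethod("show", "TAIModel", function(object) {
    cat("TAIModel:", length(object@w), "sense codons; w in [",
        format(min(object@w), digits = 4), ", 1 ]\n")
})

#' @rdname EnrichmentResult-class
#' @param x an \code{EnrichmentResult}
#' @export
enrichmentTable <- function(x) x@table

#' @rdname ClusterModel-class
#' @param x a \code{ClusterModel}
#' @export
clusterLabels <- function(x) {
    if (methods::is(x, "ClusterModel")) x@labels else x@clusterLabels
}

#' @rdname ClusterModel-class
#' @export
clusterCenters <- function(x) x@centers
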