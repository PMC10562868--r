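#' Generate planted interaction-profile ground truth
#'
#' Draws a cluster x factor matrix of planted mean log2 fold changes, assigns
#' genes to clusters (sizes as equal as possible unless \code{clusterSizes}
#' is given), and realizes per-gene LFCs as the cluster center plus Gaussian
#' noise in log2 space. Center entries are drawn from
#' \{-centerSeparation, 0, +centerSeparation\}, redrawing until rows are
#' pairwise distinct and each cluster is enriched or depleted with at least a
#' quarter of the factors, so every planted cluster is detectable by the
#' enrichment stage.
#'
#' @param nGenes number of genes.
#' @param nFactors number of immunoprecipitated factors (columns).
#' @param k number of planted clusters; must satisfy \code{1 <= k <= nGenes}.
#' @param centerSeparation magnitude (log2 units) of nonzero center entries.
#' @param geneNoiseSd SD of the per-gene Gaussian perturbation of its center.
#' @param seed integer seed; the output is reproducible given the seed.
#' @param clusterSizes optional integer vector of length k summing to nGenes.
#' @param baselineMean,baselineLogSd lognormal parameters of the expected
#'   total-extract mean count per gene (median \code{baselineMean}).
#' @param factorNames optional factor names (default F01, F02, ...).
#' @return A \linkS4class{SyntheticTruth}.
#' @examples
#' tr <- generateTruth(nGenes = 100, nFactors = 4, k = 3, seed = 1)
#' table(clusterLabels(tr))
#' @export
generateTruth <- function(nGenes, nFactors, k = 7, centerSeparation = 2,
                          geneNoiseSd = 0.3, seed = 1, clusterSizes = NULL,
                          baselineMean = 200, baselineLogSd = 0.8,
                          factorNames = NULL) {
    if (k < 1 || k > nGenes)
        stop("k must lie in [1, nGenes]")
    if (centerSeparation < 0)
        stop("centerSeparation must be >= 0")
    if (centerSeparation == 0 && k > 1)
        stop("centerSeparation = 0 makes cluster centers coincide; use k = 1")
    if (is.null(factorNames))
        factorNames <- sprintf("F%02d", seq_len(nFactors))
    stopifnot(length(factorNames) == nFactors)
    set.seed(seed)

    minActive <- max(1L, ceiling(nFactors / 4))
    drawCenters <- function() {
        m <- matrix(sample(c(-1, 0, 1), k * nFactors, replace = TRUE,
                           prob = c(0.3, 0.4, 0.3)) * centerSeparation,
                    nrow = k)
        m
    }
    centers <- drawCenters()
    if (centerSeparation == 0) {
        centers[] <- 0
    } else {
        for (i in seq_len(200)) {
            active <- rowSums(centers != 0) >= minActive
            distinct <- !anyDuplicated(apply(centers, 1, paste, collapse = ","))
            if (all(active) && distinct) break
            redo <- which(!active)
            if (length(redo))
                centers[redo, ] <- drawCenters()[redo, , drop = FALSE]
            if (!distinct && !length(redo)) centers <- drawCenters()
        }
    }
    dimnames(centers) <- list(paste0("planted", seq_len(k)), factorNames)

    if (is.null(clusterSizes)) {
        base <- nGenes %/% k
        clusterSizes <- rep(base, k)
        extra <- nGenes - base * k
        if (extra > 0) clusterSizes[seq_len(extra)] <- base + 1L
    }
    if (length(clusterSizes) != k || sum(clusterSizes) != nGenes)
        stop("clusterSizes must have length k and sum to nGenes")
    labels <- rep(seq_len(k), times = clusterSizes)
    genes <- sprintf("gene%05d", seq_len(nGenes))
    names(labels) <- genes

    geneLfc <- centers[labels, , drop = FALSE] +
        matrix(rnorm(nGenes * nFactors, 0, geneNoiseSd), nGenes)
    dimnames(geneLfc) <- list(genes, factorNames)

    baseline <- rlnorm(nGenes, meanlog = log(baselineMean),
                       sdlog = baselineLogSd)
    names(baseline) <- genes

    methods::new("SyntheticTruth", clusterLabels = as.integer(labels) |>
                     setNames(genes), centers = centers, geneLfc = geneLfc,
                 baseline = baseline, seed = as.integer(seed))
}

#' @rdname SyntheticTruth-class
#' @param x a \code{SyntheticTruth}
#' @export
plantedLfc <- function(x) x@geneLfc

#' @rdname SyntheticTruth-class
#' @export
plantedCenters <- function(x) x@centers

#' @rdname SyntheticTruth-class
#' @export
baselineAbundance <- function(x) x@baseline

.sampleLengths <- function(spec, n) {
    if (is.function(spec)) {
        out <- spec(n)
    } else if (length(spec) == 1L) {
        out <- rep(spec, n)
    } else if (length(spec) == 2L) {
        # (meanlog-scale median, sdlog) lognormal lengths
        out <- round(rlnorm(n, meanlog = log(spec[1]), sdlog = spec[2]))
    } else stop("length spec must be a scalar, (median, sdlog) pair or function")
    out <- pmax(1L, as.integer(round(out)))
    if (any(out <= 0)) stop("length distributions must yield positive lengths")
    out
}

.senseCodons <- function() {
    bases <- c("A", "C", "G", "T")
    cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    sort(setdiff(cods, c("TAA", "TAG", "TGA")))
}

#' Generate synthetic transcript annotation and sequences
#'
#' Produces per-gene 5'UTR, CDS and 3'UTR sequences. UTR bases are sampled
#' i.i.d. from \code{composition}; CDSs begin with ATG, end with a stop codon
#' and use sense codons sampled with probability proportional to the product
#' of base probabilities. Clusters named in \code{aRichClusters} have the
#' adenosine probability of their 5'UTRs raised to the given value, either
#' over the whole UTR or only over \code{aRichWindow} positions upstream of
#' the start codon (position -1 is the base immediately 5' of the AUG).
#'
#' @param labels named integer vector, gene -> cluster (as from
#'   \code{\link{generateTruth}}).
#' @param lengths list with elements \code{utr5}, \code{cds}, \code{utr3};
#'   each a scalar (fixed length), a \code{(median, sdlog)} pair for
#'   lognormal lengths, or a \code{function(n)}. CDS lengths are rounded up
#'   to multiples of 3 and floored at 9 nt (start + 1 codon + stop).
#' @param composition named base probabilities (A, C, G, T) summing to 1.
#' @param aRichClusters named numeric vector: cluster id (as character) ->
#'   5'UTR adenosine probability for that cluster's genes.
#' @param aRichWindow integer vector of upstream offsets (e.g. \code{1:10}
#'   for positions -1..-10) to which the A boost is restricted; \code{NULL}
#'   boosts the whole 5'UTR.
#' @param seed integer seed.
#' @return A \linkS4class{TranscriptAnnotation}.
#' @export
generateAnnotation <- function(labels,
                               lengths = list(utr5 = c(60, 0.6),
                                              cds = c(450, 0.5),
                                              utr3 = c(120, 0.6)),
                               composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                               aRichClusters = NULL, aRichWindow = NULL,
                               seed = 1) {
    if (any(composition < 0) || any(composition > 1) ||
        abs(sum(composition) - 1) > 1e-8)
        stop("composition probabilities must lie in [0,1] and sum to 1")
    if (!is.null(aRichClusters) &&
        (any(aRichClusters < 0) || any(aRichClusters > 1)))
        stop("A-rich probabilities must lie in [0,1]")
    set.seed(seed)
    genes <- names(labels)
    n <- length(genes)
    bases <- c("A", "C", "G", "T")
    pr <- composition[bases]

    u5len <- .sampleLengths(lengths$utr5, n)
    u3len <- .sampleLengths(lengths$utr3, n)
    cdslen <- .sampleLengths(lengths$cds, n)
    cdslen <- pmax(9L, as.integer(ceiling(cdslen / 3) * 3))

    sampleSeq <- function(len, p) {
        paste(sample(bases, len, replace = TRUE, prob = p), collapse = "")
    }
    aProb <- function(g) {
        cl <- as.character(labels[[g]])
        if (!is.null(aRichClusters) && cl %in% names(aRichClusters))
            aRichClusters[[cl]] else NA_real_
    }
    boostedP <- function(pa) {
        rest <- pr[c("C", "G", "T")]
        c(A = pa, rest / sum(rest) * (1 - pa))[bases] |> setNames(bases)
    }

    utr5 <- character(n); utr3 <- character(n); cds <- character(n)
    sense <- .senseCodons()
    codonP <- vapply(strsplit(sense, ""), function(b) prod(pr[b]), 0)
    codonP <- codonP / sum(codonP)
    stops <- c("TAA", "TAG", "TGA")
    for (i in seq_len(n)) {
        pa <- aProb(genes[i])
        if (is.na(pa)) {
            utr5[i] <- sampleSeq(u5len[i], pr)
        } else if (is.null(aRichWindow)) {
            utr5[i] <- sampleSeq(u5len[i], boostedP(pa))
        } else {
            s <- strsplit(sampleSeq(u5len[i], pr), "")[[1]]
            off <- aRichWindow[aRichWindow <= u5len[i]]
            if (length(off)) {
                bp <- boostedP(pa)
                s[u5len[i] - off + 1L] <-
                    sample(bases, length(off), replace = TRUE, prob = bp)
            }
            utr5[i] <- paste(s, collapse = "")
        }
        utr3[i] <- sampleSeq(u3len[i], pr)
        nInternal <- cdslen[i] / 3L - 2L
        cds[i] <- paste0("ATG",
                         paste(sample(sense, nInternal, replace = TRUE,
                                      prob = codonP), collapse = ""),
                         sample(stops, 1))
    }
    methods::new("TranscriptAnnotation",
                 utr5 = Biostrings::DNAStringSet(setNames(utr5, genes)),
                 cds = Biostrings::DNAStringSet(setNames(cds, genes)),
                 utr3 = Biostrings::DNAStringSet(setNames(utr3, genes)))
}

#' Simulate paired IP/total RIP-seq counts
#'
#' For every factor and replicate one total and one IP sample are drawn.
#' Total counts are NB with mean libSize * baseline and dispersion phi
#' (variance mu + phi mu^2; phi = 0 degenerates to Poisson); IP counts use
#' mean libSize * baseline * 2^plantedLFC.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nReplicates replicate pairs per factor.
#' @param dispersion NB dispersion phi, scalar or per-gene vector, >= 0.
#' @param librarySizes per-sample relative depth factors: scalar, or named
#'   vector over the generated sample names; default 1 for all samples.
#' @param seed integer seed.
#' @return A \linkS4class{RipExperiment}; sample names are
#'   \code{<factor>_rep<r>_<role>}.
#' @export
simulateCounts <- function(truth, nReplicates = 3, dispersion = 0.1,
                           librarySizes = 1, seed = 1) {
    if (any(dispersion < 0)) stop("dispersion must be >= 0")
    if (any(librarySizes <= 0)) stop("library sizes must be positive")
    set.seed(seed)
    lfc <- truth@geneLfc
    facs <- colnames(lfc)
    genes <- rownames(lfc)
    nG <- length(genes)
    phi <- rep(dispersion, length.out = nG)

    grid <- expand.grid(role = c("total", "IP"),
                        replicate = seq_len(nReplicates), factor = facs,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("factor", "replicate", "role")]
    ids <- sprintf("%s_rep%d_%s", grid$factor, grid$replicate, grid$role)
    ls <- if (length(librarySizes) == 1L)
        setNames(rep(librarySizes, length(ids)), ids)
    else librarySizes[ids]
    if (any(is.na(ls))) stop("librarySizes must cover every sample name")

    drawNB <- function(mu) {
        poisLike <- phi == 0
        out <- numeric(nG)
        if (any(poisLike)) out[poisLike] <- rpois(sum(poisLike), mu[poisLike])
        if (any(!poisLike))
            out[!poisLike] <- rnbinom(sum(!poisLike),
                                      size = 1 / phi[!poisLike],
                                      mu = mu[!poisLike])
        out
    }
    counts <- matrix(0, nG, length(ids), dimnames = list(genes, ids))
    for (j in seq_along(ids)) {
        mu <- ls[j] * truth@baseline
        if (grid$role[j] == "IP") mu <- mu * 2^lfc[, grid$factor[j]]
        counts[, j] <- drawNB(mu)
    }
    RipExperiment(counts, data.frame(grid, row.names = ids))
}

#' Generate cluster-correlated per-gene property tables
#'
#' Draws each property independently per gene from a base distribution whose
#' location is shifted (in units of the base scale) for genes of designated
#' clusters, emulating external datasets such as RNA half-lives, ribosome
#' occupancies, SSU positional ratios, protein fractions or structure scores.
#'
#' @param labels named integer vector, gene -> cluster.
#' @param effectSpec named list, one element per property. Each element is a
#'   list with \code{base} ("lognormal" or "normal"), \code{location},
#'   \code{scale} (meanlog/sdlog for lognormal, mean/sd for normal) and
#'   optional \code{shift}: named numeric vector of location shifts in scale
#'   units, names = cluster ids.
#' @param seed integer seed.
#' @return data.frame with rownames = genes and one column per property.
#' @examples
#' tr <- generateTruth(60, 3, k = 2, seed = 2)
#' pt <- generatePropertyTables(clusterLabels(tr),
#'     list(half_life = list(base = "lognormal", location = log(20),
#'                           scale = 0.5, shift = c("2" = 1))), seed = 3)
#' @export
generatePropertyTables <- function(labels, effectSpec, seed = 1) {
    set.seed(seed)
    genes <- names(labels)
    n <- length(genes)
    out <- data.frame(row.names = genes)
    for (prop in names(effectSpec)) {
        sp <- effectSpec[[prop]]
        base <- if (is.null(sp$base)) "lognormal" else sp$base
        loc <- rep(sp$location, n)
        if (!is.null(sp$shift)) {
            bad <- setdiff(names(sp$shift), as.character(unique(labels)))
            if (length(bad))
                stop("effectSpec for '", prop, "' names unknown cluster(s): ",
                     paste(bad, collapse = ", "))
            for (cl in names(sp$shift))
                loc[labels == as.integer(cl)] <-
                    loc[labels == as.integer(cl)] + sp$shift[[cl]] * sp$scale
        }
        vals <- switch(base,
            lognormal = rlnorm(n, meanlog = loc, sdlog = sp$scale),
            normal = rnorm(n, mean = loc, sd = sp$scale),
            stop("unknown base distribution: ", base))
        out[[prop]] <- vals
    }
    out
}

#' Default property specification for the synthetic pipeline
#'
#' Cluster-correlated stand-ins for the external property datasets consumed
#' by the cluster characterization stage (half-life, ribosome occupancy, SSU
#' positional ratio, protein fraction, structure score). Directions mirror
#' the biology the pipeline is designed to expose: one heavily translated,
#' stable, protein-rich cluster and one repressed, short-lived cluster.
#'
#' @param k number of planted clusters.
#' @return effectSpec list suitable for \code{\link{generatePropertyTables}}.
#' @export
defaultPropertySpec <- function(k = 7) {
    hi <- as.character(min(5, k))   # heavily translated cluster
    lo <- as.character(min(6, k))   # repressed/decay cluster
    list(
        half_life = list(base = "lognormal", location = log(20), scale = 0.5,
                         shift = setNames(c(1, -1), c(hi, lo))),
        ribo_occupancy = list(base = "lognormal", location = 0, scale = 0.6,
                              shift = setNames(c(1.5, -1), c(hi, lo))),
        ssu_ratio = list(base = "lognormal", location = 0, scale = 0.4,
                         shift = setNames(c(-0.5), lo)),
        protein_fraction = list(base = "lognormal", location = log(1e-4),
                                scale = 1, shift = setNames(c(2), hi)),
        structure_gini = list(base = "normal", location = 0.5, scale = 0.08,
                              shift = setNames(c(-1), hi)))
}

#' Write a simulated study to plain-text files
#'
#' Emits counts.tsv (genes x samples), samples.tsv, transcripts.fa (records
#' \code{<gene>|utr5}, \code{<gene>|cds}, \code{<gene>|utr3}), annotation.gff3
#' (1-based inclusive transcript coordinates with five_prime_UTR / CDS /
#' three_prime_UTR features), properties.tsv and truth tables.
#'
#' @param dir output directory (created if absent).
#' @param truth,experiment,annotation,properties simulation components;
#'   any but \code{experiment} may be NULL to skip.
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(dir, experiment, truth = NULL, annotation = NULL,
                            properties = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wtsv <- function(df, name, rowLabel = "gene") {
        path <- file.path(dir, name)
        df <- data.frame(setNames(list(rownames(df)), rowLabel), df,
                         check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        files <<- c(files, path)
    }
    wtsv(as.data.frame(ripCounts(experiment)), "counts.tsv")
    smp <- as.data.frame(SummarizedExperiment::colData(experiment))
    wtsv(smp, "samples.tsv", rowLabel = "sample_id")
    if (!is.null(truth)) {
        wtsv(data.frame(cluster = truth@clusterLabels,
                        baseline = truth@baseline,
                        row.names = names(truth@clusterLabels)), "truth.tsv")
        wtsv(as.data.frame(truth@geneLfc), "truth_lfc.tsv")
        wtsv(as.data.frame(truth@centers), "truth_centers.tsv",
             rowLabel = "cluster")
    }
    if (!is.null(properties)) wtsv(properties, "properties.tsv")
    if (!is.null(annotation)) {
        seqs <- c(setNames(annotation@utr5,
                           paste0(names(annotation@utr5), "|utr5")),
                  setNames(annotation@cds,
                           paste0(names(annotation@cds), "|cds")),
                  setNames(annotation@utr3,
                           paste0(names(annotation@utr3), "|utr3")))
        fa <- file.path(dir, "transcripts.fa")
        Biostrings::writeXStringSet(seqs, fa)
        files <- c(files, fa)
        rl <- regionLengths(annotation)
        mk <- function(start, end, type, phase = NA_integer_)
            GenomicRanges::GRanges(rl$gene,
                IRanges::IRanges(start, end), strand = "+", type = type,
                phase = phase)
        gr <- c(mk(1L, rl$utr5, "five_prime_UTR"),
                mk(rl$utr5 + 1L, rl$utr5 + rl$cds, "CDS", phase = 0L),
                mk(rl$utr5 + rl$cds + 1L, rl$transcript, "three_prime_UTR"))
        gr <- gr[order(GenomicRanges::seqnames(gr),
                       GenomicRanges::start(gr))]
        gff <- file.path(dir, "annotation.gff3")
        rtracklayer::export(gr, gff, format = "gff3")
        files <- c(files, gff)
    }
    invisible(files)
}

#' Read a counts + sample-metadata pair written by \code{writeSimulation}
#'
#' @param countsFile,samplesFile TSV paths.
#' @return A \linkS4class{RipExperiment}.
#' @export
readRipExperiment <- function(countsFile, samplesFile) {
    cnt <- read.delim(countsFile, check.names = FALSE)
    rownames(cnt) <- cnt[[1]]
    cnt <- as.matrix(cnt[, -1, drop = FALSE])
    smp <- read.delim(samplesFile)
    rownames(smp) <- smp$sample_id
    RipExperiment(cnt, smp)
}
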