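#' Assemble the gene x factor LFC matrix over the filtered universe
#'
#' Rows follow the universe order, columns the order of \code{results}.
#' Genes that fell below the testing floor in some factor (no estimate)
#' receive LFC 0 there -- the neutral "no enrichment" imputation.
#'
#' @param results named list of \linkS4class{EnrichmentResult}.
#' @param universe character vector of gene ids (from
#'   \code{\link{filterTranscripts}}).
#' @return A \linkS4class{ProfileMatrix}.
#' @export
buildLfcMatrix <- function(results, universe) {
    mat <- matrix(0, length(universe), length(results),
                  dimnames = list(universe, names(results)))
    for (f in names(results)) {
        tb <- results[[f]]@table
        missing <- setdiff(universe, as.character(tb$gene))
        if (length(missing))
            stop("universe gene(s) absent from result set '", f, "': ",
                 paste(head(missing, 5), collapse = ", "))
        lfc <- setNames(tb$lfc, tb$gene)[universe]
        lfc[is.na(lfc)] <- 0
        mat[, f] <- lfc
    }
    methods::new("ProfileMatrix", lfc = mat)
}

#' Pairwise experiment correlation and dissimilarity
#'
#' Pearson correlation R between factor LFC columns over every universe
#' gene, R2 = R^2 (the pairwise-heatmap statistic) and the dissimilarity
#' D = 1 - R used to relate experiments by hierarchical clustering.
#'
#' @param profile a \linkS4class{ProfileMatrix} (or plain matrix).
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
pairwiseR2 <- function(profile) {
    m <- if (methods::is(profile, "ProfileMatrix")) profile@lfc else profile
    if (nrow(m) < 3) stop("at least 3 genes are required")
    v <- apply(m, 2, sd)
    if (any(v == 0))
        stop("zero-variance factor column(s): ",
             paste(colnames(m)[v == 0], collapse = ", "))
    R <- cor(m)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    methods::new("CorrelationMatrix", R = R, R2 = R^2, D = 1 - R)
}

#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Classic unweighted pair group method with arithmetic mean: iteratively
#' merge the closest pair of clusters, the distance from the merged node to
#' any other being the size-weighted mean of its parts; node height is the
#' merge distance. Ties break deterministically toward the pair with the
#' smallest original leaf indices, and the leaf order places the subtree
#' containing the smaller original index on the left.
#'
#' @param D symmetric non-negative matrix with zero diagonal (or
#'   \code{dist}).
#' @return An object of class \code{hclust} (method "average").
#' @examples
#' D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' h <- upgma(D)
#' h$height   # 2, 8
#' @export
upgma <- function(D) {
    if (inherits(D, "dist")) D <- as.matrix(D)
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        stop("D must be symmetric")
    if (any(diag(D) != 0)) stop("D must have a zero diagonal")
    n <- nrow(D)
    labs <- rownames(D)
    if (is.null(labs)) labs <- as.character(seq_len(n))
    if (n == 1)
        stop("need at least 2 items")

    size <- rep(1L, n)            # active cluster sizes
    id <- -seq_len(n)             # hclust merge coding: negatives are leaves
    minLeaf <- seq_len(n)         # smallest original index in each cluster
    ordList <- as.list(seq_len(n))
    d <- D
    merge <- matrix(0L, n - 1, 2)
    height <- numeric(n - 1)
    active <- rep(TRUE, n)

    for (step in seq_len(n - 1)) {
        act <- which(active)
        best <- c(NA, NA); bestD <- Inf
        for (ii in seq_along(act)) for (jj in seq_along(act)) {
            if (jj <= ii) next
            i <- act[ii]; j <- act[jj]
            dij <- d[i, j]
            better <- dij < bestD - 1e-15 ||
                (abs(dij - bestD) <= 1e-15 && !is.na(best[1]) &&
                 (pmin(minLeaf[i], minLeaf[j]) < pmin(minLeaf[best[1]], minLeaf[best[2]]) ||
                  (pmin(minLeaf[i], minLeaf[j]) == pmin(minLeaf[best[1]], minLeaf[best[2]]) &&
                   pmax(minLeaf[i], minLeaf[j]) < pmax(minLeaf[best[1]], minLeaf[best[2]]))))
            if (is.na(best[1]) || better) { best <- c(i, j); bestD <- dij }
        }
        i <- best[1]; j <- best[2]
        # left subtree = the one holding the smaller original leaf index
        if (minLeaf[j] < minLeaf[i]) { tmp <- i; i <- j; j <- tmp }
        merge[step, ] <- c(id[i], id[j])
        height[step] <- d[i, j]
        # size-weighted arithmetic mean to every other active cluster
        for (kk in which(active)) {
            if (kk == i || kk == j) next
            d[i, kk] <- d[kk, i] <-
                (size[i] * d[i, kk] + size[j] * d[j, kk]) / (size[i] + size[j])
        }
        size[i] <- size[i] + size[j]
        minLeaf[i] <- min(minLeaf[i], minLeaf[j])
        ordList[[i]] <- c(ordList[[i]], ordList[[j]])
        id[i] <- step
        active[j] <- FALSE
    }
    out <- list(merge = merge, height = height,
                order = ordList[[which(active)]], labels = labs,
                method = "average", call = match.call(),
                dist.method = "user-supplied")
    class(out) <- "hclust"
    out
}

#' Export a dendrogram as a Newick string or file
#'
#' @param h an \code{hclust} (e.g. from \code{\link{upgma}}).
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when writing to a file.
#' @export
asNewick <- function(h, file = NULL) {
    phy <- ape::as.phylo(h)
    if (is.null(file)) {
        ape::write.tree(phy)
    } else {
        ape::write.tree(phy, file = file)
        invisible(ape::write.tree(phy))
    }
}

.kppInit <- function(m, k) {
    n <- nrow(m)
    centers <- matrix(NA_real_, k, ncol(m))
    first <- sample.int(n, 1)
    centers[1, ] <- m[first, ]
    if (k > 1) {
        d2 <- rowSums((m - rep(centers[1, ], each = n))^2)
        for (c in 2:k) {
            pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
            nxt <- sample.int(n, 1, prob = pr)
            centers[c, ] <- m[nxt, ]
            d2 <- pmin(d2, rowSums((m - rep(centers[c, ], each = n))^2))
        }
    }
    centers
}

.assign <- function(m, centers) {
    # squared Euclidean via the expansion ||x||^2 - 2 x.c + ||c||^2
    cross <- m %*% t(centers)
    cn <- rowSums(centers^2)
    d2 <- matrix(rowSums(m^2), nrow(m), nrow(centers)) -
        2 * cross + matrix(cn, nrow(m), nrow(centers), byrow = TRUE)
    max.col(-d2, ties.method = "first")
}

.lloyd <- function(m, k, maxIter) {
    centers <- .kppInit(m, k)
    lab <- .assign(m, centers)
    for (it in seq_len(maxIter)) {
        for (c in seq_len(k)) {
            mem <- lab == c
            if (!any(mem)) {
                # reseed an empty cluster from the farthest point
                d2 <- rowSums((m - centers[lab, , drop = FALSE])^2)
                far <- which.max(d2)
                centers[c, ] <- m[far, ]
            } else {
                centers[c, ] <- colMeans(m[mem, , drop = FALSE])
            }
        }
        newLab <- .assign(m, centers)
        if (all(newLab == lab)) { lab <- newLab; break }
        lab <- newLab
    }
    for (c in seq_len(k))
        if (any(lab == c))
            centers[c, ] <- colMeans(m[lab == c, , drop = FALSE])
    inertia <- sum((m - centers[lab, , drop = FALSE])^2)
    list(labels = lab, centers = centers, inertia = inertia)
}

#' Partition genes into k interaction-profile clusters
#'
#' Lloyd's k-means with squared-Euclidean distance on the raw LFC rows,
#' k-means++ initialization, best of \code{nStarts} restarts by total
#' within-cluster sum of squares, and farthest-point reseeding of empty
#' clusters. Cluster IDs 1..k are relabeled to follow the UPGMA leaf order
#' of the centers under correlation distance, so the numbering is
#' reproducible across runs.
#'
#' @param profile a \linkS4class{ProfileMatrix} or numeric matrix.
#' @param k number of clusters (default 7).
#' @param nStarts independent restarts (default 50).
#' @param maxIter Lloyd iterations per start.
#' @param seed integer seed; the result is deterministic given it.
#' @param scaleRows scale rows to unit variance before clustering
#'   (default FALSE: raw LFCs).
#' @return A \linkS4class{ClusterModel}.
#' @export
kmeansClusters <- function(profile, k = 7, nStarts = 50, maxIter = 300,
                           seed = 1, scaleRows = FALSE) {
    m <- if (methods::is(profile, "ProfileMatrix")) profile@lfc else profile
    if (k > nrow(m)) stop("k exceeds the number of genes")
    if (scaleRows) {
        rs <- apply(m, 1, sd)
        m <- sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
    }
    set.seed(seed)
    best <- NULL
    for (s in seq_len(nStarts)) {
        fit <- .lloyd(m, k, maxIter)
        if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
    }
    centers <- best$centers
    labels <- best$labels

    if (k > 1) {
        # relabel by UPGMA leaf order of the centers (correlation distance,
        # falling back to scaled Euclidean when a center has no variance)
        ctr <- centers
        v <- apply(ctr, 1, sd)
        Dc <- if (all(v > 0) && ncol(ctr) > 1) 1 - cor(t(ctr))
              else as.matrix(dist(ctr)) / max(as.matrix(dist(ctr)), 1e-12)
        diag(Dc) <- 0
        dimnames(Dc) <- list(as.character(seq_len(k)), as.character(seq_len(k)))
        hc <- upgma(Dc)
        newOrder <- hc$order                  # old ids in leaf order
        remap <- integer(k); remap[newOrder] <- seq_len(k)
        labels <- remap[labels]
        centers <- centers[newOrder, , drop = FALSE]
        hc$labels <- as.character(remap[as.integer(hc$labels)])
        tree <- hc
    } else {
        tree <- NULL
    }
    rownames(centers) <- as.character(seq_len(k))
    colnames(centers) <- colnames(m)
    methods::new("ClusterModel", k = as.integer(k),
                 labels = setNames(as.integer(labels), rownames(m)),
                 centers = centers, inertia = best$inertia, tree = tree,
                 seed = as.integer(seed), nStarts = as.integer(nStarts))
}

#' Inertia and silhouette diagnostics across candidate k
#'
#' The number of clusters in the pipeline is a judgment call made on the
#' heatmap; this reports, per candidate k, the best-of-starts inertia and
#' the mean Euclidean silhouette width so the choice can be inspected. No
#' automatic selection is performed.
#'
#' @param profile a \linkS4class{ProfileMatrix} or matrix.
#' @param kRange integer vector of candidate k in [2, nGenes - 1].
#' @param nStarts,seed as in \code{\link{kmeansClusters}}.
#' @return data.frame with columns k, inertia, meanSilhouette.
#' @export
chooseKDiagnostics <- function(profile, kRange = 2:10, nStarts = 10,
                               seed = 1) {
    m <- if (methods::is(profile, "ProfileMatrix")) profile@lfc else profile
    stopifnot(all(kRange >= 2), all(kRange <= nrow(m) - 1))
    dm <- dist(m)
    out <- lapply(kRange, function(k) {
        cm <- kmeansClusters(m, k = k, nStarts = nStarts, seed = seed)
        sil <- cluster::silhouette(as.integer(cm@labels), dm)
        data.frame(k = k, inertia = cm@inertia,
                   meanSilhouette = mean(sil[, "sil_width"]))
    })
    do.call(rbind, out)
}
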