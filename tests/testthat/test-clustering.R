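mkRes <- function(factorName, genes, lfc, tested = TRUE) {
    methods::new("EnrichmentResult", factorName = factorName,
        table = S4Vectors::DataFrame(gene = genes, lfc = lfc,
            p = rep(0.5, length(genes)), fdr = rep(0.5, length(genes)),
            tested = rep(tested, length.out = length(genes))))
}

test_that("LFC matrix assembly is exact, order-equivariant and strict", {
    res <- list(A = mkRes("A", c("g1", "g2"), c(1.5, -2)),
                B = mkRes("B", c("g1", "g2"), c(0.25, 3)))
    pm <- buildLfcMatrix(res, c("g1", "g2"))
    expect_equal(unname(lfcMatrix(pm)),
                 matrix(c(1.5, -2, 0.25, 3), 2), tolerance = 0)

    pm2 <- buildLfcMatrix(res, c("g2", "g1"))
    expect_equal(lfcMatrix(pm2), lfcMatrix(pm)[c("g2", "g1"), ])

    # untested genes impute 0; absent genes are an error
    res$A@table$lfc[2] <- NA
    res$A@table$tested[2] <- FALSE
    expect_equal(unname(lfcMatrix(buildLfcMatrix(res, c("g1", "g2")))[2, "A"]), 0)
    expect_error(buildLfcMatrix(res, c("g1", "g3")), "g3")
})

test_that("pairwise correlation identities hold elementwise", {
    m <- cbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(2, 1, 3))
    rownames(m) <- paste0("g", 1:3)
    cm <- pairwiseR2(m)
    expect_equal(cm@R["A", "A"], 1)
    expect_equal(cm@D["A", "A"], 0)
    expect_equal(cm@R["A", "B"], -1, tolerance = 1e-12)
    expect_equal(cm@D["A", "B"], 2, tolerance = 1e-12)
    expect_lt(max(abs(cm@D - (1 - cm@R))), 1e-12)
    expect_lt(max(abs(cm@R2 - cm@R^2)), 1e-12)

    bad <- cbind(A = c(1, 1, 1), B = c(1, 2, 3))
    rownames(bad) <- paste0("g", 1:3)
    expect_error(pairwiseR2(bad), "A")
})

test_that("factors sharing planted structure correlate above independent ones", {
    wins <- vapply(1:20, function(s) {
        set.seed(s)
        lab <- rep(1:4, each = 50)
        ctr <- matrix(rnorm(4 * 2, 0, 2), 4)   # shared centers for A and B
        ctrC <- matrix(rnorm(4, 0, 2), 4)      # independent centers for C
        m <- cbind(A = ctr[lab, 1] + rnorm(200, 0, 0.5),
                   B = ctr[lab, 1] + rnorm(200, 0, 0.5),
                   C = ctrC[lab] + rnorm(200, 0, 0.5))
        rownames(m) <- sprintf("g%03d", 1:200)
        cm <- pairwiseR2(m)
        cm@R2["A", "B"] > cm@R2["A", "C"]
    }, NA)
    expect_true(all(wins))
})

test_that("UPGMA reproduces hand computations and the base case", {
    D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    h <- upgma(D)
    expect_equal(h$height, c(2, 8))
    expect_equal(h$merge[1, ], c(-1, -2))
    expect_equal(h$labels[h$order], c("A", "B", "C"))

    D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    h2 <- upgma(D2)
    expect_equal(h2$height, 3)

    Dn <- D; Dn[1, 2] <- 5
    expect_error(upgma(Dn), "symmetric")
})

test_that("UPGMA cophenetics are exact on ultrametric input and match hclust heights", {
    # 4-leaf ultrametric: ((A,B):2, (C,D):4):10
    U <- matrix(10, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    U["A", "B"] <- U["B", "A"] <- 2
    U["C", "D"] <- U["D", "C"] <- 4
    diag(U) <- 0
    h <- upgma(U)
    cp <- as.matrix(cophenetic(h))
    expect_equal(cp[LETTERS[1:4], LETTERS[1:4]], U, tolerance = 1e-12)

    # independent oracle: average-linkage hclust agrees on merge heights
    set.seed(5)
    m <- matrix(rnorm(60), 10)
    D <- as.matrix(dist(m))
    expect_equal(upgma(D)$height, stats::hclust(dist(m), "average")$height,
                 tolerance = 1e-10)
})

test_that("k-means separates planted structure and satisfies its identities", {
    set.seed(2)
    cloud <- rbind(matrix(rnorm(100, 10, 0.1), 50),
                   matrix(rnorm(100, -10, 0.1), 50))
    rownames(cloud) <- sprintf("g%03d", 1:100)
    truthLab <- rep(1:2, each = 50)
    cm <- kmeansClusters(cloud, k = 2, nStarts = 5, seed = 1)
    expect_equal(adjustedRand(clusterLabels(cm), truthLab), 1)

    # centers equal member means
    for (cl in 1:2) {
        mem <- clusterLabels(cm) == cl
        expect_equal(unname(clusterCenters(cm)[cl, ]),
                     unname(colMeans(cloud[mem, , drop = FALSE])),
                     tolerance = 1e-8)
    }

    # degenerate k = n
    cmN <- kmeansClusters(cloud[1:8, ], k = 8, nStarts = 3, seed = 2)
    expect_equal(cmN@inertia, 0, tolerance = 1e-12)
    expect_equal(sort(unique(clusterLabels(cmN))), 1:8)

    expect_error(kmeansClusters(cloud[1:3, ], k = 5), "exceeds")
})

test_that("planted seven-profile structure is recovered across seeds", {
    aris <- vapply(1:5, function(s) {
        tr <- generateTruth(700, 12, k = 7, centerSeparation = 2,
                            geneNoiseSd = 0.3, seed = s)
        cm <- kmeansClusters(plantedLfc(tr), k = 7, nStarts = 25, seed = s)
        adjustedRand(clusterLabels(cm), clusterLabels(tr))
    }, 0)
    expect_true(all(aris >= 0.8))
})

test_that("k-means is deterministic given the seed and label-permutation invariant", {
    tr <- generateTruth(200, 6, k = 4, centerSeparation = 2,
                        geneNoiseSd = 0.3, seed = 9)
    m <- plantedLfc(tr)
    a <- kmeansClusters(m, k = 4, nStarts = 10, seed = 3)
    b <- kmeansClusters(m, k = 4, nStarts = 10, seed = 3)
    expect_identical(clusterLabels(a), clusterLabels(b))

    perm <- sample(nrow(m))
    c2 <- kmeansClusters(m[perm, ], k = 4, nStarts = 10, seed = 3)
    # same partition as a set partition of gene names
    part <- function(lab) unname(lapply(split(names(lab), lab), sort))
    expect_setequal(part(clusterLabels(c2)), part(clusterLabels(a)))

    # matches the reference implementation's optimum on easy data
    km <- stats::kmeans(m, centers = 4, nstart = 25, iter.max = 100)
    expect_lte(a@inertia, km$tot.withinss * (1 + 1e-6))
})

test_that("k diagnostics surface the planted k and expose null structure", {
    tr <- generateTruth(210, 8, k = 7, centerSeparation = 4,
                        geneNoiseSd = 0.2, seed = 13)
    diag7 <- chooseKDiagnostics(plantedLfc(tr), kRange = 2:9, nStarts = 10,
                                seed = 1)
    expect_equal(diag7$k[which.max(diag7$meanSilhouette)], 7)
    expect_true(all(diff(diag7$inertia) <= 1e-8))

    trNull <- generateTruth(150, 8, k = 1, centerSeparation = 2,
                            geneNoiseSd = 0.5, seed = 14)
    diag1 <- chooseKDiagnostics(plantedLfc(trNull), kRange = 2, nStarts = 10,
                                seed = 1)
    expect_lt(diag1$meanSilhouette, 0.25)
})

test_that("cluster numbering follows the center dendrogram leaf order", {
    tr <- generateTruth(300, 10, k = 5, centerSeparation = 2,
                        geneNoiseSd = 0.2, seed = 21)
    cm <- kmeansClusters(plantedLfc(tr), k = 5, nStarts = 20, seed = 4)
    expect_false(is.null(cm@tree))
    leaf <- as.integer(cm@tree$labels[cm@tree$order])
    expect_equal(leaf, 1:5)
    # tree distances match 1 - Pearson of the relabeled centers
    Dc <- 1 - cor(t(clusterCenters(cm)))
    h2 <- upgma(Dc)
    expect_equal(cm@tree$height, h2$height, tolerance = 1e-10)
})
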