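test_that("zero-noise truth reproduces its centers exactly and degenerate k collapses", {
    tr <- generateTruth(nGenes = 7, nFactors = 2, k = 7,
                        centerSeparation = 2, geneNoiseSd = 0, seed = 1)
    expect_equal(sort(unique(clusterLabels(tr))), 1:7)
    expect_equal(unname(table(clusterLabels(tr))), rep(1L, 7),
                 ignore_attr = TRUE)
    expect_equal(unname(plantedLfc(tr)),
                 unname(plantedCenters(tr)[clusterLabels(tr), ]))

    tr1 <- generateTruth(nGenes = 50, nFactors = 3, k = 1,
                         centerSeparation = 2, geneNoiseSd = 0, seed = 2)
    expect_true(all(clusterLabels(tr1) == 1L))
    expect_equal(max(apply(plantedLfc(tr1), 2, var)), 0)

    expect_error(generateTruth(nGenes = 3, nFactors = 2, k = 5), "k must")
    expect_error(generateTruth(10, 2, k = 2, centerSeparation = 0), "k = 1")
})

test_that("per-cluster mean LFC concentrates on the planted center", {
    tr <- generateTruth(nGenes = 1000, nFactors = 12, k = 7,
                        centerSeparation = 2, geneNoiseSd = 0.3, seed = 7)
    lab <- clusterLabels(tr)
    for (cl in 1:7) {
        mem <- names(lab)[lab == cl]
        emp <- colMeans(plantedLfc(tr)[mem, , drop = FALSE])
        bound <- 3 * 0.3 / sqrt(length(mem))
        expect_true(all(abs(emp - plantedCenters(tr)[cl, ]) < bound),
                    info = paste("cluster", cl))
    }
})

test_that("identical seeds give bit-identical simulations", {
    a <- generateTruth(100, 4, k = 3, seed = 42)
    b <- generateTruth(100, 4, k = 3, seed = 42)
    expect_identical(plantedLfc(a), plantedLfc(b))
    expect_identical(baselineAbundance(a), baselineAbundance(b))
    ea <- simulateCounts(a, nReplicates = 2, dispersion = 0.1, seed = 9)
    eb <- simulateCounts(b, nReplicates = 2, dispersion = 0.1, seed = 9)
    expect_identical(ripCounts(ea), ripCounts(eb))
    expect_false(identical(ripCounts(ea),
                           ripCounts(simulateCounts(a, 2, 0.1, seed = 10))))
})

test_that("annotation composition controls hold, degenerate and stochastic", {
    lab <- setNames(rep(1:2, each = 50), sprintf("g%03d", 1:100))
    ann <- generateAnnotation(lab, aRichClusters = c("2" = 1.0), seed = 3)
    u5 <- ann@utr5[names(lab)[lab == 2]]
    af <- Biostrings::letterFrequency(u5, "A")[, 1]
    expect_equal(af, Biostrings::width(u5), ignore_attr = TRUE)

    # uniform composition: genome-wide 5'UTR A fraction within binomial 99% CI
    ann2 <- generateAnnotation(lab, seed = 4)
    a <- sum(Biostrings::letterFrequency(ann2@utr5, "A"))
    tot <- sum(Biostrings::width(ann2@utr5))
    se <- sqrt(0.25 * 0.75 / tot)
    expect_lt(abs(a / tot - 0.25), 2.58 * se)

    ann3 <- generateAnnotation(lab, lengths = list(utr5 = 50, cds = 300,
                                                   utr3 = 100), seed = 5)
    expect_true(all(regionLengths(ann3)$transcript == 450))
    expect_true(all(substr(as.character(ann3@cds), 1, 3) == "ATG"))

    expect_error(generateAnnotation(lab, composition = c(A = 0.5, C = 0.5,
                                                         G = 0.5, T = -0.5)),
                 "composition")
})

test_that("simulated counts match their NB/Poisson generative contract", {
    # null configuration: per-gene log2(IP/total) concentrated at 0
    tr <- generateTruth(500, 1, k = 1, centerSeparation = 0, geneNoiseSd = 0,
                        seed = 1, baselineMean = 1e4, baselineLogSd = 0)
    ex <- simulateCounts(tr, nReplicates = 1, dispersion = 0, seed = 2)
    cnt <- ripCounts(ex)
    lr <- log2((cnt[, 2] + 0.5) / (cnt[, 1] + 0.5))
    expect_lt(abs(median(lr)), 0.05)

    # a planted +2 gene recovers its ratio under Poisson concentration
    tr2 <- generateTruth(50, 1, k = 2, centerSeparation = 2, geneNoiseSd = 0,
                         seed = 3, baselineMean = 1e4, baselineLogSd = 0)
    tr2@geneLfc[] <- 0
    tr2@geneLfc[1, 1] <- 2
    ex2 <- simulateCounts(tr2, nReplicates = 1, dispersion = 0, seed = 4)
    ip <- ripCounts(ex2)[1, grepl("_IP$", colnames(ripCounts(ex2)))]
    tot <- ripCounts(ex2)[1, grepl("_total$", colnames(ripCounts(ex2)))]
    expect_lt(abs(log2(ip / tot) - 2), 0.1)

    # doubling a library size doubles that column's expected sum
    tr3 <- generateTruth(5000, 1, k = 1, centerSeparation = 0,
                         geneNoiseSd = 0, seed = 5, baselineMean = 100)
    ids <- c("F01_rep1_total", "F01_rep1_IP")
    ex3 <- simulateCounts(tr3, nReplicates = 1, dispersion = 0,
                          librarySizes = setNames(c(1, 1), ids), seed = 6)
    ex4 <- simulateCounts(tr3, nReplicates = 1, dispersion = 0,
                          librarySizes = setNames(c(2, 1), ids), seed = 6)
    ratio <- sum(ripCounts(ex4)[, 1]) / sum(ripCounts(ex3)[, 1])
    expect_lt(abs(ratio - 2), 0.02)

    # phi = 0 matches Poisson moments
    tr4 <- generateTruth(1e5, 1, k = 1, centerSeparation = 0, geneNoiseSd = 0,
                         seed = 7, baselineMean = 50, baselineLogSd = 0)
    ex5 <- simulateCounts(tr4, nReplicates = 1, dispersion = 0, seed = 8)
    x <- ripCounts(ex5)[, 1]
    expect_lt(abs(var(x) / mean(x) - 1), 0.02)

    expect_error(simulateCounts(tr4, dispersion = -1), "dispersion")
    expect_error(simulateCounts(tr4, librarySizes = -2), "positive")
})

test_that("naive LFC estimates recover the planted profile", {
    tr <- generateTruth(300, 4, k = 3, centerSeparation = 2,
                        geneNoiseSd = 0.3, seed = 11, baselineMean = 500,
                        baselineLogSd = 0)
    ex <- simulateCounts(tr, nReplicates = 3, dispersion = 0.05, seed = 12)
    cnt <- ripCounts(ex)
    cd <- SummarizedExperiment::colData(ex)
    for (f in factorNames(ex)[1:2]) {
        ip <- cnt[, cd$factor == f & cd$role == "IP", drop = FALSE]
        tot <- cnt[, cd$factor == f & cd$role == "total", drop = FALSE]
        naive <- rowMeans(log2((ip + 0.5) / (tot + 0.5)))
        expect_gt(cor(naive, plantedLfc(tr)[, f]), 0.95)
    }
})

test_that("property tables carry their planted location shifts", {
    lab <- setNames(rep(1:4, each = 200), sprintf("g%04d", 1:800))
    # recoverable +3 SD shift
    up <- lapply(1:10, function(s) {
        pt <- generatePropertyTables(lab, list(
            te = list(base = "normal", location = 0, scale = 1,
                      shift = c("3" = 3))), seed = s)
        v <- setNames(pt$te, rownames(pt))
        median(v[lab == 3]) > median(v)
    })
    expect_true(all(unlist(up)))

    # null shift: Mann-Whitney rejections near nominal
    set.seed(1)
    ps <- replicate(200, {
        pt <- generatePropertyTables(lab[1:80], list(
            te = list(base = "normal", location = 0, scale = 1)),
            seed = sample.int(1e6, 1))
        v <- setNames(pt$te, rownames(pt))
        suppressWarnings(wilcox.test(v[lab[1:80] == 1], v)$p.value)
    })
    rate <- mean(ps < 0.05)
    expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))

    # degenerate scale: all values tie, U = n1 n2 / 2 under midranks
    pt0 <- generatePropertyTables(lab, list(
        hl = list(base = "lognormal", location = log(5), scale = 0)), seed = 2)
    v0 <- setNames(pt0$hl, rownames(pt0))
    cmp <- compareProperty(v0, lab, "hl")
    expect_equal(cmp$U, cmp$n * (length(v0) - 0) / 2, tolerance = 1e-12)
    expect_true(all(cmp$p == 1))

    expect_error(generatePropertyTables(lab, list(
        te = list(base = "normal", location = 0, scale = 1,
                  shift = c("9" = 1)))), "unknown cluster")
})
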