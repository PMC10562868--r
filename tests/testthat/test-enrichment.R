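test_that("TMM effective library sizes honor identity and pure depth changes", {
    set.seed(1)
    a <- rpois(400, 100)
    cnt <- cbind(s1 = a, s2 = a)
    ls <- normalizeLibSizes(cnt)
    expect_equal(unname(attr(ls, "normFactors")), c(1, 1), tolerance = 1e-8)

    cnt2 <- cbind(s1 = a, s2 = 2L * a)
    ls2 <- normalizeLibSizes(cnt2)
    nf <- attr(ls2, "normFactors")
    expect_equal(unname(nf[1]), unname(nf[2]), tolerance = 1e-8)
    expect_equal(unname(ls2[2] / ls2[1]), 2, tolerance = 1e-8)

    cnt3 <- cbind(s1 = a, s2 = rep(0L, 400))
    expect_error(normalizeLibSizes(cnt3), "s2")
})

test_that("TMM factors agree with an independent trimmed-mean reimplementation", {
    set.seed(7)
    n <- 500
    base <- rlnorm(n, log(100), 1)
    de <- seq_len(n) <= 25                      # 5% DE genes, 4-fold up in s2
    cnt <- cbind(s1 = rpois(n, base),
                 s2 = rpois(n, base * ifelse(de, 4, 1) * 1.3))
    nf <- attr(normalizeLibSizes(cnt), "normFactors")
    expect_equal(unname(nf), unname(oracleTMM(cnt)), tolerance = 0.05)
})

test_that("dispersion estimation recovers known truth and obeys its limits", {
    tr <- generateTruth(2000, 1, k = 1, centerSeparation = 0, geneNoiseSd = 0,
                        seed = 1, baselineMean = 200)
    exPois <- simulateCounts(tr, nReplicates = 3, dispersion = 0, seed = 2)
    fitP <- estimateDispersion(exPois, "F01")
    expect_lt(fitP@dispersionCommon, 0.01)

    tr2 <- generateTruth(2000, 1, k = 1, centerSeparation = 0, geneNoiseSd = 0,
                         seed = 3, baselineMean = 300, baselineLogSd = 0.4)
    ex2 <- simulateCounts(tr2, nReplicates = 3, dispersion = 0.2, seed = 4)
    fit2 <- estimateDispersion(ex2, "F01")
    expect_gt(fit2@dispersionCommon, 0.15)
    expect_lt(fit2@dispersionCommon, 0.25)

    fitInf <- estimateDispersion(ex2, "F01", priorDf = Inf)
    expect_equal(unname(fitInf@dispersionTagwise),
                 rep(fitInf@dispersionCommon,
                     length(fitInf@dispersionTagwise)), tolerance = 1e-8)

    ex1 <- simulateCounts(tr2, nReplicates = 1, dispersion = 0.2, seed = 5)
    expect_error(estimateDispersion(ex1, "F01"), "single replicate")
})

test_that("identity IP/total pairs give exactly zero LFC", {
    set.seed(11)
    tot <- matrix(rpois(600, 80), 200)
    cnt <- cbind(tot[, 1], tot[, 1], tot[, 2], tot[, 2], tot[, 3], tot[, 3])
    rownames(cnt) <- sprintf("g%03d", 1:200)
    ex <- makePairedExperiment(cnt)
    res <- testEnrichment(ex, "Fx")
    tb <- enrichmentTable(res)
    expect_true(all(abs(tb$lfc[tb$tested]) < 1e-8))
})

test_that("null simulation is calibrated and planted enrichment is recovered", {
    trNull <- generateTruth(2000, 1, k = 1, centerSeparation = 0,
                            geneNoiseSd = 0, seed = 21, baselineMean = 200)
    exNull <- simulateCounts(trNull, nReplicates = 3, dispersion = 0.1,
                             seed = 22)
    tb <- enrichmentTable(testEnrichment(exNull, "F01"))
    p <- tb$p[tb$tested]
    expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
    expect_lte(mean(tb$fdr[tb$tested] < 0.01), 0.02)

    # balanced strata of planted enrichment (a global shift would be --
    # correctly -- absorbed by normalization, so strata must coexist)
    trAlt <- generateTruth(500, 1, k = 1, centerSeparation = 0,
                           geneNoiseSd = 0, seed = 23, baselineMean = 1000,
                           baselineLogSd = 0)
    strata <- rep(c(-2, 0, 2), length.out = 500)
    trAlt@geneLfc[] <- strata
    exAlt <- simulateCounts(trAlt, nReplicates = 3, dispersion = 0.05,
                            seed = 24)
    tbA <- enrichmentTable(testEnrichment(exAlt, "F01"))
    for (s in c(-2, 0, 2)) {
        med <- median(tbA$lfc[tbA$tested & strata == s])
        expect_lt(abs(med - s), 0.2)
    }
})

test_that("swapping IP and total roles negates LFC and preserves p-values", {
    tr <- generateTruth(300, 1, k = 2, centerSeparation = 2, geneNoiseSd = 0.2,
                        seed = 31, baselineMean = 150)
    ex <- simulateCounts(tr, nReplicates = 3, dispersion = 0.1, seed = 32)
    tb1 <- enrichmentTable(testEnrichment(ex, "F01"))
    cd <- SummarizedExperiment::colData(ex)
    cd$role <- ifelse(cd$role == "IP", "total", "IP")
    exSwap <- RipExperiment(ripCounts(ex), as.data.frame(cd))
    tb2 <- enrichmentTable(testEnrichment(exSwap, "F01"))
    ok <- tb1$tested & tb2$tested
    expect_equal(tb1$lfc[ok], -tb2$lfc[ok], tolerance = 1e-6)
    expect_equal(tb1$p[ok], tb2$p[ok], tolerance = 1e-6)

    expect_error(testEnrichment(ex, "nosuch"), "absent")
})

test_that("transcript filtering applies the FDR and total-reads rules", {
    cnt <- matrix(30L, 4, 4,
                  dimnames = list(paste0("g", 1:4), NULL))
    cnt[3, 1] <- 15L  # one shallow total sample for g3
    ex <- makePairedExperiment(cnt, "A")

    mkRes <- function(factorName, fdr) {
        tb <- S4Vectors::DataFrame(gene = paste0("g", 1:4),
                                   lfc = rep(1, 4), p = fdr, fdr = fdr,
                                   tested = TRUE)
        methods::new("EnrichmentResult", factorName = factorName, table = tb)
    }
    resA <- mkRes("A", c(0.005, 0.02, 0.001, 0.5))
    resB <- mkRes("B", c(0.5, 0.03, 0.5, 0.5))
    # factor B has no samples in ex; restrict to factor A's totals
    keep <- filterTranscripts(list(A = resA, B = resB), ex)
    # g1: significant + deep -> kept; g2: min FDR 0.02 -> dropped;
    # g3: FDR 0.001 but one total sample at 15 <= 20 -> dropped; g4: ns.
    expect_identical(keep, "g1")

    # count of exactly 20 fails the strict rule
    cnt20 <- matrix(21L, 2, 4, dimnames = list(c("g1", "g2"), NULL))
    cnt20[1, 3] <- 20L
    ex20 <- makePairedExperiment(cnt20, "A")
    res20 <- methods::new("EnrichmentResult", factorName = "A",
        table = S4Vectors::DataFrame(gene = c("g1", "g2"),
            lfc = c(1, 1), p = c(0.001, 0.001), fdr = c(0.001, 0.001),
            tested = TRUE))
    expect_identical(filterTranscripts(list(A = res20), ex20), "g2")
})

test_that("BH adjustment within a factor is monotone and bounded by p", {
    tr <- generateTruth(400, 1, k = 2, centerSeparation = 2, geneNoiseSd = 0.3,
                        seed = 41, baselineMean = 100)
    ex <- simulateCounts(tr, nReplicates = 2, dispersion = 0.15, seed = 42)
    tb <- enrichmentTable(testEnrichment(ex, "F01"))
    tb <- tb[tb$tested, ]
    ord <- order(tb$p)
    expect_true(all(diff(tb$fdr[ord]) >= -1e-12))
    expect_true(all(tb$fdr >= tb$p - 1e-12))
    expect_true(all(tb$fdr <= 1))
})

test_that("scaling a column and its library size together leaves results unchanged", {
    tr <- generateTruth(300, 1, k = 2, centerSeparation = 2, geneNoiseSd = 0.2,
                        seed = 51, baselineMean = 200)
    ex <- simulateCounts(tr, nReplicates = 3, dispersion = 0.1, seed = 52)
    cnt <- ripCounts(ex)
    tb1 <- enrichmentTable(testEnrichment(ex, "F01"))
    # multiply one sample by an integer c: with TMM recomputed the effective
    # size scales by c, so LFC and p are invariant up to normalization noise
    cnt2 <- cnt; cnt2[, 3] <- cnt2[, 3] * 4L
    ex2 <- RipExperiment(cnt2,
        as.data.frame(SummarizedExperiment::colData(ex)))
    tb2 <- enrichmentTable(testEnrichment(ex2, "F01"))
    ok <- tb1$tested & tb2$tested
    expect_gt(cor(tb1$lfc[ok], tb2$lfc[ok]), 0.999)
    expect_lt(median(abs(tb1$lfc[ok] - tb2$lfc[ok])), 0.02)
})
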