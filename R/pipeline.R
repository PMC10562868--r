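.defaultConfig <- function() {
    list(
        # simulation (study conditions of the desk-scale design)
        n_genes = 2000L, n_factors = 12L, n_replicates = 3L, k_truth = 7L,
        center_separation = 2, gene_noise_sd = 0.3, dispersion = 0.1,
        baseline_mean = 200,
        # enrichment / filtering
        fdr_max = 0.01, min_total_reads = 20, prior_df = 10,
        expression_floor = 1,
        # clustering
        k = 7L, n_starts = 50L, scale_rows = FALSE,
        # properties / overlaps
        significance = 0.05, n_draws = 1e6, min_coverage = 25,
        max_depth = 50,
        # input files (optional; when counts/samples are given the simulate
        # stage is skipped)
        counts = NULL, samples = NULL, properties = NULL,
        # output
        outdir = "ripclust_run")
}

#' Validate a pipeline configuration
#'
#' Fills defaults (FDR < 0.01, > 20 reads per total sample, k = 7,
#' significance 0.05, 1e6 Monte-Carlo draws), rejects unknown keys and
#' checks types, positivity and that referenced input files exist.
#'
#' @param config path to a YAML file, or a named list (possibly empty).
#' @return the completed configuration list.
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
        if (is.null(config)) config <- list()
    }
    def <- .defaultConfig()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- def
    cfg[names(config)] <- config
    numKeys <- c("n_genes", "n_factors", "n_replicates", "k_truth",
                 "center_separation", "gene_noise_sd", "dispersion",
                 "baseline_mean", "fdr_max", "min_total_reads", "prior_df",
                 "expression_floor", "k", "n_starts", "significance",
                 "n_draws", "min_coverage", "max_depth")
    for (key in numKeys) {
        v <- cfg[[key]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v))
            stop("configuration key '", key, "' must be a single number")
    }
    pos <- c("n_genes", "n_factors", "n_replicates", "k_truth", "fdr_max",
             "min_total_reads", "k", "n_starts", "significance", "n_draws")
    for (key in pos)
        if (cfg[[key]] <= 0) stop("configuration key '", key,
                                  "' must be positive")
    if (cfg$fdr_max > 1 || cfg$significance > 1)
        stop("fdr_max and significance must lie in (0, 1]")
    for (key in c("counts", "samples", "properties")) {
        v <- cfg[[key]]
        if (!is.null(v) && !file.exists(v))
            stop("configured file for '", key, "' does not exist: ", v)
    }
    if (xor(is.null(cfg$counts), is.null(cfg$samples)))
        stop("counts and samples must be given together")
    cfg
}

#' Derive a reproducible per-stage seed from the global seed
#'
#' A fixed multiplicative hash of (global seed, stage name); stages can be
#' rerun independently yet reproducibly, and derived seeds stay below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
    h <- as.numeric(seed) %% 2147483647
    for (ch in utf8ToInt(stage))
        h <- (h * 131 + ch) %% 2147483647
    as.integer(h)
}

.stageRecord <- function(name, seed, files, t0) {
    files <- files[file.exists(files)]
    list(stage = name, seed = seed,
         outputs = as.list(setNames(unname(tools::md5sum(files)),
                                    basename(files))),
         elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
}

#' Run the full pipeline
#'
#' simulate (unless counts are supplied) -> enrich -> filter -> cluster ->
#' properties -> tai -> overlap. Every stage writes plain-text outputs under
#' \code{config$outdir} so it can be rerun independently, and the returned
#' manifest records per-stage seeds and output checksums; identical config
#' and seed reproduce identical checksums.
#'
#' @param config list or YAML path (see \code{\link{validateConfig}}).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @return the run manifest (also written to \code{manifest.json}).
#' @export
runAll <- function(config = list(), seed = 1) {
    cfg <- validateConfig(config)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(tool = "ripclust",
                     version = as.character(packageVersion("ripclust")),
                     seed = seed, config = cfg,
                     started = format(Sys.time(), usetz = TRUE),
                     stages = list())
    note <- function(...) message("[ripclust] ", ...)
    addStage <- function(rec) manifest$stages[[rec$stage]] <<- rec

    # --- simulate -----------------------------------------------------
    t0 <- as.numeric(Sys.time())
    sSeed <- stageSeed(seed, "simulate")
    truth <- NULL; annotation <- NULL; properties <- NULL
    if (is.null(cfg$counts)) {
        note("simulate: ", cfg$n_genes, " genes x ", cfg$n_factors,
             " factors x ", cfg$n_replicates, " pairs")
        truth <- generateTruth(cfg$n_genes, cfg$n_factors, k = cfg$k_truth,
                               centerSeparation = cfg$center_separation,
                               geneNoiseSd = cfg$gene_noise_sd,
                               seed = sSeed, baselineMean = cfg$baseline_mean)
        experiment <- simulateCounts(truth, nReplicates = cfg$n_replicates,
                                     dispersion = cfg$dispersion,
                                     seed = stageSeed(seed, "counts"))
        annotation <- generateAnnotation(
            clusterLabels(truth),
            aRichClusters = setNames(0.5, as.character(min(5, cfg$k_truth))),
            seed = stageSeed(seed, "annotation"))
        properties <- generatePropertyTables(
            clusterLabels(truth), defaultPropertySpec(cfg$k_truth),
            seed = stageSeed(seed, "properties"))
        writeSimulation(cfg$outdir, experiment, truth, annotation, properties)
        addStage(.stageRecord("simulate", sSeed,
            file.path(cfg$outdir, c("counts.tsv", "samples.tsv", "truth.tsv",
                                    "truth_lfc.tsv", "truth_centers.tsv",
                                    "properties.tsv", "transcripts.fa",
                                    "annotation.gff3")), t0))
    } else {
        note("loading counts from ", cfg$counts)
        experiment <- readRipExperiment(cfg$counts, cfg$samples)
        if (!is.null(cfg$properties)) {
            properties <- read.delim(cfg$properties)
            rownames(properties) <- properties[[1]]
            properties <- properties[, -1, drop = FALSE]
        }
        addStage(.stageRecord("simulate", NA, character(0), t0))
    }

    # --- enrich -------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    note("enrich: paired NB test per factor")
    results <- testAllFactors(experiment, priorDf = cfg$prior_df,
                              expressionFloor = cfg$expression_floor)
    enrichFiles <- character(0)
    for (f in names(results)) {
        path <- file.path(cfg$outdir, paste0("enrichment_", f, ".tsv"))
        write.table(as.data.frame(results[[f]]@table), path, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        enrichFiles <- c(enrichFiles, path)
    }
    addStage(.stageRecord("enrich", NA, enrichFiles, t0))

    # --- filter -------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    universe <- filterTranscripts(results, experiment, fdrMax = cfg$fdr_max,
                                  minTotalReads = cfg$min_total_reads)
    note("filter: ", length(universe), " transcripts in the universe")
    if (!length(universe)) stop("stage 'filter' failed: empty universe")
    uniPath <- file.path(cfg$outdir, "universe.txt")
    writeLines(universe, uniPath)
    addStage(.stageRecord("filter", NA, uniPath, t0))

    # --- cluster ------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    cSeed <- stageSeed(seed, "cluster")
    profile <- buildLfcMatrix(results, universe)
    corr <- pairwiseR2(profile)
    expTree <- upgma(corr@D)
    model <- kmeansClusters(profile, k = cfg$k, nStarts = cfg$n_starts,
                            seed = cSeed, scaleRows = cfg$scale_rows)
    note("cluster: k = ", cfg$k, ", inertia ",
         format(model@inertia, digits = 6))
    wm <- function(mat, name, rowLabel = "gene") {
        path <- file.path(cfg$outdir, name)
        df <- data.frame(setNames(list(rownames(mat)), rowLabel),
                         as.data.frame(mat), check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        path
    }
    clusterFiles <- c(
        wm(profile@lfc, "lfc_matrix.tsv"),
        wm(corr@R2, "r2_matrix.tsv", "factor"),
        wm(corr@D, "dissimilarity.tsv", "factor"),
        wm(model@centers, "centers.tsv", "cluster"))
    p <- file.path(cfg$outdir, "clusters.tsv")
    write.table(data.frame(gene = names(model@labels),
                           cluster = model@labels), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    clusterFiles <- c(clusterFiles, p)
    p <- file.path(cfg$outdir, "experiment_tree.nwk")
    asNewick(expTree, p)
    clusterFiles <- c(clusterFiles, p)
    if (!is.null(model@tree)) {
        p <- file.path(cfg$outdir, "cluster_tree.nwk")
        asNewick(model@tree, p)
        clusterFiles <- c(clusterFiles, p)
    }
    addStage(.stageRecord("cluster", cSeed, clusterFiles, t0))

    # --- properties ---------------------------------------------------
    t0 <- as.numeric(Sys.time())
    propFiles <- character(0)
    labels <- model@labels
    if (!is.null(properties)) {
        sub <- properties[intersect(rownames(properties), names(labels)), ,
                          drop = FALSE]
        cmp <- comparePropertyTable(sub, labels)
        p <- file.path(cfg$outdir, "comparisons.tsv")
        write.table(cmp, p, sep = "\t", quote = FALSE, row.names = FALSE)
        propFiles <- c(propFiles, p)
        if ("protein_fraction" %in% colnames(sub)) {
            ps <- clusterPropertySum(
                setNames(sub$protein_fraction, rownames(sub)), labels)
            p <- file.path(cfg$outdir, "protein_share.tsv")
            write.table(ps, p, sep = "\t", quote = FALSE, row.names = FALSE)
            propFiles <- c(propFiles, p)
        }
    }
    if (!is.null(annotation)) {
        af <- utrAFraction(annotation)
        keep <- intersect(names(af), names(labels))
        cmpA <- compareProperty(af[keep], labels[keep], "utr5_a_fraction")
        p <- file.path(cfg$outdir, "utr5_a_fraction.tsv")
        write.table(cmpA, p, sep = "\t", quote = FALSE, row.names = FALSE)
        propFiles <- c(propFiles, p)
        pos <- positionalAEnrichment(annotation, labels,
                                     maxDepth = cfg$max_depth,
                                     minCoverage = cfg$min_coverage)
        p <- file.path(cfg$outdir, "positional_profile.tsv")
        write.table(pos, p, sep = "\t", quote = FALSE, row.names = FALSE)
        propFiles <- c(propFiles, p)
    }
    note("properties: ", length(propFiles), " table(s)")
    addStage(.stageRecord("properties", NA, propFiles, t0))

    # --- tai ----------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    taiFiles <- character(0)
    if (!is.null(annotation)) {
        tSeed <- stageSeed(seed, "tai")
        modelTai <- taiWeights(syntheticTGCN(tSeed))
        gt <- genesTai(annotation, modelTai)
        p <- file.path(cfg$outdir, "gene_te.tsv")
        write.table(gt, p, sep = "\t", quote = FALSE, row.names = FALSE)
        taiFiles <- c(taiFiles, p)
        p <- file.path(cfg$outdir, "codon_weights.tsv")
        write.table(data.frame(codon = names(modelTai@w),
                               W = modelTai@W, w = modelTai@w), p,
                    sep = "\t", quote = FALSE, row.names = FALSE)
        taiFiles <- c(taiFiles, p)
        keep <- intersect(gt$gene, names(labels))
        cmpT <- compareProperty(setNames(gt$tai, gt$gene)[keep],
                                labels[keep], "classical_te")
        p <- file.path(cfg$outdir, "classical_te_comparisons.tsv")
        write.table(cmpT, p, sep = "\t", quote = FALSE, row.names = FALSE)
        taiFiles <- c(taiFiles, p)
        addStage(.stageRecord("tai", tSeed, taiFiles, t0))
    } else {
        addStage(.stageRecord("tai", NA, character(0), t0))
    }

    # --- overlap ------------------------------------------------------
    t0 <- as.numeric(Sys.time())
    oSeed <- stageSeed(seed, "overlap")
    clusterSets <- split(names(labels), labels)
    names(clusterSets) <- paste0("cluster", names(clusterSets))
    ovFiles <- character(0)
    if (!is.null(truth)) {
        truthSets <- split(names(clusterLabels(truth)), clusterLabels(truth))
        names(truthSets) <- paste0("planted", names(truthSets))
        truthSets <- lapply(truthSets, intersect, y = universe)
        rows <- list()
        for (a in names(clusterSets)) for (b in names(truthSets)) {
            r <- hypergeomOverlap(clusterSets[[a]], truthSets[[b]], universe)
            rows[[paste(a, b)]] <- data.frame(query = a, term = b, r)
        }
        ov <- do.call(rbind, rows)
        ov$pAdj <- stats::ave(ov$p, ov$query,
                              FUN = function(p) p.adjust(p, "BH"))
        p <- file.path(cfg$outdir, "overlaps.tsv")
        write.table(ov, p, sep = "\t", quote = FALSE, row.names = FALSE)
        ovFiles <- c(ovFiles, p)
        # three-way Monte-Carlo on the two largest recovered clusters and
        # the largest planted set (degenerate k yields fewer than two
        # cluster sets, in which case the three-way stage is skipped)
        if (length(clusterSets) >= 2) {
            big <- names(sort(lengths(clusterSets), decreasing = TRUE))[1:2]
            mc <- mcMultiwayOverlap(
                list(clusterSets[[big[1]]],
                     truthSets[[which.max(lengths(truthSets))]],
                     clusterSets[[big[2]]]),
                universe, nDraws = cfg$n_draws, seed = oSeed)
            p <- file.path(cfg$outdir, "threeway_overlap.tsv")
            write.table(mc, p, sep = "\t", quote = FALSE, row.names = FALSE)
            ovFiles <- c(ovFiles, p)
        }
        te <- termEnrichment(clusterSets,
                             data.frame(term = paste0("planted",
                                 clusterLabels(truth)[universe]),
                                 gene = universe), universe)
        p <- file.path(cfg$outdir, "term_enrichment.tsv")
        write.table(te, p, sep = "\t", quote = FALSE, row.names = FALSE)
        ovFiles <- c(ovFiles, p)
    }
    note("overlap: ", length(ovFiles), " table(s)")
    addStage(.stageRecord("overlap", oSeed, ovFiles, t0))

    manifest$finished <- format(Sys.time(), usetz = TRUE)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}

#' Per-stage checksum records of a manifest
#'
#' The determinism contract of the pipeline: identical config + seed give
#' identical stage checksums. Timestamps and wall-times are excluded.
#'
#' @param manifest a manifest as returned by \code{\link{runAll}}.
#' @return named list stage -> list(seed, outputs).
#' @export
manifestChecksums <- function(manifest) {
    lapply(manifest$stages, function(s) s[c("seed", "outputs")])
}
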