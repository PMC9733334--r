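#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects \code{matrix.mtx} (genes x cells), \code{features.tsv} (gene
#' ids, optionally a second symbol column) and \code{barcodes.tsv} in
#' \code{dir}. Gene and barcode order are preserved; dimension mismatches
#' are reported with the offending counts.
#'
#' @param dir directory containing the triplet.
#' @param mitoPrefix prefix flagging mitochondrial genes in rowData.
#' @return A \code{SingleCellExperiment} with a sparse integer
#'   \code{counts} assay.
#' @export
readMtxTriplet <- function(dir, mitoPrefix = "MT-") {
    mtx <- file.path(dir, "matrix.mtx")
    feat <- file.path(dir, "features.tsv")
    bc <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(features) != nrow(m))
        stop("matrix has ", nrow(m), " rows but features.tsv lists ",
             nrow(features), " genes")
    if (length(barcodes) != ncol(m))
        stop("matrix has ", ncol(m), " columns but barcodes.tsv lists ",
             length(barcodes), " barcodes")
    genes <- features[[1]]
    dimnames(m) <- list(genes, barcodes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")),
        rowData = S4Vectors::DataFrame(
            gene = genes, mito = startsWith(genes, mitoPrefix),
            row.names = genes),
        colData = S4Vectors::DataFrame(barcode = barcodes, batch = "batch1",
                                       row.names = barcodes))
    sce
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Inverse of [readMtxTriplet()]: writes \code{matrix.mtx},
#' \code{features.tsv} and \code{barcodes.tsv}; integer counts round-trip
#' losslessly with gene/barcode order preserved.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeMtxTriplet <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- SummarizedExperiment::assay(sce, "counts")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(rownames(sce)),
                       file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(colnames(sce)),
                       file.path(dir, "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Read a dense gene x cell count TSV
#'
#' Genes as rows (first column gene names), a header row of cell barcodes.
#'
#' @param path TSV file path.
#' @param mitoPrefix prefix flagging mitochondrial genes.
#' @return A \code{SingleCellExperiment} with a sparse \code{counts} assay.
#' @export
readDenseTSV <- function(path, mitoPrefix = "MT-") {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    genes <- rownames(m)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
        rowData = S4Vectors::DataFrame(
            gene = genes, mito = startsWith(genes, mitoPrefix),
            row.names = genes),
        colData = S4Vectors::DataFrame(barcode = colnames(m),
                                       batch = "batch1",
                                       row.names = colnames(m)))
}

# ---- pipeline configuration -------------------------------------------------

.pipelineSchema <- list(
    seed = NA,
    input = list(mtx_dir = NA, dense_tsv = NA),
    simulate = list(nGenes = NA, nCells = NA, nClusters = NA,
                    clusterProportions = NA, programs = NA,
                    programAssignments = NA, programLog2Effect = NA,
                    baselineMeanLogMu = NA, baselineMeanLogSigma = NA,
                    nbDispersion = NA, mitoFractionGenes = NA,
                    libSizeSigma = NA, qcMinGenes = NA, qcMaxMitoFrac = NA,
                    nLowdepthCells = NA, nHighmitoCells = NA,
                    nDoublets = NA, programSize = NA, seed = NA),
    qc = list(min_genes = NA, max_mito_frac = NA, use_doublet_truth = NA),
    normalize = list(scale = NA),
    scale = list(clip = NA),
    cluster = list(n_clusters = NA, n_pcs = NA, seed = NA),
    cell_cycle = list(enabled = NA, regress = NA, n_bins = NA,
                      n_ctrl = NA, seed = NA),
    enrich = list(gmt = NA, use_planted = NA),
    derive_signatures = list(enabled = NA, lfc_min = NA, alpha = NA,
                             min_pct = NA),
    classify = list(signature_a = NA, signature_b = NA, t_a = NA,
                    t_b = NA, cluster_id = NA),
    output_dir = NA)

.validateConfig <- function(config, schema = .pipelineSchema,
                            path = "config") {
    unknown <- setdiff(names(config), names(schema))
    if (length(unknown) > 0)
        stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
    for (k in names(config)) {
        if (is.list(schema[[k]]) && is.list(config[[k]]) &&
            !k %in% c("simulate"))
            .validateConfig(config[[k]], schema[[k]],
                            paste0(path, "$", k))
    }
    invisible(TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file path; keys are validated against the pipeline
#'   schema (unknown keys are rejected).
#' @return The configuration list.
#' @export
readRunConfig <- function(path) {
    config <- yaml::read_yaml(path)
    .validateConfig(config)
    config
}

.cfg <- function(config, stage, key, default) {
    v <- config[[stage]][[key]]
    if (is.null(v)) default else v
}

#' Run the full analysis pipeline
#'
#' Orchestrates QC filtering, normalization, gene-wise scaling, clustering,
#' optional cell-cycle scoring/regression, signature enrichment, cluster
#' DEG signature derivation and optional pathway classification on either
#' simulated or file-based input, per a declarative configuration.
#' Re-running with the same configuration reproduces all outputs.
#'
#' @param config nested list (see \code{stemFEA:::.pipelineSchema} for the
#'   accepted keys) or a YAML path readable by [readRunConfig()]. Unknown
#'   keys are rejected. Supply either \code{simulate} (arguments to
#'   [simConfig()]) or \code{input} (\code{mtx_dir} or \code{dense_tsv}).
#' @return List with the processed \code{sce}, the QC report, the
#'   enrichment table, per-cluster derived signatures, optional
#'   classification results, a stage log, the configuration echo and
#'   provenance (config hash, seed, package version). When
#'   \code{output_dir} is set, all tables are written there as TSV with a
#'   provenance header plus a \code{config.yaml} echo.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    .validateConfig(config)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    log <- character(0)
    say <- function(...) {
        msg <- paste0(...)
        log <<- c(log, msg)
        message(msg)
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    # -- input
    sce <- runStage("input", {
        if (!is.null(config$simulate)) {
            simArgs <- config$simulate
            if (is.null(simArgs$seed)) simArgs$seed <- seed
            sc <- do.call(simConfig, simArgs)
            say("simulate: ", sc$nGenes, " genes x ", sc$nCells,
                " cells, ", sc$nClusters, " clusters, seed ", sc$seed)
            simulateCounts(sc)
        } else if (!is.null(config$input$mtx_dir)) {
            readMtxTriplet(config$input$mtx_dir)
        } else if (!is.null(config$input$dense_tsv)) {
            readDenseTSV(config$input$dense_tsv)
        } else stop("no input: supply 'simulate' or 'input'")
    })
    say("input: ", nrow(sce), " genes x ", ncol(sce), " cells")

    # -- qc
    simCfg <- S4Vectors::metadata(sce)$sim_config
    minGenes <- .cfg(config, "qc", "min_genes",
                     if (!is.null(simCfg)) simCfg$qcMinGenes else 2000)
    maxMito <- .cfg(config, "qc", "max_mito_frac",
                    if (!is.null(simCfg)) simCfg$qcMaxMitoFrac else 0.15)
    doublets <- NULL
    if (isTRUE(.cfg(config, "qc", "use_doublet_truth",
                    !is.null(simCfg))) && !is.null(sce$qcFail))
        doublets <- sce$qcFail == "doublet"
    sce <- runStage("qc",
        qcFilter(sce, minGenes = minGenes, maxMitoFrac = maxMito,
                 doubletLabels = doublets))
    qcReport <- S4Vectors::metadata(sce)$qc_report
    say("qc: retained ", ncol(sce), " cells (min genes ", minGenes,
        ", max mito ", maxMito, ")")

    # -- normalize / scale / cluster
    sce <- runStage("normalize",
        normalizeLog(sce, scale = .cfg(config, "normalize", "scale", 1e4)))
    sce <- runStage("scale",
        scaleGenes(sce, clip = .cfg(config, "scale", "clip", 10)))
    sce <- runStage("cluster",
        clusterCells(sce,
            nClusters = .cfg(config, "cluster", "n_clusters", 4),
            nPCs = .cfg(config, "cluster", "n_pcs", 20),
            seed = .cfg(config, "cluster", "seed", seed)))
    say("cluster: sizes ",
        paste(table(sce$cluster), collapse = "/"))

    # -- cell cycle
    phaseTab <- NULL
    if (isTRUE(.cfg(config, "cell_cycle", "enabled", FALSE))) {
        sce <- runStage("cell_cycle",
            ccScore(sce,
                nBins = .cfg(config, "cell_cycle", "n_bins", 25),
                nCtrl = .cfg(config, "cell_cycle", "n_ctrl", 50),
                seed = .cfg(config, "cell_cycle", "seed", seed)))
        phaseTab <- phaseComposition(sce)
        if (isTRUE(.cfg(config, "cell_cycle", "regress", FALSE))) {
            sce <- runStage("cc_regress", ccRegress(sce))
            say("cell_cycle: scored and regressed")
        } else say("cell_cycle: scored")
    }

    # -- enrichment
    signatures <- runStage("enrich", {
        if (!is.null(config$enrich$gmt)) readGMT(config$enrich$gmt)
        else if (isTRUE(.cfg(config, "enrich", "use_planted",
                             !is.null(simCfg)))) plantedSignatures(sce)
        else NULL
    })
    enrichment <- NULL
    if (length(signatures) > 0) {
        enrichment <- runStage("enrich", enrichmentTable(sce, signatures))
        say("enrich: ", sum(enrichment$enriched), " of ",
            nrow(enrichment), " (signature, cluster) pairs enriched")
    }

    # -- derived cluster signatures
    derived <- NULL
    if (isTRUE(.cfg(config, "derive_signatures", "enabled", FALSE))) {
        derived <- runStage("derive_signatures", {
            lapply(levels(droplevels(sce$cluster)), function(id)
                suppressWarnings(deriveClusterSignature(
                    sce, clusterId = id,
                    lfcMin = .cfg(config, "derive_signatures",
                                  "lfc_min", 0.25),
                    alpha = .cfg(config, "derive_signatures",
                                 "alpha", 0.05),
                    minPct = .cfg(config, "derive_signatures",
                                  "min_pct", 0.1))))
        })
        names(derived) <- levels(droplevels(sce$cluster))
        say("derive_signatures: ", length(derived), " clusters")
    }

    # -- pathway classification
    classes <- NULL
    if (!is.null(config$classify)) {
        classes <- runStage("classify", {
            sigA <- signatures[[config$classify$signature_a]]
            sigB <- signatures[[config$classify$signature_b]]
            if (is.null(sigA) || is.null(sigB))
                stop("classify: signatures not found among loaded sets")
            labels <- classifyCells(
                scoreSignature(sce, sigA), scoreSignature(sce, sigB),
                tA = .cfg(config, "classify", "t_a", 0),
                tB = .cfg(config, "classify", "t_b", 0))
            ab <- NULL
            if (!is.null(config$classify$cluster_id))
                ab <- classAbundance(labels, sce$cluster,
                                     config$classify$cluster_id)
            list(labels = labels, abundance = ab)
        })
        say("classify: ", paste(levels(classes$labels), collapse = "/"))
    }

    prov <- .provenance(config, seed)
    result <- list(sce = sce, qc_report = qcReport,
                   enrichment = enrichment, derived = derived,
                   classes = classes, phase_composition = phaseTab,
                   log = log, config = config, provenance = prov)
    if (!is.null(config$output_dir))
        writeTables(result, config$output_dir)
    result
}

#' Write pipeline result tables as TSV
#'
#' Each table is written with a leading \code{#} provenance line carrying
#' the configuration hash, seed and package version.
#'
#' @param result a [runPipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeTables <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prov <- result$provenance
    header <- sprintf("# %s | config_hash=%s | seed=%s",
                      prov$tool, prov$config_hash, prov$seed)
    writeOne <- function(df, name) {
        path <- file.path(dir, name)
        con <- file(path, "w")
        writeLines(header, con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
        path
    }
    paths <- character(0)
    if (!is.null(result$qc_report))
        paths <- c(paths, writeOne(result$qc_report, "qc_report.tsv"))
    if (!is.null(result$enrichment))
        paths <- c(paths, writeOne(result$enrichment, "enrichment.tsv"))
    if (!is.null(result$phase_composition))
        paths <- c(paths, writeOne(result$phase_composition,
                                   "phase_composition.tsv"))
    if (!is.null(result$sce)) {
        cd <- as.data.frame(SummarizedExperiment::colData(result$sce))
        keep <- intersect(c("barcode", "batch", "cluster", "phase",
                            "sScore", "g2mScore", "nGenesExpressed",
                            "mitoFrac"), colnames(cd))
        paths <- c(paths, writeOne(cd[, keep, drop = FALSE], "cells.tsv"))
    }
    if (!is.null(result$derived)) {
        sigs <- Filter(Negate(is.null),
                       lapply(result$derived, `[[`, "signature"))
        if (length(sigs) > 0)
            writeGMT(sigs, file.path(dir, "derived_signatures.gmt"))
        for (id in names(result$derived))
            paths <- c(paths, writeOne(result$derived[[id]]$deg,
                                       sprintf("deg_cluster%s.tsv", id)))
    }
    if (!is.null(result$classes)) {
        lab <- result$classes$labels
        paths <- c(paths, writeOne(
            data.frame(barcode = names(lab), class = as.character(lab)),
            "pathway_classes.tsv"))
        if (!is.null(result$classes$abundance))
            paths <- c(paths, writeOne(result$classes$abundance,
                                       "class_abundance.tsv"))
    }
    yaml::write_yaml(result$config, file.path(dir, "config.yaml"))
    writeLines(c(header, result$log), file.path(dir, "run.log"))
    invisible(paths)
}

#' Reported QC-passing mammosphere cell counts
#'
#' The documented per-line QC-passing cell counts of the two profiled ER+
#' mammosphere scRNA-seq experiments this pipeline models (after the
#' standard filters: < 2000 expressed genes or > 15\% mitochondrial reads
#' excluded), and their integrated total. Kept as a regression anchor: the
#' per-line counts must sum to the integrated total.
#'
#' @format Named integer vector with elements \code{MCF7}, \code{T47D} and
#'   \code{integrated}.
#' @export
msCellCounts <- c(MCF7 = 2974L, T47D = 2765L, integrated = 5739L)
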