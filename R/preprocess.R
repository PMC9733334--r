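#' Quality-control filtering of a count matrix
#'
#' Removes cells with fewer than \code{minGenes} expressed genes, cells
#' whose mitochondrial reads exceed \code{maxMitoFrac} of total reads, and
#' cells flagged as doublets by an external label. The defaults (2000
#' genes, 15\% mitochondrial) are the standard thresholds for 10x
#' mammosphere-style experiments.
#'
#' Mitochondrial genes are taken from \code{rowData(counts)$mito} when
#' present, otherwise identified by the \code{mitoPrefix} on gene names.
#'
#' @param counts a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param minGenes minimum number of expressed (count > 0) genes per cell.
#' @param maxMitoFrac maximum mitochondrial read fraction per cell.
#' @param doubletLabels optional per-cell logical; \code{TRUE} cells are
#'   removed as doublets.
#' @param mitoPrefix gene-name prefix identifying mitochondrial genes when
#'   no \code{mito} rowData column exists.
#' @return The filtered \code{SingleCellExperiment}; the per-reason removal
#'   counts are stored as a data.frame in \code{metadata(.)$qc_report} and
#'   per-cell QC metrics (\code{nGenesExpressed}, \code{mitoFrac}) are added
#'   to \code{colData}.
#' @examples
#' sce <- simulateCounts(simConfig(nGenes = 400, nCells = 120,
#'     nLowdepthCells = 5, qcMinGenes = 100, seed = 3))
#' filtered <- qcFilter(sce, minGenes = 100, maxMitoFrac = 0.15)
#' S4Vectors::metadata(filtered)$qc_report
#' @export
qcFilter <- function(counts, minGenes = 2000, maxMitoFrac = 0.15,
                     doubletLabels = NULL, mitoPrefix = "MT-") {
    stopifnot(minGenes > 0, maxMitoFrac > 0)
    m <- SummarizedExperiment::assay(counts, "counts")
    nGenesExpr <- Matrix::colSums(m > 0)
    rd <- SummarizedExperiment::rowData(counts)
    mito <- if ("mito" %in% colnames(rd)) rd$mito else
        startsWith(rownames(counts), mitoPrefix)
    total <- Matrix::colSums(m)
    mitoFrac <- if (any(mito))
        Matrix::colSums(m[mito, , drop = FALSE]) / pmax(total, 1) else
        rep(0, ncol(m))
    if (is.null(doubletLabels)) doubletLabels <- rep(FALSE, ncol(m))
    stopifnot(length(doubletLabels) == ncol(m))

    lowdepth <- nGenesExpr < minGenes
    highmito <- mitoFrac > maxMitoFrac
    removed <- lowdepth | highmito | doubletLabels

    report <- data.frame(
        reason = c("lowdepth", "highmito", "doublet", "removed", "retained"),
        n = c(sum(lowdepth), sum(highmito), sum(doubletLabels),
              sum(removed), sum(!removed)))
    if (all(removed)) {
        dominant <- c("lowdepth", "highmito", "doublet")[
            which.max(c(sum(lowdepth), sum(highmito), sum(doubletLabels)))]
        stop("no cells survive QC; dominant removal reason: ", dominant)
    }
    counts$nGenesExpressed <- as.integer(nGenesExpr)
    counts$mitoFrac <- as.numeric(mitoFrac)
    out <- counts[, !removed]
    S4Vectors::metadata(out)$qc_report <- report
    S4Vectors::metadata(out)$qc_params <- list(
        minGenes = minGenes, maxMitoFrac = maxMitoFrac,
        removed_barcodes = colnames(counts)[removed])
    out
}

#' Depth-normalize counts to a fixed scale with log1p transform
#'
#' \code{value = log(1 + scale * count / cellTotal)}: each cell is scaled to
#' a common total of \code{scale} counts and log-transformed, the de-facto
#' standard normalization for droplet scRNA-seq.
#'
#' @param counts a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param scale target per-cell total (default 1e4).
#' @return The object with a dense \code{logcounts} assay added; the
#'   normalization parameters are stored in
#'   \code{metadata(.)$normalization}.
#' @export
normalizeLog <- function(counts, scale = 1e4) {
    m <- SummarizedExperiment::assay(counts, "counts")
    totals <- Matrix::colSums(m)
    if (any(totals == 0))
        stop("all-zero cell(s) present (should have been removed by QC): ",
             paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "))
    norm <- log1p(sweep(.denseMatrix(m), 2L, totals / scale, "/"))
    SummarizedExperiment::assay(counts, "logcounts") <- norm
    S4Vectors::metadata(counts)$normalization <-
        list(method = "depth+log1p", scale = scale, pseudocount = 1)
    counts
}

#' Gene-wise z-scaling of normalized expression
#'
#' Per gene, across cells: \code{(x - mean) / sd}, clipped to
#' \code{[-clip, clip]}. Zero-variance genes map to all-zero rows so that
#' downstream signature scores never propagate NaN.
#'
#' @param norm a \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param clip symmetric clip bound in SD units (default 10); \code{NULL}
#'   or \code{Inf} disables clipping.
#' @return The object with a \code{scaled} assay added.
#' @export
scaleGenes <- function(norm, clip = 10) {
    Y <- .denseMatrix(SummarizedExperiment::assay(norm, "logcounts"))
    mu <- rowMeans(Y)
    sdv <- apply(Y, 1L, stats::sd)
    Z <- (Y - mu) / ifelse(sdv > 0, sdv, 1)
    Z[sdv == 0, ] <- 0
    if (!is.null(clip) && is.finite(clip))
        Z <- pmin(pmax(Z, -clip), clip)
    SummarizedExperiment::assay(norm, "scaled") <- Z
    S4Vectors::metadata(norm)$scaling <-
        list(clip = if (is.null(clip)) Inf else clip)
    norm
}

#' Cluster cells on principal components of scaled expression
#'
#' PCA on the gene-wise scaled matrix followed by k-means in PC space;
#' deterministic under a fixed seed. Cluster ids are 0-based, relabeled by
#' decreasing size. Cluster labels may equally be supplied externally to
#' downstream functions; this is the package's reference workflow.
#'
#' @param scaled a \code{SingleCellExperiment} with a \code{scaled} assay.
#' @param nClusters number of clusters (default 4).
#' @param nPCs number of principal components (capped at
#'   \code{min(genes, cells) - 1}).
#' @param seed integer seed for k-means starts.
#' @param nStart k-means restarts.
#' @return The object with a \code{cluster} factor column added to
#'   \code{colData}; parameters recorded in \code{metadata(.)$clustering}.
#' @export
clusterCells <- function(scaled, nClusters = 4, nPCs = 20, seed = 1,
                         nStart = 10) {
    Z <- SummarizedExperiment::assay(scaled, "scaled")
    if (nClusters > ncol(Z))
        stop("more clusters requested than cells")
    nPCs <- min(nPCs, nrow(Z) - 1L, ncol(Z) - 1L)
    if (nClusters == ncol(Z)) {              # degenerate: singletons
        scaled$cluster <- factor(seq_len(ncol(Z)) - 1L,
                                 levels = 0:(nClusters - 1L))
        S4Vectors::metadata(scaled)$clustering <- list(
            method = "singletons", nClusters = nClusters, nPCs = nPCs,
            seed = seed, nStart = nStart)
        return(scaled)
    }
    X <- t(Z)                                # cells x genes
    # PC scores U D via the eigendecomposition of the smaller Gram matrix
    if (nrow(X) <= ncol(X)) {
        ev <- eigen(tcrossprod(X), symmetric = TRUE)
        d <- sqrt(pmax(ev$values[seq_len(nPCs)], 0))
        scores <- ev$vectors[, seq_len(nPCs), drop = FALSE] %*% diag(d, nPCs)
    } else {
        ev <- eigen(crossprod(X), symmetric = TRUE)
        scores <- X %*% ev$vectors[, seq_len(nPCs), drop = FALSE]
    }
    km <- .withSeed(seed,
        stats::kmeans(scores, centers = nClusters, nstart = nStart,
                      iter.max = 100))
    # stable 0-based ids: order clusters by decreasing size, ties by first
    # occurrence
    sizes <- tabulate(km$cluster, nClusters)
    relabel <- order(-sizes, seq_len(nClusters))
    labels <- match(km$cluster, relabel) - 1L
    scaled$cluster <- factor(labels, levels = 0:(nClusters - 1L))
    S4Vectors::metadata(scaled)$clustering <- list(
        method = "kmeans_on_pca", nClusters = nClusters, nPCs = nPCs,
        seed = seed, nStart = nStart)
    scaled
}

#' Combine batches by within-batch standardization
#'
#' Each batch is depth-normalized and gene-wise z-scaled independently on
#' the shared gene universe (intersection), then concatenated. By
#' construction every batch has per-gene mean 0, which removes batch
#' location effects; this is a deliberately simple location-matching
#' combination, not an anchor-based integration (see the vignette).
#'
#' @param matrices named list of \code{SingleCellExperiment}s with
#'   \code{counts} assays.
#' @param scale,clip passed to [normalizeLog()] / [scaleGenes()].
#' @return A combined \code{SingleCellExperiment} with \code{scaled} and
#'   \code{logcounts} assays, a \code{batch} column, and batch-prefixed
#'   barcodes.
#' @export
combineBatches <- function(matrices, scale = 1e4, clip = 10) {
    stopifnot(length(matrices) >= 1)
    if (is.null(names(matrices)))
        names(matrices) <- paste0("batch", seq_along(matrices))
    shared <- Reduce(intersect, lapply(matrices, rownames))
    if (length(shared) == 0) stop("empty gene intersection across batches")
    parts <- lapply(names(matrices), function(b) {
        x <- matrices[[b]][shared, ]
        x <- scaleGenes(normalizeLog(x, scale = scale), clip = clip)
        colnames(x) <- paste0(b, "_", colnames(x))
        x$batch <- b
        x
    })
    scaledM <- do.call(cbind, lapply(parts, function(x)
        SummarizedExperiment::assay(x, "scaled")))
    logM <- do.call(cbind, lapply(parts, function(x)
        SummarizedExperiment::assay(x, "logcounts")))
    countM <- do.call(cbind, lapply(parts, function(x)
        SummarizedExperiment::assay(x, "counts")))
    cd <- do.call(rbind, lapply(parts, function(x)
        SummarizedExperiment::colData(x)))
    out <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = countM, logcounts = logM, scaled = scaledM),
        colData = cd)
    S4Vectors::metadata(out)$combination <- list(
        method = "within_batch_standardization",
        batches = names(matrices), sharedGenes = length(shared),
        note = paste("batch location effects removed by per-batch gene-wise",
                     "standardization; no anchor-based integration"))
    out
}
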