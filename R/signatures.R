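#' Derive a cluster signature from differentially expressed genes
#'
#' Per-gene two-sided Wilcoxon rank-sum test of in-cluster vs all other
#' cells on normalized (\code{logcounts}) expression, with log2 fold change
#' computed on de-logged group means (pseudocount 1e-9) and
#' Benjamini-Hochberg adjustment over the tested genes. The signature is
#' the genes with adjusted P below \code{alpha}, log2 fold change above
#' \code{lfcMin} (direction \code{"up"}), expressed in at least
#' \code{minPct} of in-cluster cells. Genes expressed in fewer than
#' \code{minPct} of cells in both groups are not tested.
#'
#' @param norm a \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param clusters per-cell cluster labels (default
#'   \code{colData(norm)$cluster}).
#' @param clusterId the cluster whose markers are sought.
#' @param lfcMin minimum log2 fold change (default 0.25).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param minPct minimum expressed fraction (default 0.1).
#' @param direction currently \code{"up"}: the signature is built from
#'   up-regulated genes, matching signatures derived from cluster DEGs.
#' @return List with \code{deg} (the full tested DEG table: \code{gene,
#'   log2_fc, p_value, bh_adjusted_p, pct_in, pct_out, direction}) and
#'   \code{signature} (a [GeneSignature-class]; empty gene lists return
#'   \code{NULL} with a warning).
#' @export
deriveClusterSignature <- function(norm, clusters = NULL, clusterId,
                                   lfcMin = 0.25, alpha = 0.05,
                                   minPct = 0.1, direction = "up") {
    Y <- .denseMatrix(SummarizedExperiment::assay(norm, "logcounts"))
    if (is.null(clusters)) clusters <- norm$cluster
    cl <- .clusterVector(clusters)
    stopifnot(length(cl) == ncol(Y))
    inGroup <- cl == as.character(clusterId)
    if (sum(inGroup) < 3 || sum(!inGroup) < 3)
        stop("cluster '", clusterId,
             "' needs >= 3 cells inside and outside")

    pctIn <- rowMeans(Y[, inGroup, drop = FALSE] > 0)
    pctOut <- rowMeans(Y[, !inGroup, drop = FALSE] > 0)
    tested <- pctIn >= minPct | pctOut >= minPct
    if (!any(tested)) stop("no genes pass the expression filter")
    Yt <- Y[tested, , drop = FALSE]

    eps <- 1e-9
    meanIn <- rowMeans(expm1(Yt[, inGroup, drop = FALSE]))
    meanOut <- rowMeans(expm1(Yt[, !inGroup, drop = FALSE]))
    lfc <- log2((meanIn + eps) / (meanOut + eps))
    p <- .rankSumRows(Yt, inGroup)
    bh <- stats::p.adjust(p, method = "BH")

    deg <- data.frame(
        gene = rownames(Yt), log2_fc = lfc, p_value = p,
        bh_adjusted_p = bh,
        pct_in = pctIn[tested], pct_out = pctOut[tested],
        direction = ifelse(lfc >= 0, "up", "down"),
        row.names = NULL, stringsAsFactors = FALSE)
    deg <- deg[order(deg$bh_adjusted_p, -abs(deg$log2_fc)), ]

    keep <- deg$bh_adjusted_p < alpha & deg$log2_fc > lfcMin &
        deg$pct_in >= minPct
    sig <- NULL
    if (any(keep)) {
        sig <- geneSignature(
            paste0("cluster", clusterId, "_signature"),
            deg$gene[keep], direction = "up",
            provenance = sprintf(
                "DEG-derived: cluster %s vs rest; rank-sum BH p < %g, log2FC > %g, min pct %g",
                clusterId, alpha, lfcMin, minPct))
    } else {
        warning("no genes pass the DEG thresholds for cluster '",
                clusterId, "'; returning NULL signature")
    }
    list(deg = deg, signature = sig)
}

#' Overlap report between two gene signatures
#'
#' Exact set arithmetic: intersection size and the percent of each
#' signature contained in the other.
#'
#' @param a,b [GeneSignature-class] objects.
#' @return \code{data.frame} with \code{n_a, n_b, n_common,
#'   pct_a_in_b, pct_b_in_a}.
#' @examples
#' a <- geneSignature("a", c("g1", "g2", "g3", "g4", "g5"))
#' b <- geneSignature("b", c("g1", "g2", "g3", "g4", "x"))
#' signatureOverlap(a, b)   # 80% of a in b
#' @export
signatureOverlap <- function(a, b) {
    ga <- sigGenes(a); gb <- sigGenes(b)
    common <- length(intersect(ga, gb))
    data.frame(
        a = sigName(a), b = sigName(b),
        n_a = length(ga), n_b = length(gb), n_common = common,
        pct_a_in_b = 100 * common / length(ga),
        pct_b_in_a = 100 * common / length(gb),
        stringsAsFactors = FALSE)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a set are removed with a warning; a line without genes is an
#' error reporting its line number.
#'
#' @param path GMT file path.
#' @return Named list of [GeneSignature-class] objects.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sigs <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("malformed GMT line ", i, ": expected name, description ",
                 "and at least one gene")
        genes <- parts[-c(1L, 2L)]
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0)
            stop("malformed GMT line ", i, ": no genes")
        sigs[[parts[[1]]]] <- geneSignature(
            parts[[1]], genes, provenance = parts[[2]])
    }
    sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures list of [GeneSignature-class] objects.
#' @param path output file path.
#' @return Invisibly, the path. \code{writeGMT} then \code{readGMT} is an
#'   identity on names and gene lists.
#' @export
writeGMT <- function(signatures, path) {
    if (methods::is(signatures, "GeneSignature"))
        signatures <- list(signatures)
    lines <- vapply(signatures, function(s) {
        desc <- if (nzchar(s@provenance)) s@provenance else "na"
        paste(c(sigName(s), desc, sigGenes(s)), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
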