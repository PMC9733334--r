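#' Per-cell z-scored signature score
#'
#' For each cell, the mean of the gene-wise z-scores (the \code{scaled}
#' assay) over the signature genes present in the matrix. The mean (rather
#' than the sum) makes scores comparable across signatures of different
#' sizes. Missing signature genes are dropped and counted; an overlap below
#' \code{minOverlapFrac} triggers a warning, zero overlap an error.
#'
#' @param scaled a \code{SingleCellExperiment} with a \code{scaled} assay,
#'   or a plain genes x cells matrix of gene-wise z-scores.
#' @param sig a [GeneSignature-class].
#' @param minOverlapFrac warn when fewer than this fraction of signature
#'   genes are present.
#' @return A [SignatureScores-class] object.
#' @export
scoreSignature <- function(scaled, sig, minOverlapFrac = 0.2) {
    Z <- if (methods::is(scaled, "SummarizedExperiment"))
        SummarizedExperiment::assay(scaled, "scaled") else as.matrix(scaled)
    genes <- sigGenes(sig)
    present <- intersect(genes, rownames(Z))
    missing <- setdiff(genes, rownames(Z))
    if (length(present) == 0)
        stop("no signature genes present in the matrix for '", sigName(sig),
             "'; missing: ", paste(utils::head(missing, 10), collapse = ", "),
             if (length(missing) > 10) ", ..." else "")
    if (length(present) / length(genes) < minOverlapFrac)
        warning("signature '", sigName(sig), "': only ", length(present),
                " of ", length(genes), " genes present")
    score <- colMeans(Z[present, , drop = FALSE])
    new("SignatureScores", name = sigName(sig), scores = score,
        nGenesUsed = length(present), nGenesMissing = length(missing))
}

.clusterVector <- function(clusters, barcodes = NULL) {
    if (methods::is(clusters, "SummarizedExperiment"))
        clusters <- SummarizedExperiment::colData(clusters)$cluster
    as.character(clusters)
}

#' ROC-AUC enrichment of a signature in one cluster
#'
#' The AUC is the Mann-Whitney statistic
#' \eqn{(R_{in} - n_{in}(n_{in}+1)/2) / (n_{in} n_{out})} computed with
#' midranks: the probability that a random in-cluster cell outscores a
#' random out-of-cluster cell (ties counted half). Significance is the
#' two-sided Wilcoxon rank-sum test: exact enumeration of the rank-sum null
#' when \eqn{n_{in} + n_{out} \le 20}, tie-corrected normal approximation
#' otherwise. A signature is called enriched when AUC > 0.6 and P < 0.01.
#'
#' @param scores a [SignatureScores-class] (or named numeric vector).
#' @param clusters per-cell cluster labels, aligned with the scores (or a
#'   \code{SingleCellExperiment} carrying a \code{cluster} column).
#' @param clusterId the cluster to test.
#' @param aucThreshold,pThreshold the enrichment rule (defaults 0.6, 0.01).
#' @return One-row \code{data.frame}: \code{signature, cluster, auc,
#'   p_value, enriched, n_in, n_out}.
#' @export
aucEnrichment <- function(scores, clusters, clusterId,
                          aucThreshold = 0.6, pThreshold = 0.01) {
    s <- if (methods::is(scores, "SignatureScores"))
        cellScores(scores) else scores
    nm <- if (methods::is(scores, "SignatureScores"))
        scores@name else "signature"
    cl <- .clusterVector(clusters)
    stopifnot(length(cl) == length(s))
    if (!as.character(clusterId) %in% cl)
        stop("cluster '", clusterId, "' not present")
    inGroup <- cl == as.character(clusterId)
    if (sum(inGroup) < 2 || sum(!inGroup) < 2)
        stop("cluster '", clusterId,
             "' needs >= 2 cells inside and outside")
    rs <- .rankSumTest(s, inGroup)
    data.frame(
        signature = nm, cluster = as.character(clusterId),
        auc = rs$auc, p_value = rs$p,
        enriched = rs$auc > aucThreshold & rs$p < pThreshold,
        n_in = rs$nIn, n_out = rs$nOut,
        stringsAsFactors = FALSE)
}

#' Enrichment table over signatures and clusters
#'
#' Runs [scoreSignature()] + [aucEnrichment()] for every (signature,
#' cluster) pair. A Benjamini-Hochberg column is added for transparency but
#' the \code{enriched} flag follows the raw AUC > 0.6, P < 0.01 rule.
#'
#' @param scaled a \code{SingleCellExperiment} with \code{scaled} assay and
#'   \code{cluster} column (or supply \code{clusters}).
#' @param signatures list of [GeneSignature-class] objects.
#' @param clusters optional per-cell labels overriding
#'   \code{colData(scaled)$cluster}.
#' @param ... passed to [aucEnrichment()].
#' @return Long-format \code{data.frame} with one row per (signature,
#'   cluster): \code{signature, cluster, auc, p_value, bh_p, enriched,
#'   n_in, n_out}. Use [aucMatrix()] for the signature x cluster AUC
#'   matrix.
#' @export
enrichmentTable <- function(scaled, signatures, clusters = NULL, ...) {
    if (length(signatures) == 0) stop("no signatures supplied")
    if (is.null(clusters)) clusters <- scaled$cluster
    cl <- .clusterVector(clusters)
    ids <- sort(unique(cl))
    if (length(ids) < 2)
        stop("at least two clusters are required for enrichment")
    rows <- list()
    for (sig in signatures) {
        sc <- scoreSignature(scaled, sig)
        for (id in ids)
            rows[[length(rows) + 1L]] <- aucEnrichment(sc, cl, id, ...)
    }
    out <- do.call(rbind, rows)
    out$bh_p <- stats::p.adjust(out$p_value, method = "BH")
    out[, c("signature", "cluster", "auc", "p_value", "bh_p", "enriched",
            "n_in", "n_out")]
}

#' Signature x cluster AUC matrix from an enrichment table
#'
#' @param tab output of [enrichmentTable()].
#' @return Numeric matrix, signatures as rows, clusters as columns.
#' @export
aucMatrix <- function(tab) {
    sigs <- unique(tab$signature)
    cls <- sort(unique(tab$cluster))
    m <- matrix(NA_real_, length(sigs), length(cls),
                dimnames = list(sigs, cls))
    m[cbind(match(tab$signature, sigs), match(tab$cluster, cls))] <- tab$auc
    m
}

.bandLabel <- function(r) {
    a <- abs(r)
    if (a >= 0.3 && a < 0.5) "moderate"
    else if (a >= 0.5 && a <= 0.9) "strong"
    else "none"
}

#' Pearson correlation between two signature score vectors
#'
#' Two-sided Pearson correlation on an optional cell subset, with the band
#' convention: |r| in 0.3-0.5 is a moderate correlation, 0.5-0.9 a strong
#' one.
#'
#' @param a,b [SignatureScores-class] objects over the same cell universe.
#' @param cellSubset optional character vector of barcodes (e.g. one
#'   cluster's cells).
#' @return \code{data.frame} with \code{pearson_r}, \code{r_p_value},
#'   \code{band_label}, \code{n}.
#' @export
signatureCorrelation <- function(a, b, cellSubset = NULL) {
    sa <- cellScores(a); sb <- cellScores(b)
    if (!identical(sort(names(sa)), sort(names(sb))))
        stop("score vectors cover different cell universes")
    sb <- sb[names(sa)]
    if (!is.null(cellSubset)) {
        sa <- sa[cellSubset]; sb <- sb[cellSubset]
    }
    if (length(sa) < 3) stop("subset must contain at least 3 cells")
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0)
        stop("zero variance in signature scores on the subset")
    ct <- stats::cor.test(sa, sb, method = "pearson")
    data.frame(
        pair = paste(a@name, b@name, sep = " ~ "),
        pearson_r = unname(ct$estimate),
        r_p_value = ct$p.value,
        band_label = .bandLabel(unname(ct$estimate)),
        n = length(sa), stringsAsFactors = FALSE)
}

#' Multiple linear regression among signature scores
#'
#' Ordinary least squares of one signature score on several others (with
#' intercept), as used to relate pathway activities within a cluster.
#'
#' @param y response [SignatureScores-class].
#' @param xs named list of predictor [SignatureScores-class] objects.
#' @param cellSubset optional barcodes restricting the fit.
#' @param conditionMax collinearity guard: error when the model-matrix
#'   condition number exceeds this.
#' @return List with \code{coefficients} (term, estimate, std_error,
#'   t_value, p_value), \code{r_squared}, \code{n}.
#' @export
signatureRegression <- function(y, xs, cellSubset = NULL,
                                conditionMax = 1e8) {
    sy <- cellScores(y)
    if (methods::is(xs, "SignatureScores")) xs <- list(xs)
    if (is.null(names(xs)) || any(!nzchar(names(xs))))
        names(xs) <- vapply(xs, function(s) s@name, character(1))
    X <- vapply(xs, function(s) cellScores(s)[names(sy)],
                numeric(length(sy)))
    if (!is.null(cellSubset)) {
        sy <- sy[cellSubset]
        X <- X[cellSubset, , drop = FALSE]
    }
    if (length(sy) <= ncol(X) + 1)
        stop("subset too small for ", ncol(X), " predictors")
    mm <- cbind(`(Intercept)` = 1, X)
    if (kappa(mm, exact = TRUE) > conditionMax)
        stop("collinear predictors (condition number above threshold)")
    fit <- stats::lm(sy ~ X)
    sm <- summary(fit)
    co <- sm$coefficients
    list(
        coefficients = data.frame(
            term = c("(Intercept)", colnames(X)),
            estimate = co[, 1], std_error = co[, 2],
            t_value = co[, 3], p_value = co[, 4],
            row.names = NULL, stringsAsFactors = FALSE),
        r_squared = sm$r.squared,
        n = length(sy))
}
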