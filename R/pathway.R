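#' Four-way per-cell pathway-activity classification
#'
#' The computational analog of dual-reporter sorting: each cell is assigned
#' to one of four classes from two signature score vectors by strict
#' thresholding — \code{dual_positive} when both scores exceed their
#' thresholds, \code{a_active} / \code{b_active} when only one does,
#' \code{dual_negative} otherwise (scores exactly at threshold are
#' negative). The default threshold 0 calls a pathway active when the
#' cell's z-scored signature score is above the population mean.
#'
#' @param a,b [SignatureScores-class] objects over the same cells (e.g.
#'   ER and NF-kB pathway signatures).
#' @param tA,tB activity thresholds (default 0).
#' @return Named factor over cells with levels \code{dual_negative,
#'   a_active, b_active, dual_positive}; the thresholds and signature names
#'   are attached as attributes.
#' @export
classifyCells <- function(a, b, tA = 0, tB = 0) {
    sa <- cellScores(a); sb <- cellScores(b)
    if (!identical(sort(names(sa)), sort(names(sb))))
        stop("score vectors cover different cell sets")
    sb <- sb[names(sa)]
    aOn <- sa > tA
    bOn <- sb > tB
    cls <- ifelse(aOn & bOn, "dual_positive",
                  ifelse(aOn, "a_active",
                         ifelse(bOn, "b_active", "dual_negative")))
    out <- factor(cls, levels = c("dual_negative", "a_active", "b_active",
                                  "dual_positive"))
    names(out) <- names(sa)
    attr(out, "thresholds") <- c(t_a = tA, t_b = tB)
    attr(out, "signatures") <- c(a = a@name, b = b@name)
    out
}

#' Class abundance in a cluster relative to the whole population
#'
#' For each pathway class: its fraction among the cluster's cells, its
#' overall fraction, and the percent change
#' \code{100 * (frac_in - frac_overall) / frac_overall}, with a two-sided
#' two-sample proportion test (in-cluster vs out-of-cluster) per class.
#' An absolute-difference mode (\code{frac_in - frac_overall}, in
#' percentage points) is also emitted.
#'
#' @param labels factor from [classifyCells()].
#' @param clusters per-cell cluster labels aligned with \code{labels}.
#' @param clusterId the cluster of interest.
#' @return \code{data.frame} with one row per class: \code{class, n_in,
#'   frac_in, frac_overall, pct_change, abs_change_pp, p_value}. Classes
#'   absent from the whole population have \code{pct_change = NA}.
#' @export
classAbundance <- function(labels, clusters, clusterId) {
    cl <- .clusterVector(clusters)
    stopifnot(length(cl) == length(labels))
    inC <- cl == as.character(clusterId)
    if (!any(inC)) stop("cluster '", clusterId, "' is empty or absent")
    lv <- levels(labels)
    rows <- lapply(lv, function(k) {
        nInK <- sum(labels[inC] == k)
        nOutK <- sum(labels[!inC] == k)
        fracIn <- nInK / sum(inC)
        fracAll <- (nInK + nOutK) / length(labels)
        pct <- if (fracAll > 0)
            100 * (fracIn - fracAll) / fracAll else NA_real_
        p <- if (sum(inC) > 0 && sum(!inC) > 0)
            suppressWarnings(stats::prop.test(
                c(nInK, nOutK), c(sum(inC), sum(!inC))))$p.value
        else NA_real_
        data.frame(class = k, n_in = nInK, frac_in = fracIn,
                   frac_overall = fracAll, pct_change = pct,
                   abs_change_pp = 100 * (fracIn - fracAll),
                   p_value = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Per-class marker expression and fold change vs a reference class
#'
#' Mean normalized expression of selected genes per pathway class, with
#' fold change relative to a reference class (default
#' \code{dual_negative}) computed on de-logged means with a pseudocount,
#' and a rank-sum P value vs the reference per class.
#'
#' @param norm a \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param labels factor from [classifyCells()] over the same cells.
#' @param genes genes to report (must be present).
#' @param reference reference class (default \code{"dual_negative"}).
#' @return \code{data.frame}: \code{gene, class, mean_expr, fold_change,
#'   p_value} (reference rows have fold change 1 and P = NA).
#' @export
classMarkerExpression <- function(norm, labels, genes,
                                  reference = "dual_negative") {
    Y <- .denseMatrix(SummarizedExperiment::assay(norm, "logcounts"))
    missing <- setdiff(genes, rownames(Y))
    if (length(missing) > 0)
        stop("genes not present: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(Y)]
    if (sum(labels == reference, na.rm = TRUE) == 0)
        stop("reference class '", reference, "' is empty")
    eps <- 1e-9
    refIdx <- which(labels == reference)
    rows <- list()
    for (g in genes) {
        y <- Y[g, ]
        refMean <- mean(expm1(y[refIdx]))
        for (k in levels(labels)) {
            idx <- which(labels == k)
            if (length(idx) == 0) next
            mExpr <- mean(y[idx])
            fc <- (mean(expm1(y[idx])) + eps) / (refMean + eps)
            p <- if (k == reference) NA_real_ else
                .rankSumTest(c(y[idx], y[refIdx]),
                             c(rep(TRUE, length(idx)),
                               rep(FALSE, length(refIdx))),
                             exact = FALSE)$p
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g, class = k, mean_expr = mExpr,
                fold_change = fc, p_value = p, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
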