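#' Per-gene z-scores across a tumor cohort
#'
#' Standardizes each gene's expression across tumors (mean 0, sd 1),
#' matching precomputed cBioPortal-style mRNA z-scores. Zero-variance
#' genes become all-zero rows with a warning. Re-applying is idempotent.
#'
#' @param expr genes x tumors numeric matrix, or a
#'   \code{SummarizedExperiment} with an \code{expr} assay.
#' @return Numeric z-score matrix with the same dimnames.
#' @export
zscoreCohort <- function(expr) {
    if (methods::is(expr, "SummarizedExperiment"))
        expr <- SummarizedExperiment::assay(expr, "expr")
    expr <- as.matrix(expr)
    if (ncol(expr) < 3) stop("cohort must contain at least 3 tumors")
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1L, stats::sd)
    if (any(sdv == 0))
        warning(sum(sdv == 0), " zero-variance gene(s) set to zero")
    z <- (expr - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    z
}

#' Stratify tumors by signature-gene z-score alterations
#'
#' A tumor is signature-positive when at least \code{minAlteredGenes} of
#' the signature's genes exceed the alteration threshold: \code{z >=
#' threshold} in mode \code{"up"} (the default, since DEG-derived
#' signatures are built from up-regulated genes) or \code{|z| >= threshold}
#' in mode \code{"both"} (the symmetric cBioPortal convention). The default
#' threshold is 2 standard deviations from the mean.
#'
#' @param z per-gene z-score matrix from [zscoreCohort()] (or a
#'   \code{SummarizedExperiment}; its \code{expr} assay is z-scored).
#' @param sig a [GeneSignature-class].
#' @param threshold alteration threshold in SDs (default 2).
#' @param mode \code{"up"} or \code{"both"}.
#' @param minAlteredGenes minimum altered signature genes to call a tumor
#'   positive (default 1).
#' @return \code{data.frame} with \code{tumor, positive, n_altered} and an
#'   \code{"altered_genes"} attribute (list of altered genes per positive
#'   tumor); stratification parameters attached as attributes.
#' @export
stratifyBySignature <- function(z, sig, threshold = 2,
                                mode = c("up", "both"),
                                minAlteredGenes = 1) {
    mode <- match.arg(mode)
    if (methods::is(z, "SummarizedExperiment")) z <- zscoreCohort(z)
    genes <- intersect(sigGenes(sig), rownames(z))
    if (length(genes) == 0)
        stop("no signature genes present in the cohort")
    zs <- z[genes, , drop = FALSE]
    altered <- if (mode == "up") zs >= threshold else abs(zs) >= threshold
    nAlt <- colSums(altered)
    out <- data.frame(
        tumor = colnames(z), positive = nAlt >= minAlteredGenes,
        n_altered = as.integer(nAlt),
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "altered_genes") <- apply(altered, 2L, function(a)
        rownames(zs)[a], simplify = FALSE)
    attr(out, "params") <- list(signature = sigName(sig),
                                threshold = threshold, mode = mode,
                                minAlteredGenes = minAlteredGenes,
                                genesUsed = length(genes))
    out
}

#' Chi-squared association between stratification and a clinical factor
#'
#' Pearson chi-squared test (no continuity correction) on the
#' positive/negative x clinical-level contingency table.
#'
#' @param labels logical or two-level vector of signature positivity.
#' @param clinical categorical clinical column (grade, subtype, ...).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return List: \code{statistic}, \code{df}, \code{p_value},
#'   \code{table} (the observed contingency table).
#' @export
categoricalAssociation <- function(labels, clinical, correct = FALSE) {
    tab <- table(labels, clinical)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("both margins need at least 2 observed levels")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0))
        stop("zero expected cell count; consider merging levels")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, table = tab)
}

#' Log-rank comparison of survival between stratification groups
#'
#' Standard two-group log-rank test on right-censored data, with
#' Kaplan-Meier survival tables emitted for plotting.
#'
#' @param labels two-group labels per tumor.
#' @param time survival time (e.g. months).
#' @param event event indicator (1 = event, 0 = censored).
#' @return List: \code{statistic} (log-rank chi-squared), \code{df},
#'   \code{p_value}, \code{km} (data.frame \code{group, time, n_risk,
#'   n_event, surv, lower, upper}), \code{n_events} per group.
#' @export
survivalCompare <- function(labels, time, event) {
    labels <- as.factor(labels)
    if (nlevels(droplevels(labels)) < 2)
        stop("two groups are required for a log-rank comparison")
    if (sum(event) == 0)
        stop("no events observed (all observations censored)")
    byGroup <- tapply(event, labels, sum)
    if (any(byGroup == 0))
        stop("each group must contain at least one event")
    sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
    df <- length(sd$n) - 1L
    fit <- survival::survfit(survival::Surv(time, event) ~ labels)
    sm <- summary(fit)
    km <- data.frame(
        group = sub("^labels=", "", as.character(sm$strata)),
        time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
        surv = sm$surv, lower = sm$lower, upper = sm$upper,
        stringsAsFactors = FALSE)
    list(statistic = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         km = km, n_events = as.vector(byGroup))
}

#' Per-tumor signature score and stratum comparisons
#'
#' The cohort signature score of a tumor is the mean z-score over the
#' signature genes present. When a grouping is supplied, strata are
#' compared by two-sided Welch t-tests (all pairwise when more than two
#' levels).
#'
#' @param z z-score matrix from [zscoreCohort()].
#' @param sig a [GeneSignature-class].
#' @param group optional per-tumor stratum (grade, subtype, relapse
#'   status, ...).
#' @return List: \code{score} (named per-tumor vector) and, when
#'   \code{group} is given, \code{tests} (data.frame \code{group1, group2,
#'   mean1, mean2, t, p_value}).
#' @export
cohortSignatureScore <- function(z, sig, group = NULL) {
    genes <- intersect(sigGenes(sig), rownames(z))
    if (length(genes) == 0)
        stop("no signature genes present in the cohort")
    score <- colMeans(z[genes, , drop = FALSE])
    out <- list(score = score)
    if (!is.null(group)) {
        group <- droplevels(as.factor(group))
        small <- names(which(table(group) < 2))
        if (length(small) > 0)
            stop("stratum with < 2 tumors: ", paste(small, collapse = ", "))
        lv <- levels(group)
        pairs <- utils::combn(lv, 2L)
        tests <- apply(pairs, 2L, function(pr) {
            x <- score[group == pr[1]]; y <- score[group == pr[2]]
            tt <- stats::t.test(x, y)
            data.frame(group1 = pr[1], group2 = pr[2],
                       mean1 = mean(x), mean2 = mean(y),
                       t = unname(tt$statistic), p_value = tt$p.value,
                       stringsAsFactors = FALSE)
        })
        out$tests <- do.call(rbind, tests)
    }
    out
}
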