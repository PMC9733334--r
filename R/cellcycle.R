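#' Packaged S and G2M phase gene lists
#'
#' The standard human cell-cycle phase gene symbols (43 S-phase, 54
#' G2M-phase) used by the canonical scRNA-seq phase-scoring workflow.
#' Users may substitute their own lists in [ccScore()] and
#' [simulateCyclePrograms()].
#'
#' @return List with character vectors \code{s} and \code{g2m}.
#' @export
cycleGenes <- function() {
    list(
        s = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1",
              "UNG", "GINS2", "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1",
              "HELLS", "RFC2", "RPA2", "NASP", "RAD51AP1", "GMNN",
              "WDR76", "SLBP", "CCNE2", "UBR7", "POLD3", "MSH2", "ATAD2",
              "RAD51", "RRM2", "CDC45", "CDC6", "EXO1", "TIPIN", "DSCC1",
              "BLM", "CASP8AP2", "USP1", "CLSPN", "POLA1", "CHAF1B",
              "BRIP1", "E2F8", "MLF1IP"),
        g2m = c("HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2",
                "TOP2A", "NDC80", "CKS2", "NUF2", "CKS1B", "MKI67",
                "TMPO", "CENPF", "TACC3", "FAM64A", "SMC4", "CCNB2",
                "CKAP2L", "CKAP2", "AURKB", "BUB1", "KIF11", "ANP32E",
                "TUBB4B", "GTSE1", "KIF20B", "HJURP", "CDCA3", "HN1",
                "CDC20", "TTK", "CDC25C", "KIF2C", "RANGAP1", "NCAPD2",
                "DLGAP5", "CDCA2", "CDCA8", "ECT2", "KIF23", "HMMR",
                "AURKA", "PSRC1", "ANLN", "LBR", "CKAP5", "CENPE",
                "CTCF", "NEK2", "G2E3", "GAS2L3", "CBX5", "CENPA"))
}

#' Cell-cycle phase scoring with expression-matched control genes
#'
#' Program score per cell = mean normalized expression of the program genes
#' minus mean expression of control genes drawn from the same
#' average-expression bins: genes are binned by their mean normalized
#' expression into \code{nBins} bins and \code{nCtrl} control genes are
#' sampled (seed-fixed) per program gene from its bin. A cell with both
#' scores at or below zero is G1; otherwise its phase is the larger of the
#' S and G2M scores.
#'
#' @param norm a \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param sGenes,g2mGenes phase gene lists (defaults: [cycleGenes()]).
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl control genes per program gene (default 50).
#' @param seed integer seed for control sampling.
#' @return The object with \code{sScore}, \code{g2mScore} and \code{phase}
#'   columns added to \code{colData}; parameters in
#'   \code{metadata(.)$cell_cycle}.
#' @export
ccScore <- function(norm, sGenes = cycleGenes()$s,
                    g2mGenes = cycleGenes()$g2m,
                    nBins = 25, nCtrl = 50, seed = 1) {
    Y <- .denseMatrix(SummarizedExperiment::assay(norm, "logcounts"))
    sUse <- intersect(sGenes, rownames(Y))
    gUse <- intersect(g2mGenes, rownames(Y))
    if (length(sUse) == 0 || length(gUse) == 0)
        stop("S or G2M program genes entirely absent from the matrix")

    avg <- rowMeans(Y)
    brk <- unique(stats::quantile(avg, probs = seq(0, 1,
                                                   length.out = nBins + 1)))
    bin <- cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    names(bin) <- rownames(Y)

    # controls exclude both phase programs, so one program's genes never
    # serve as the other's reference
    excluded <- c(sUse, gUse)
    sampleControls <- function(program, streamOffset) {
        .withSeed(.subSeed(seed, streamOffset), {
            ctrl <- character(0)
            for (g in program) {
                pool <- setdiff(names(bin)[bin == bin[[g]]], excluded)
                if (length(pool) == 0)
                    pool <- setdiff(names(bin), excluded)
                ctrl <- c(ctrl, sample(pool, min(nCtrl, length(pool))))
            }
            unique(ctrl)
        })
    }
    scoreProgram <- function(program, streamOffset) {
        ctrl <- sampleControls(program, streamOffset)
        colMeans(Y[program, , drop = FALSE]) -
            colMeans(Y[ctrl, , drop = FALSE])
    }
    sScore <- scoreProgram(sUse, 11L)
    g2mScore <- scoreProgram(gUse, 12L)

    phase <- ifelse(sScore <= 0 & g2mScore <= 0, "G1",
                    ifelse(sScore > g2mScore, "S", "G2M"))
    norm$sScore <- sScore
    norm$g2mScore <- g2mScore
    norm$phase <- factor(phase, levels = c("G1", "S", "G2M"))
    S4Vectors::metadata(norm)$cell_cycle <- list(
        nBins = nBins, nCtrl = nCtrl, seed = seed,
        nS = length(sUse), nG2M = length(gUse))
    norm
}

#' Regress cell-cycle scores out of scaled expression
#'
#' Per gene, replaces scaled expression by the residuals of its
#' least-squares fit on (sScore, g2mScore, intercept), then re-standardizes
#' gene-wise so downstream scoring operates on a valid z-scaled matrix.
#' Constant score vectors leave the matrix unchanged (warning).
#'
#' @param scaled a \code{SingleCellExperiment} with a \code{scaled} assay
#'   and \code{sScore}/\code{g2mScore} columns (from [ccScore()]).
#' @param clip clip bound applied during re-standardization.
#' @return The object with its \code{scaled} assay replaced by cycle-
#'   regressed, re-standardized values.
#' @export
ccRegress <- function(scaled, clip = 10) {
    if (is.null(scaled$sScore) || is.null(scaled$g2mScore))
        stop("run ccScore() first: sScore/g2mScore columns are missing")
    Z <- SummarizedExperiment::assay(scaled, "scaled")
    s <- scaled$sScore; g <- scaled$g2mScore
    if (stats::sd(s) == 0 && stats::sd(g) == 0) {
        warning("constant cell-cycle scores: nothing to regress out")
        X <- cbind(1, rep(0, length(s)), rep(0, length(s)))
    } else {
        X <- cbind(1, s, g)
    }
    qrX <- qr(X)
    resid <- t(qr.resid(qrX, t(Z)))
    dimnames(resid) <- dimnames(Z)

    mu <- rowMeans(resid)
    sdv <- apply(resid, 1L, stats::sd)
    out <- (resid - mu) / ifelse(sdv > 0, sdv, 1)
    out[sdv == 0, ] <- 0
    if (!is.null(clip) && is.finite(clip))
        out <- pmin(pmax(out, -clip), clip)
    SummarizedExperiment::assay(scaled, "scaled") <- out
    S4Vectors::metadata(scaled)$cycle_regressed <- TRUE
    scaled
}

#' Per-cluster cell-cycle phase composition
#'
#' @param clusters per-cell cluster labels (or a
#'   \code{SingleCellExperiment} with \code{cluster} and \code{phase}
#'   columns).
#' @param phases per-cell phase labels (ignored when \code{clusters} is an
#'   experiment object).
#' @return \code{data.frame} with one row per (cluster, phase) and columns
#'   \code{cluster, phase, n, pct}; percentages per cluster sum to 100.
#' @export
phaseComposition <- function(clusters, phases = NULL) {
    if (methods::is(clusters, "SummarizedExperiment")) {
        phases <- clusters$phase
        clusters <- clusters$cluster
    }
    cl <- as.character(clusters)
    ph <- factor(as.character(phases), levels = c("G1", "S", "G2M"))
    tab <- table(cluster = cl, phase = ph)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    colnames(out) <- c("cluster", "phase", "n")
    tot <- rowSums(tab)
    out$pct <- 100 * out$n / tot[out$cluster]
    out[order(out$cluster, match(out$phase, c("G1", "S", "G2M"))), ,
        drop = FALSE]
}
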