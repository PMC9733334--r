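#' Simulation configuration for synthetic single-cell counts
#'
#' Describes a negative-binomial gene x cell count simulation with cluster
#' structure and planted up-regulated gene programs. Gene means are
#' log-normal; program genes in carrier clusters have their mean multiplied
#' by \code{2^programLog2Effect}; per-cell library-size variation is a
#' log-normal multiplier. Designated cells are forced to fail quality
#' control (low expressed-gene count, or high mitochondrial fraction) and
#' doublets are sums of two cell profiles, so that downstream filtering can
#' be validated against ground truth.
#'
#' All randomness flows from the single root \code{seed}: each internal
#' draw (gene means, cluster assignment, library sizes, counts, QC
#' designations) uses a sub-stream seed derived deterministically from it.
#'
#' @param nGenes,nCells,nClusters dimensions of the simulation.
#' @param clusterProportions cluster mixing weights; must sum to 1. Default
#'   equal proportions.
#' @param programs named list of gene-symbol vectors defining planted
#'   programs; \code{NULL} auto-creates disjoint programs of
#'   \code{programSize} non-mitochondrial genes, one per entry of
#'   \code{programAssignments}.
#' @param programAssignments named list mapping cluster id (\code{"0"} ...
#'   \code{"nClusters-1"}) to the program names it carries. Default plants
#'   one 50-gene program \code{"prog1"} in cluster \code{"1"}.
#' @param programLog2Effect log2 fold applied to program-gene means in
#'   carrier cells; 0 makes all clusters exchangeable.
#' @param baselineMeanLogMu,baselineMeanLogSigma log-normal parameters of
#'   baseline gene means.
#' @param nbDispersion shared negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}).
#' @param mitoFractionGenes fraction of genes flagged mitochondrial (named
#'   with the \code{MT-} prefix).
#' @param libSizeSigma sdlog of the per-cell log-normal library-size factor.
#' @param qcMinGenes,qcMaxMitoFrac the QC thresholds the forced-failure
#'   cells are pushed across (low-depth cells end below \code{qcMinGenes}
#'   expressed genes; high-mito cells above \code{qcMaxMitoFrac}).
#' @param nLowdepthCells,nHighmitoCells,nDoublets numbers of cells forced
#'   to fail each QC rule.
#' @param programSize genes per auto-created program.
#' @param seed root integer seed.
#' @return A validated list of class \code{"SimConfig"}.
#' @seealso [simulateCounts()]
#' @export
simConfig <- function(nGenes = 3000, nCells = 2000, nClusters = 4,
                      clusterProportions = NULL,
                      programs = NULL,
                      programAssignments = list("1" = "prog1"),
                      programLog2Effect = 2,
                      baselineMeanLogMu = 0,
                      baselineMeanLogSigma = 1.2,
                      nbDispersion = 0.4,
                      mitoFractionGenes = 0.02,
                      libSizeSigma = 0.3,
                      qcMinGenes = 800,
                      qcMaxMitoFrac = 0.15,
                      nLowdepthCells = 0,
                      nHighmitoCells = 0,
                      nDoublets = 0,
                      programSize = 50,
                      seed = 1) {
    if (is.null(clusterProportions))
        clusterProportions <- rep(1 / nClusters, nClusters)
    config <- list(
        nGenes = as.integer(nGenes), nCells = as.integer(nCells),
        nClusters = as.integer(nClusters),
        clusterProportions = clusterProportions,
        programs = programs,
        programAssignments = programAssignments,
        programLog2Effect = programLog2Effect,
        baselineMeanLogMu = baselineMeanLogMu,
        baselineMeanLogSigma = baselineMeanLogSigma,
        nbDispersion = nbDispersion,
        mitoFractionGenes = mitoFractionGenes,
        libSizeSigma = libSizeSigma,
        qcMinGenes = as.integer(qcMinGenes),
        qcMaxMitoFrac = qcMaxMitoFrac,
        nLowdepthCells = as.integer(nLowdepthCells),
        nHighmitoCells = as.integer(nHighmitoCells),
        nDoublets = as.integer(nDoublets),
        programSize = as.integer(programSize),
        seed = as.integer(seed))
    class(config) <- "SimConfig"
    .simValidate(config)
    config
}

.simValidate <- function(config) {
    if (config$nGenes < 1L || config$nCells < 1L)
        stop("simulation requires at least one gene and one cell")
    if (config$nClusters < 1L)
        stop("'nClusters' must be positive")
    if (abs(sum(config$clusterProportions) - 1) > 1e-9)
        stop("'clusterProportions' must sum to 1")
    if (any(config$clusterProportions < 0))
        stop("'clusterProportions' must be non-negative")
    if (config$nbDispersion <= 0)
        stop("'nbDispersion' must be positive")
    if (config$mitoFractionGenes < 0 || config$mitoFractionGenes >= 1)
        stop("'mitoFractionGenes' must lie in [0, 1)")
    nForced <- config$nLowdepthCells + config$nHighmitoCells +
        config$nDoublets
    if (any(c(config$nLowdepthCells, config$nHighmitoCells,
              config$nDoublets) < 0L))
        stop("forced-failure cell counts must be non-negative")
    if (nForced > config$nCells)
        stop("more forced QC failures than cells")
    if (config$programLog2Effect < 0)
        stop("'programLog2Effect' must be >= 0")
    if (length(config$programAssignments) > 0) {
        ids <- suppressWarnings(as.integer(names(config$programAssignments)))
        if (any(is.na(ids)) || any(ids < 0) || any(ids >= config$nClusters))
            stop("'programAssignments' names must be cluster ids in 0..",
                 config$nClusters - 1L)
    }
    invisible(TRUE)
}

# Gene names, mitochondrial flags and planted program membership.
# extraSymbols are substituted into the (non-mito) gene universe so that
# externally supplied lists (e.g. cell-cycle genes) are present.
.simGeneMeta <- function(config, extraSymbols = character(0)) {
    nMito <- round(config$nGenes * config$mitoFractionGenes)
    geneNames <- sprintf("G%05d", seq_len(config$nGenes))
    if (nMito > 0)
        geneNames[seq_len(nMito)] <- sprintf("MT-%d", seq_len(nMito))
    mitoFlag <- seq_len(config$nGenes) <= nMito

    programs <- config$programs
    progNames <- unique(unlist(config$programAssignments, use.names = FALSE))
    if (is.null(programs) && length(progNames) > 0) {
        # Deterministic layout: programs occupy consecutive non-mito genes
        # after any reserved extra symbols.
        start <- nMito + length(extraSymbols) + 1L
        programs <- list()
        for (p in progNames) {
            idx <- seq(start, length.out = config$programSize)
            if (max(idx) > config$nGenes)
                stop("gene universe too small for the requested programs")
            programs[[p]] <- geneNames[idx]
            start <- start + config$programSize
        }
    }
    if (length(extraSymbols) > 0) {
        slots <- seq(nMito + 1L, length.out = length(extraSymbols))
        if (max(slots) > config$nGenes)
            stop("gene universe too small for the supplied gene lists")
        geneNames[slots] <- extraSymbols
    }
    for (p in names(programs)) {
        if (!all(programs[[p]] %in% geneNames))
            stop("program '", p, "' contains genes outside the gene universe")
    }
    list(geneNames = geneNames, mitoFlag = mitoFlag, programs = programs)
}

# Core generator shared by simulateCounts() and simulateCyclePrograms().
# phaseSpec, when non-NULL, is list(sGenes, g2mGenes, carrierFraction,
# effect) and adds an S/G2M program layer with recorded true phase.
.simulateCore <- function(config, phaseSpec = NULL) {
    .simValidate(config)
    extra <- if (!is.null(phaseSpec)) {
        c(phaseSpec$sGenes, phaseSpec$g2mGenes)
    } else {
        # seed the universe with the standard cycle symbols (when they
        # fit) so phase scoring is exercisable on any simulation
        cyc <- c(cycleGenes()$s, cycleGenes()$g2m)
        nMito <- round(config$nGenes * config$mitoFractionGenes)
        nProg <- length(unique(unlist(config$programAssignments,
                                      use.names = FALSE)))
        need <- nMito + length(cyc) +
            if (is.null(config$programs)) nProg * config$programSize else 0
        if (need <= config$nGenes) cyc else character(0)
    }
    meta <- .simGeneMeta(config, extraSymbols = extra)
    geneNames <- meta$geneNames
    nG <- config$nGenes
    nC <- config$nCells

    baseMu <- .withSeed(.subSeed(config$seed, 1L),
        stats::rlnorm(nG, config$baselineMeanLogMu,
                      config$baselineMeanLogSigma))
    # program genes (planted or phase) come from the expressed regime:
    # their baseline mean is floored at the median gene mean, since gene
    # signatures are defined on detectably expressed genes
    progGenes <- unique(c(unlist(meta$programs, use.names = FALSE), extra))
    if (length(progGenes) > 0) {
        rows <- match(progGenes, geneNames)
        baseMu[rows] <- pmax(baseMu[rows], exp(config$baselineMeanLogMu))
    }
    clust <- .withSeed(.subSeed(config$seed, 2L),
        sample.int(config$nClusters, nC, replace = TRUE,
                   prob = config$clusterProportions)) - 1L
    lib <- .withSeed(.subSeed(config$seed, 3L),
        stats::rlnorm(nC, 0, config$libSizeSigma))

    # cluster x gene multiplier for planted programs
    progMult <- matrix(1, nrow = nG, ncol = config$nClusters)
    for (cl in names(config$programAssignments)) {
        k <- as.integer(cl) + 1L
        for (p in config$programAssignments[[cl]]) {
            rows <- match(meta$programs[[p]], geneNames)
            progMult[rows, k] <- progMult[rows, k] *
                2^config$programLog2Effect
        }
    }

    mu <- baseMu * progMult[, clust + 1L, drop = FALSE]

    phase <- NULL
    if (!is.null(phaseSpec)) {
        if (length(phaseSpec$sGenes) == 0 || length(phaseSpec$g2mGenes) == 0)
            stop("S and G2M gene lists must both be nonempty")
        if (length(intersect(phaseSpec$sGenes, phaseSpec$g2mGenes)) > 0)
            stop("S and G2M gene lists must be disjoint")
        cf <- rep_len(phaseSpec$carrierFraction, config$nClusters)
        phase <- .withSeed(.subSeed(config$seed, 6L), {
            ph <- rep("G1", nC)
            carriers <- which(stats::runif(nC) < cf[clust + 1L])
            ph[carriers] <- sample(c("S", "G2M"), length(carriers),
                                   replace = TRUE)
            ph
        })
        eff <- 2^phaseSpec$effect
        sRows <- match(phaseSpec$sGenes, geneNames)
        gRows <- match(phaseSpec$g2mGenes, geneNames)
        mu[sRows, phase == "S"] <- mu[sRows, phase == "S"] * eff
        mu[gRows, phase == "G2M"] <- mu[gRows, phase == "G2M"] * eff
    }

    mu <- sweep(mu, 2L, lib, "*")
    counts <- .withSeed(.subSeed(config$seed, 4L),
        matrix(stats::rnbinom(nG * nC, mu = as.vector(mu),
                              size = 1 / config$nbDispersion),
               nrow = nG))

    # QC ground truth: disjoint designated failure cells
    qcFail <- rep("none", nC)
    nForced <- config$nLowdepthCells + config$nHighmitoCells +
        config$nDoublets
    if (nForced > 0) {
        forced <- .withSeed(.subSeed(config$seed, 5L),
                            sample.int(nC, nForced))
        lowIdx <- forced[seq_len(config$nLowdepthCells)]
        hiIdx <- forced[config$nLowdepthCells +
                        seq_len(config$nHighmitoCells)]
        dblIdx <- forced[config$nLowdepthCells + config$nHighmitoCells +
                         seq_len(config$nDoublets)]
        qcFail[lowIdx] <- "lowdepth"
        qcFail[hiIdx] <- "highmito"
        qcFail[dblIdx] <- "doublet"

        counts <- .withSeed(.subSeed(config$seed, 7L), {
            target <- max(1L, config$qcMinGenes %/% 2L)
            for (i in lowIdx) {
                expressed <- which(counts[, i] > 0 & !meta$mitoFlag)
                keep <- if (length(expressed) > target)
                    sample(expressed, target) else expressed
                drop <- setdiff(seq_len(nG), keep)
                counts[drop, i] <- 0L
            }
            fr <- min(2 * config$qcMaxMitoFrac, 0.45)
            for (i in hiIdx) {
                tot <- sum(counts[, i])
                mitoNow <- sum(counts[meta$mitoFlag, i])
                need <- ceiling(fr * (tot - mitoNow) / (1 - fr))
                if (need > mitoNow) {
                    add <- need - mitoNow
                    w <- which(meta$mitoFlag)
                    counts[w[1L], i] <- counts[w[1L], i] + add
                }
            }
            normalCells <- which(qcFail == "none")
            for (i in dblIdx) {
                partner <- sample(normalCells, 1L)
                counts[, i] <- counts[, i] + counts[, partner]
            }
            counts
        })
    }

    barcodes <- sprintf("CELL%05d", seq_len(nC))
    dimnames(counts) <- list(geneNames, barcodes)

    planted <- lapply(names(meta$programs), function(p)
        geneSignature(p, meta$programs[[p]], direction = "up",
                      provenance = "planted simulation program"))
    names(planted) <- names(meta$programs)

    programOf <- rep(NA_character_, nG)
    for (p in names(meta$programs))
        programOf[match(meta$programs[[p]], geneNames)] <- p

    cd <- S4Vectors::DataFrame(
        barcode = barcodes,
        batch = "batch1",
        trueCluster = factor(clust, levels = 0:(config$nClusters - 1L)),
        qcFail = factor(qcFail,
                        levels = c("none", "lowdepth", "highmito", "doublet")),
        row.names = barcodes)
    if (!is.null(phase))
        cd$truePhase <- factor(phase, levels = c("G1", "S", "G2M"))

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = cd,
        rowData = S4Vectors::DataFrame(
            gene = geneNames, mito = meta$mitoFlag, program = programOf,
            row.names = geneNames))
    S4Vectors::metadata(sce)$sim_config <- config
    S4Vectors::metadata(sce)$planted_signatures <- planted
    S4Vectors::metadata(sce)$provenance <- .provenance(config, config$seed)
    sce
}

#' Simulate a gene x cell count matrix with planted programs
#'
#' Draws negative-binomial counts with cluster-specific means per
#' [simConfig()], returning a [SingleCellExperiment::SingleCellExperiment]
#' whose \code{colData} carries the ground truth (\code{trueCluster},
#' \code{qcFail}) and whose metadata carries the planted program gene sets
#' as [GeneSignature-class] objects (see [plantedSignatures()]).
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return A \code{SingleCellExperiment} with a sparse \code{counts} assay.
#' @examples
#' sce <- simulateCounts(simConfig(nGenes = 300, nCells = 100,
#'                                 programSize = 20, seed = 7))
#' table(sce$trueCluster)
#' @export
simulateCounts <- function(config) {
    if (!inherits(config, "SimConfig"))
        stop("'config' must be created by simConfig()")
    .simulateCore(config)
}

#' Simulate counts with S/G2M proliferation programs and quiescent cells
#'
#' Adds a cell-cycle layer to the simulation: a \code{carrierFraction} of
#' cells is split between an S-program-on and a G2M-program-on state (their
#' respective gene lists boosted by \code{2^cycleLog2Effect}), while
#' non-carriers ("quiescent" cells) express neither program above baseline.
#' The true phase of every cell is recorded in \code{colData(.)$truePhase}.
#'
#' @param config a \code{SimConfig}; the S and G2M symbols are placed into
#'   its gene universe.
#' @param sGenes,g2mGenes disjoint, nonempty gene-symbol vectors (defaults:
#'   the packaged human lists, [cycleGenes()]).
#' @param carrierFraction fraction of cells carrying a proliferation
#'   program (0 gives an entirely quiescent population). May be a vector
#'   with one fraction per cluster (recycled), e.g. to plant a quiescent
#'   cluster among proliferative ones.
#' @param cycleLog2Effect log2 boost applied to program genes in carrier
#'   cells.
#' @return A \code{SingleCellExperiment} as in [simulateCounts()], with
#'   \code{truePhase} ground truth.
#' @export
simulateCyclePrograms <- function(config,
                                  sGenes = cycleGenes()$s,
                                  g2mGenes = cycleGenes()$g2m,
                                  carrierFraction = 0.5,
                                  cycleLog2Effect = 2) {
    if (!inherits(config, "SimConfig"))
        stop("'config' must be created by simConfig()")
    if (any(carrierFraction < 0) || any(carrierFraction > 1))
        stop("'carrierFraction' must lie in [0, 1]")
    .simulateCore(config, phaseSpec = list(
        sGenes = sGenes, g2mGenes = g2mGenes,
        carrierFraction = carrierFraction, effect = cycleLog2Effect))
}

#' Planted program signatures of a simulation
#'
#' @param sce a simulated \code{SingleCellExperiment}.
#' @return Named list of [GeneSignature-class] objects.
#' @export
plantedSignatures <- function(sce) {
    S4Vectors::metadata(sce)$planted_signatures
}

#' Simulate a bulk tumor cohort with a signature-positive subgroup
#'
#' Emulates a cBioPortal-style expression + clinical cohort: per-gene
#' z-scaled expression is standard normal, a \code{posFraction} subgroup has
#' its signature-gene expression shifted up by \code{zShift} standard
#' deviations, relapse-free and overall survival times are exponential with
#' the positive subgroup's hazard multiplied by \code{hazardRatio}, with
#' independent exponential censoring, and grade / molecular-subtype columns
#' are drawn with odds enrichment of high grade and Luminal B in positives.
#'
#' @param nTumors cohort size.
#' @param signature a [GeneSignature-class]; its genes form part of the
#'   simulated gene universe.
#' @param posFraction fraction of signature-positive tumors (in (0, 1),
#'   or 0 for a fully negative cohort).
#' @param zShift expression shift (in SDs) of signature genes in positives.
#' @param hazardRatio hazard multiplier for positives (> 0).
#' @param censorRate approximate fraction of censored observations.
#' @param gradeOdds,subtypeOdds odds multipliers for high grade / Luminal B
#'   in positives.
#' @param nNoiseGenes unrelated genes added to the universe.
#' @param baselineMedianMonths median relapse-free survival of negatives.
#' @param geneUniverse optional explicit gene universe; signature genes
#'   absent from it are an error.
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with an
#'   \code{expr} assay (genes x tumors) and clinical \code{colData}
#'   (\code{grade}, \code{subtype}, \code{rfs_months}, \code{rfs_event},
#'   \code{os_months}, \code{os_event}, plus ground-truth
#'   \code{truePositive}).
#' @export
simulateCohort <- function(nTumors = 1000, signature,
                           posFraction = 0.2, zShift = 3,
                           hazardRatio = 3, censorRate = 0.2,
                           gradeOdds = 3, subtypeOdds = 3,
                           nNoiseGenes = 200,
                           baselineMedianMonths = 120,
                           geneUniverse = NULL, seed = 1) {
    stopifnot(methods::is(signature, "GeneSignature"))
    if (posFraction < 0 || posFraction >= 1)
        stop("'posFraction' must lie in [0, 1)")
    if (hazardRatio <= 0) stop("'hazardRatio' must be positive")
    sig <- sigGenes(signature)
    if (is.null(geneUniverse)) {
        geneUniverse <- c(sig, sprintf("NOISE%04d", seq_len(nNoiseGenes)))
    } else if (!all(sig %in% geneUniverse)) {
        stop("signature genes absent from the simulated gene universe: ",
             paste(setdiff(sig, geneUniverse), collapse = ", "))
    }
    nG <- length(geneUniverse)
    tumors <- sprintf("TUMOR%04d", seq_len(nTumors))

    res <- .withSeed(seed, {
        positive <- stats::runif(nTumors) < posFraction
        expr <- matrix(stats::rnorm(nG * nTumors), nrow = nG,
                       dimnames = list(geneUniverse, tumors))
        expr[sig, positive] <- expr[sig, positive] + zShift

        lambdaRFS <- log(2) / baselineMedianMonths
        lambdaOS <- log(2) / (1.5 * baselineMedianMonths)
        cr <- max(censorRate, 1e-6)
        drawSurv <- function(lambda0) {
            rate <- lambda0 * ifelse(positive, hazardRatio, 1)
            t <- stats::rexp(nTumors, rate)
            cens <- stats::rexp(nTumors, lambda0 * cr / (1 - cr))
            list(time = pmin(t, cens), event = as.integer(t <= cens))
        }
        rfs <- drawSurv(lambdaRFS)
        os <- drawSurv(lambdaOS)

        oddsShift <- function(p, odds, on) {
            pp <- ifelse(on, odds * p / (1 + (odds - 1) * p), p)
            stats::runif(nTumors) < pp
        }
        highGrade <- oddsShift(0.3, gradeOdds, positive)
        grade <- ifelse(highGrade, "G3",
                        ifelse(stats::runif(nTumors) < 0.3, "G1", "G2"))
        lumB <- oddsShift(0.3, subtypeOdds, positive)
        subtype <- ifelse(lumB, "LumB", "LumA")
        list(positive = positive, expr = expr, rfs = rfs, os = os,
             grade = grade, subtype = subtype)
    })

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = res$expr),
        colData = S4Vectors::DataFrame(
            tumor = tumors,
            truePositive = res$positive,
            grade = factor(res$grade, levels = c("G1", "G2", "G3")),
            subtype = factor(res$subtype, levels = c("LumA", "LumB")),
            rfs_months = res$rfs$time, rfs_event = res$rfs$event,
            os_months = res$os$time, os_event = res$os$event,
            row.names = tumors))
    S4Vectors::metadata(se)$provenance <- .provenance(
        list(nTumors = nTumors, posFraction = posFraction, zShift = zShift,
             hazardRatio = hazardRatio, censorRate = censorRate), seed)
    se
}

#' Simulate a single-hit Poisson limiting-dilution experiment
#'
#' Each well receiving \eqn{d} cells responds independently with probability
#' \eqn{1 - e^{-f d}}, where \eqn{f} is the active-cell frequency.
#'
#' @param frequency active cells per cell, in \eqn{[0, 1]}.
#' @param doses vector of positive cell doses.
#' @param wellsPerDose wells tested at each dose.
#' @param group group label.
#' @param seed integer seed.
#' @return A limiting-dilution table: \code{data.frame(dose, tested,
#'   response, group)}.
#' @examples
#' simulateLimitingDilution(1 / 1000, c(100, 1000, 10000), 20, seed = 1)
#' @export
simulateLimitingDilution <- function(frequency, doses, wellsPerDose = 20,
                                     group = "group1", seed = 1) {
    if (frequency < 0 || frequency > 1)
        stop("'frequency' must lie in [0, 1]")
    if (any(doses <= 0)) stop("'doses' must be positive")
    p <- 1 - exp(-frequency * doses)
    response <- .withSeed(seed,
        stats::rbinom(length(doses), wellsPerDose, p))
    data.frame(dose = doses, tested = wellsPerDose,
               response = response, group = group,
               stringsAsFactors = FALSE)
}
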