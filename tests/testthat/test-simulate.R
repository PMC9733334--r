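test_that("simulation is reproducible and validates its configuration", {
    cfg <- simConfig(nGenes = 200, nCells = 80, nClusters = 2, seed = 5,
                     programSize = 20, qcMinGenes = 40)
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                     as.matrix(SummarizedExperiment::assay(b, "counts")))
    expect_identical(a$trueCluster, b$trueCluster)

    expect_error(simConfig(nGenes = 0), "at least one gene")
    expect_error(simConfig(nCells = 0), "at least one gene and one cell")
    expect_error(simConfig(clusterProportions = c(0.5, 0.4)), "sum to 1")
    expect_error(simConfig(nbDispersion = 0), "positive")
    expect_error(simConfig(nCells = 10, nLowdepthCells = 11),
                 "more forced QC failures")
})

test_that("forced QC failures are planted exactly as labelled", {
    cfg <- simConfig(nGenes = 500, nCells = 200, nClusters = 2,
                     qcMinGenes = 120, nLowdepthCells = 10,
                     nHighmitoCells = 5, nDoublets = 4, seed = 17,
                     programSize = 25)
    sce <- simulateCounts(cfg)
    counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    mito <- SummarizedExperiment::rowData(sce)$mito

    low <- colnames(sce)[sce$qcFail == "lowdepth"]
    expect_true(all(colSums(counts[, low, drop = FALSE] > 0) < 120))
    hi <- colnames(sce)[sce$qcFail == "highmito"]
    fr <- colSums(counts[mito, hi, drop = FALSE]) / colSums(counts[, hi,
                                                                   drop = FALSE])
    expect_true(all(fr > 0.15))

    filtered <- qcFilter(sce, minGenes = 120, maxMitoFrac = 0.15,
                         doubletLabels = sce$qcFail == "doublet")
    removed <- setdiff(colnames(sce), colnames(filtered))
    expect_setequal(removed, colnames(sce)[sce$qcFail != "none"])
    expect_equal(length(removed), 19)
})

test_that("zero planted effect makes clusters exchangeable for scoring", {
    sce <- smallExperiment(nGenes = 600, nCells = 2000, nClusters = 2,
                           effect = 0, seed = 301)
    sc <- scoreSignature(sce, plantedSignatures(sce)$prog1)
    for (id in c("0", "1")) {
        auc <- aucEnrichment(sc, sce$trueCluster, id)$auc
        expect_gte(auc, 0.45)
        expect_lte(auc, 0.55)
    }
})

test_that("planted-program AUC is non-decreasing in effect size", {
    aucs <- vapply(c(0, 0.5, 1, 2), function(eff) {
        sce <- smallExperiment(nGenes = 500, nCells = 2000, nClusters = 2,
                               effect = eff, seed = 77)
        sc <- scoreSignature(sce, plantedSignatures(sce)$prog1)
        aucEnrichment(sc, sce$trueCluster, "1")$auc
    }, numeric(1))
    expect_true(all(diff(aucs) >= 0))
    expect_gt(aucs[4], 0.9)
})

test_that("cycle-program simulation validates gene lists and records phase", {
    cfg <- simConfig(nGenes = 400, nCells = 100, nClusters = 2, seed = 9,
                     programAssignments = list(), qcMinGenes = 50)
    expect_error(simulateCyclePrograms(cfg, sGenes = c("A", "B"),
                                       g2mGenes = character(0)),
                 "nonempty")
    expect_error(simulateCyclePrograms(cfg, sGenes = c("A", "B"),
                                       g2mGenes = c("B", "C")),
                 "disjoint")
    sce <- simulateCyclePrograms(cfg, carrierFraction = 0)
    expect_true(all(sce$truePhase == "G1"))
    sce2 <- simulateCyclePrograms(cfg, carrierFraction = 1)
    expect_true(all(sce2$truePhase %in% c("S", "G2M")))
})

test_that("cohort simulation plants shift, hazard and enrichment as asked", {
    sig <- geneSignature("sig", sprintf("SG%02d", 1:15))
    co <- simulateCohort(400, sig, posFraction = 0.3, zShift = 3,
                         hazardRatio = 1, seed = 8)
    expr <- SummarizedExperiment::assay(co, "expr")
    pos <- co$truePositive
    gap <- mean(expr[sigGenes(sig), pos]) - mean(expr[sigGenes(sig), !pos])
    expect_gt(gap, 2.5)
    expect_lt(gap, 3.5)
    # noise genes unshifted
    noise <- setdiff(rownames(expr), sigGenes(sig))
    expect_lt(abs(mean(expr[noise, pos]) - mean(expr[noise, !pos])), 0.2)

    expect_error(simulateCohort(100, sig, posFraction = 1), "posFraction")
    expect_error(simulateCohort(100, sig, hazardRatio = 0), "hazardRatio")
    expect_error(simulateCohort(100, sig, geneUniverse = c("OTHER")),
                 "absent from the simulated gene universe")

    # fully negative cohort: only Gaussian-tail false calls at threshold 2
    co0 <- simulateCohort(500, sig, posFraction = 0, zShift = 3, seed = 12)
    st <- stratifyBySignature(zscoreCohort(co0), sig, threshold = 2)
    expect_lt(mean(st$positive), 0.5)
    expect_false(any(co0$truePositive))
})

test_that("limiting-dilution wells respond per the single-hit model", {
    tab0 <- simulateLimitingDilution(0, c(100, 1000), 10, seed = 3)
    expect_true(all(tab0$response == 0))
    tabSat <- simulateLimitingDilution(0.5, 1000, 30, seed = 3)
    expect_equal(tabSat$response, 30)
    expect_error(simulateLimitingDilution(1.5, 10), "frequency")
    expect_error(simulateLimitingDilution(0.1, c(-5)), "positive")
    # moderate regime: response fraction near 1 - exp(-f d)
    tab <- simulateLimitingDilution(1 / 500, 500, 400, seed = 6)
    expect_lt(abs(tab$response / 400 - (1 - exp(-1))), 0.08)
})
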