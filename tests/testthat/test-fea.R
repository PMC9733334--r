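test_that("signature scores are means of per-gene z-scores", {
    Z <- matrix(c(1, -1, 0.5, -0.5,
                  2, -2, 1, -1,
                  0, 0, 0, 0,
                  -1, 1, -0.5, 0.5,
                  3, -3, 0, 0), nrow = 5, byrow = TRUE,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
    sce <- sceFromMatrix(Z, "scaled")

    one <- scoreSignature(sce, geneSignature("s1", "g2"))
    expect_equal(cellScores(one), Z["g2", ])

    # hand-computed 3-gene means over (g1, g2, g4)
    three <- scoreSignature(sce, geneSignature("s3", c("g1", "g2", "g4")))
    expect_equal(unname(cellScores(three)),
                 c((1 + 2 - 1) / 3, (-1 - 2 + 1) / 3,
                   (0.5 + 1 - 0.5) / 3, (-0.5 - 1 + 0.5) / 3))

    # missing genes are dropped with bookkeeping; zero overlap errors
    part <- suppressWarnings(
        scoreSignature(sce, geneSignature("sp", c("g1", "nope", "nah"))))
    expect_equal(part@nGenesUsed, 1L)
    expect_equal(part@nGenesMissing, 2L)
    expect_warning(scoreSignature(sce, geneSignature("sw", c("g1", "x1",
                                                             "x2", "x3",
                                                             "x4", "x5"))),
                   "only 1 of 6")
    expect_error(scoreSignature(sce, geneSignature("sx", c("q1", "q2"))),
                 "no signature genes")
})

test_that("all-gene signature scores average to zero across cells", {
    sce <- smallExperiment(nGenes = 200, nCells = 100, seed = 71,
                           programSize = 20)
    all <- geneSignature("all", rownames(sce))
    sc <- cellScores(scoreSignature(sce, all))
    expect_lt(abs(mean(sc)), 1e-8)
})

test_that("AUC and exact p agree with brute-force oracles on random instances", {
    set.seed(909)
    for (i in 1:60) {
        nIn <- sample(2:8, 1)
        nOut <- sample(2:8, 1)
        # mix continuous and heavily tied instances
        x <- if (i %% 2 == 0) rnorm(nIn + nOut) else
            sample(1:4, nIn + nOut, replace = TRUE)
        inG <- c(rep(TRUE, nIn), rep(FALSE, nOut))
        cl <- ifelse(inG, "in", "out")
        res <- aucEnrichment(setNames(x, paste0("c", seq_along(x))),
                             cl, "in")
        expect_equal(res$auc, bruteForceAUC(x[inG], x[!inG]))
        expect_equal(res$p_value, enumRankSumP(x, inG))
        # tie-free instances also match base R's exact Wilcoxon p
        if (i %% 2 == 0) {
            wp <- wilcox.test(x[inG], x[!inG], exact = TRUE)$p.value
            expect_equal(res$p_value, wp)
        }
    }
})

test_that("AUC matches an independent ROC implementation at scale", {
    skip_if_not_installed("pROC")
    set.seed(11)
    x <- c(rnorm(300, 0.5), rnorm(500))
    cl <- c(rep("in", 300), rep("out", 500))
    res <- aucEnrichment(setNames(x, paste0("c", 1:800)), cl, "in")
    ref <- as.numeric(pROC::auc(pROC::roc(cl == "in", x, quiet = TRUE,
                                          direction = "<")))
    expect_equal(res$auc, ref, tolerance = 1e-12)
    # large-sample p agrees with the tie-corrected normal Wilcoxon
    wp <- wilcox.test(x[1:300], x[301:800], correct = FALSE,
                      exact = FALSE)$p.value
    expect_equal(res$p_value, wp, tolerance = 1e-9)
})

test_that("AUC obeys label-swap antisymmetry and monotone invariance", {
    set.seed(13)
    x <- setNames(c(rnorm(40), rnorm(60, 1)), paste0("c", 1:100))
    cl <- c(rep("a", 40), rep("b", 60))
    aucA <- aucEnrichment(x, cl, "a")$auc
    aucB <- aucEnrichment(x, cl, "b")$auc
    expect_equal(aucA + aucB, 1)
    # strictly monotone transforms leave the AUC unchanged
    for (f in list(function(v) exp(v), function(v) v^3,
                   function(v) rank(v))) {
        expect_equal(aucEnrichment(setNames(f(x), names(x)), cl, "a")$auc,
                     aucA)
    }
    # degenerate cases
    perfect <- aucEnrichment(setNames(c(2, 3, 0, 1), paste0("c", 1:4)),
                             c("in", "in", "out", "out"), "in")
    expect_equal(perfect$auc, 1)
    ties <- aucEnrichment(setNames(rep(1, 10), paste0("c", 1:10)),
                          rep(c("in", "out"), 5), "in")
    expect_equal(ties$auc, 0.5)
    expect_equal(ties$p_value, 1)
    expect_error(aucEnrichment(x, cl, "zzz"), "not present")
})

test_that("enrichment tables flag only the carrier cluster and are
           invariant to relabeling", {
    sce <- smallExperiment(nGenes = 400, nCells = 600, nClusters = 3,
                           effect = 2, seed = 81)
    tab <- enrichmentTable(sce, plantedSignatures(sce),
                           clusters = sce$trueCluster)
    expect_equal(tab$cluster[tab$enriched], "1")
    expect_true(all(c("bh_p") %in% colnames(tab)))
    m <- aucMatrix(tab)
    expect_equal(dim(m), c(1L, 3L))

    # relabeled clusters: same rows up to permutation
    relab <- c("0" = "B", "1" = "C", "2" = "A")[
        as.character(sce$trueCluster)]
    tab2 <- enrichmentTable(sce, plantedSignatures(sce), clusters = relab)
    ord1 <- tab[order(tab$auc), c("auc", "p_value", "enriched")]
    ord2 <- tab2[order(tab2$auc), c("auc", "p_value", "enriched")]
    expect_equal(unname(as.matrix(ord1[, 1:2])),
                 unname(as.matrix(ord2[, 1:2])))

    expect_error(enrichmentTable(sce, plantedSignatures(sce),
                                 clusters = rep("0", ncol(sce))),
                 "at least two clusters")
    expect_error(enrichmentTable(sce, list()), "no signatures")
})

test_that("correlation bands follow the 0.3-0.5 / 0.5-0.9 convention", {
    mkScores <- function(v, nm) new("SignatureScores", name = nm,
                                    scores = setNames(v, paste0("c",
                                                     seq_along(v))),
                                    nGenesUsed = 5L, nGenesMissing = 0L)
    set.seed(5)
    x <- rnorm(400)
    z <- rnorm(400)
    x <- (x - mean(x)) / sd(x)
    z <- resid(lm(z ~ x)); z <- z / sd(z)   # exactly orthogonal to x
    for (r in c(0.1, 0.4, 0.7)) {
        y <- r * x + sqrt(1 - r^2) * z
        res <- signatureCorrelation(mkScores(x, "a"), mkScores(y, "b"))
        expect_equal(res$pearson_r, r, tolerance = 1e-9)
        expect_equal(res$band_label,
                     if (r < 0.3) "none" else if (r < 0.5) "moderate"
                     else "strong")
    }
    ident <- signatureCorrelation(mkScores(x, "a"), mkScores(x, "a"))
    expect_equal(ident$pearson_r, 1)

    # independent scores: negligible correlation
    nullRes <- signatureCorrelation(mkScores(x, "a"), mkScores(z, "b"))
    expect_lt(abs(nullRes$pearson_r), 0.1)

    expect_error(signatureCorrelation(mkScores(x, "a"),
                                      mkScores(rep(1, 400), "b")),
                 "zero variance")
    expect_error(signatureCorrelation(mkScores(x, "a"), mkScores(z, "b"),
                                      cellSubset = c("c1", "c2")),
                 "at least 3 cells")
})

test_that("signature regression recovers planted coefficients", {
    mkScores <- function(v, nm) new("SignatureScores", name = nm,
                                    scores = setNames(v, paste0("c",
                                                     seq_along(v))),
                                    nGenesUsed = 5L, nGenesMissing = 0L)
    set.seed(500)
    x1 <- rnorm(500); x2 <- rnorm(500)
    y <- 2 * x1 - 1 * x2 + rnorm(500, sd = 0.1)
    fit <- signatureRegression(mkScores(y, "y"),
                               list(x1 = mkScores(x1, "x1"),
                                    x2 = mkScores(x2, "x2")))
    co <- fit$coefficients
    expect_lt(abs(co$estimate[co$term == "x1"] - 2),
              3 * co$std_error[co$term == "x1"])
    expect_lt(abs(co$estimate[co$term == "x2"] + 1),
              3 * co$std_error[co$term == "x2"])
    expect_gt(fit$r_squared, 0.99)

    # exact fit (summary warns about the perfect fit, which is the point)
    perfect <- suppressWarnings(
        signatureRegression(mkScores(x1, "y"),
                            list(x1 = mkScores(x1, "x1"))))
    expect_equal(perfect$r_squared, 1)
    expect_equal(perfect$coefficients$estimate[2], 1)

    expect_error(signatureRegression(mkScores(y, "y"),
                                     list(a = mkScores(x1, "x1"),
                                          b = mkScores(x1, "x1"))),
                 "collinear")
})
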