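# Fixtures and independent oracles used across the suite.

# A small simulated experiment, normalized and scaled; defaults sized for
# speed in unit tests.
smallExperiment <- function(nGenes = 400, nCells = 300, nClusters = 2,
                            effect = 2, seed = 101, programSize = 30, ...) {
    cfg <- simConfig(nGenes = nGenes, nCells = nCells,
                     nClusters = nClusters, programLog2Effect = effect,
                     programSize = programSize, qcMinGenes = 50,
                     seed = seed, ...)
    scaleGenes(normalizeLog(simulateCounts(cfg)))
}

# Wrap a plain matrix as a SingleCellExperiment with the given assay name.
sceFromMatrix <- function(m, assayName = "counts") {
    a <- list(m)
    names(a) <- assayName
    SingleCellExperiment::SingleCellExperiment(assays = a)
}

# Independent AUC oracle: brute-force fraction of (in, out) pairs with
# in > out, ties counted half.
bruteForceAUC <- function(inScores, outScores) {
    tot <- 0
    for (a in inScores) for (b in outScores)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(inScores) * length(outScores))
}

# Independent exact rank-sum p oracle: full enumeration of the permutation
# null of the in-group rank sum (two-sided around its mean).
enumRankSumP <- function(x, inGroup) {
    N <- length(x)
    nIn <- sum(inGroup)
    r <- rank(x)
    obs <- sum(r[inGroup])
    mu <- nIn * (N + 1) / 2
    sets <- utils::combn(N, nIn)
    sums <- colSums(matrix(r[sets], nrow = nIn))
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table).
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(n) n * (n - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    n <- sum(tab)
    expected <- sumI * sumJ / comb2(n)
    (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}
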