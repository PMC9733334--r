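# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Deterministic stream splitting: all randomness in a simulation flows from
# one root seed; sub-stream k uses seed (root + 77003 * k) mod (2^31 - 1).
.subSeed <- function(seed, k) {
    (as.integer(seed) + 77003 * as.integer(k)) %% 2147483647L
}

# Mann-Whitney / Wilcoxon rank-sum machinery: midrank AUC, exact enumeration
# of the rank-sum null for small samples, tie-corrected normal approximation
# otherwise. This is the engine behind both cluster enrichment and marker
# detection.
#
# x: numeric scores; inGroup: logical, TRUE for the "in" group.
# exact: force exact enumeration (default: total n <= exactMax).
.rankSumTest <- function(x, inGroup, exact = NULL, exactMax = 20L) {
    stopifnot(length(x) == length(inGroup))
    nIn <- sum(inGroup)
    nOut <- sum(!inGroup)
    N <- nIn + nOut
    r <- rank(x)                       # midranks
    W <- sum(r[inGroup])
    auc <- (W - nIn * (nIn + 1) / 2) / (nIn * nOut)
    mu <- nIn * (N + 1) / 2
    ties <- tabulate(match(x, unique(x)))
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- nIn * nOut / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) {                  # all values identical
        return(list(auc = 0.5, p = 1, W = W, nIn = nIn, nOut = nOut))
    }
    if (is.null(exact)) exact <- N <= exactMax
    if (exact) {
        idx <- utils::combn(N, nIn)
        sums <- colSums(matrix(r[idx], nrow = nIn))
        p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    } else {
        z <- (W - mu) / sqrt(sigma2)
        p <- 2 * stats::pnorm(-abs(z))
    }
    list(auc = auc, p = min(p, 1), W = W, nIn = nIn, nOut = nOut)
}

# Row-wise tie-corrected normal-approximation rank-sum test for marker
# detection: Y is a genes x cells matrix, inGroup a logical over cells.
# Returns a two-sided p-value per row. Used where per-gene exact enumeration
# would be wasteful (cluster sizes are large).
.rankSumRows <- function(Y, inGroup) {
    nIn <- sum(inGroup)
    nOut <- sum(!inGroup)
    N <- nIn + nOut
    mu <- nIn * (N + 1) / 2
    apply(Y, 1L, function(y) {
        r <- rank(y)
        W <- sum(r[inGroup])
        ties <- tabulate(match(y, unique(y)))
        tieTerm <- sum(ties^3 - ties)
        sigma2 <- nIn * nOut / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
        if (sigma2 <= 0) return(1)
        2 * stats::pnorm(-abs((W - mu) / sqrt(sigma2)))
    })
}

# Dense matrix from a possibly sparse assay.
.denseMatrix <- function(m) {
    if (methods::is(m, "sparseMatrix")) as.matrix(m) else as.matrix(m)
}

.provenance <- function(config = NULL, seed = NULL) {
    list(
        tool = paste0("stemFEA ",
                      as.character(utils::packageVersion("stemFEA"))),
        config_hash = if (!is.null(config)) rlang::hash(config) else NA_character_,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
}
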