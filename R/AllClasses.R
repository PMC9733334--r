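#' GeneSignature: a named, directed gene set
#'
#' The unit of functional enrichment analysis: a named list of unique gene
#' symbols together with a direction (\code{"up"}, \code{"down"} or
#' \code{"mixed"}) and a free-text provenance string recording where the set
#' came from (an MSigDB-style collection, or the parameters of a
#' differential-expression derivation).
#'
#' @slot name single character, the signature name.
#' @slot genes character vector of unique, nonempty gene symbols.
#' @slot direction one of \code{"up"}, \code{"down"}, \code{"mixed"}.
#' @slot provenance free-text source description.
#'
#' @seealso [geneSignature()], [readGMT()], [deriveClusterSignature()]
#' @export
setClass("GeneSignature",
    representation(
        name = "character",
        genes = "character",
        direction = "character",
        provenance = "character"
    )
)

setValidity("GeneSignature", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single nonempty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "'genes' must be nonempty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "'genes' must be unique")
    if (any(!nzchar(object@genes)))
        msg <- c(msg, "'genes' must not contain empty strings")
    if (length(object@direction) != 1L ||
        !object@direction %in% c("up", "down", "mixed"))
        msg <- c(msg, "'direction' must be one of 'up', 'down', 'mixed'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param genes character vector of gene symbols; duplicates are removed with
#'   a warning.
#' @param direction direction of the set, default \code{"up"}.
#' @param provenance free-text source description.
#' @return A [GeneSignature-class] object.
#' @examples
#' geneSignature("MYSET", c("ESR1", "PGR", "GREB1"))
#' @export
geneSignature <- function(name, genes, direction = "up", provenance = "") {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) {
        warning("duplicate genes in signature '", name, "' removed")
        genes <- unique(genes)
    }
    new("GeneSignature", name = name, genes = genes,
        direction = direction, provenance = as.character(provenance))
}

#' @describeIn GeneSignature-class the gene symbols of the signature.
#' @param x a \code{GeneSignature}.
#' @export
sigGenes <- function(x) x@genes

#' @describeIn GeneSignature-class the signature name.
#' @export
sigName <- function(x) x@name

setMethod("show", "GeneSignature", function(object) {
    cat("GeneSignature '", object@name, "' (", object@direction, "), ",
        length(object@genes), " genes\n", sep = "")
    ex <- utils::head(object@genes, 6L)
    cat("  ", paste(ex, collapse = ", "),
        if (length(object@genes) > 6L) ", ..." else "", "\n", sep = "")
    if (nzchar(object@provenance))
        cat("  provenance: ", object@provenance, "\n", sep = "")
})

#' SignatureScores: per-cell z-scored signature scores
#'
#' The per-cell score of a gene signature: for each cell, the mean of the
#' gene-wise z-scores (scaled expression) over the signature genes present in
#' the matrix.
#'
#' @slot name signature name.
#' @slot scores named numeric vector, one score per cell (names are barcodes).
#' @slot nGenesUsed number of signature genes found in the matrix.
#' @slot nGenesMissing number of signature genes absent from the matrix.
#'
#' @seealso [scoreSignature()]
#' @export
setClass("SignatureScores",
    representation(
        name = "character",
        scores = "numeric",
        nGenesUsed = "integer",
        nGenesMissing = "integer"
    )
)

setValidity("SignatureScores", function(object) {
    msg <- NULL
    if (object@nGenesUsed < 1L)
        msg <- c(msg, "at least one signature gene must be used")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (is.null(names(object@scores)))
        msg <- c(msg, "scores must be named by cell barcode")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SignatureScores-class the named per-cell score vector.
#' @param x a \code{SignatureScores}.
#' @export
cellScores <- function(x) x@scores

setMethod("show", "SignatureScores", function(object) {
    cat("SignatureScores '", object@name, "': ", length(object@scores),
        " cells, ", object@nGenesUsed, " genes used (",
        object@nGenesMissing, " missing)\n", sep = "")
    cat("  score range: [", signif(min(object@scores), 4), ", ",
        signif(max(object@scores), 4), "]\n", sep = "")
})

#' LDAEstimate: single-hit Poisson limiting-dilution frequency estimate
#'
#' Result of fitting the single-hit model
#' \eqn{P(\mathrm{response} \mid d) = 1 - e^{-f d}} to a limiting-dilution
#' table: the maximum-likelihood active-cell frequency \eqn{f}, a 95\% Wald
#' confidence interval on the log scale, and a saturation flag for designs
#' where every well (or no well) responded and only a one-sided bound exists.
#'
#' @slot group group label.
#' @slot frequency estimated active-cell frequency (active cells per cell).
#' @slot ciLower,ciUpper 95\% confidence bounds on the frequency.
#' @slot saturation one of \code{"none"}, \code{"all_respond"},
#'   \code{"none_respond"}.
#' @slot logLik maximized log-likelihood (NA when saturated).
#'
#' @seealso [estimateFrequency()], [compareFrequencies()]
#' @export
setClass("LDAEstimate",
    representation(
        group = "character",
        frequency = "numeric",
        ciLower = "numeric",
        ciUpper = "numeric",
        saturation = "character",
        logLik = "numeric"
    )
)

setValidity("LDAEstimate", function(object) {
    msg <- NULL
    if (!object@saturation %in% c("none", "all_respond", "none_respond"))
        msg <- c(msg, "invalid saturation flag")
    f <- object@frequency
    if (is.finite(f) && (f < 0 || f > 1))
        msg <- c(msg, "frequency must lie in [0, 1]")
    if (object@saturation == "none" &&
        (object@ciLower > f || object@ciUpper < f))
        msg <- c(msg, "confidence interval must contain the point estimate")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn LDAEstimate-class the estimated frequency.
#' @param x an \code{LDAEstimate}.
#' @export
frequency <- function(x) x@frequency

#' @describeIn LDAEstimate-class lower and upper 95\% confidence bounds.
#' @export
frequencyCI <- function(x) c(lower = x@ciLower, upper = x@ciUpper)

.asOneIn <- function(f) {
    if (!is.finite(f) || f <= 0) return("-")
    paste0("1/", format(round(1 / f, 1), big.mark = ","))
}

setMethod("show", "LDAEstimate", function(object) {
    cat("LDAEstimate", if (nzchar(object@group))
        paste0("[", object@group, "]"), "\n")
    cat("  frequency: ", signif(object@frequency, 4), " (",
        .asOneIn(object@frequency), ")\n", sep = "")
    cat("  95% CI: [", signif(object@ciLower, 4), ", ",
        signif(object@ciUpper, 4), "]  (",
        .asOneIn(object@ciUpper), " - ", .asOneIn(object@ciLower), ")\n",
        sep = "")
    if (object@saturation != "none")
        cat("  saturated design (", object@saturation,
            "): one-sided 95% bound reported\n", sep = "")
})
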