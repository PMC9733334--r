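.checkLDATable <- function(table) {
    need <- c("dose", "tested", "response")
    if (!all(need %in% colnames(table)))
        stop("limiting-dilution table needs columns: ",
             paste(need, collapse = ", "))
    if (nrow(table) == 0) stop("empty limiting-dilution table")
    if (any(table$dose <= 0)) stop("doses must be positive")
    if (any(table$tested <= 0)) stop("wells tested must be positive")
    if (any(table$response < 0 | table$response > table$tested))
        stop("responses must lie in [0, wells tested]")
    invisible(TRUE)
}

# log-likelihood of the single-hit model at frequency f
.ldaLogLik <- function(f, table) {
    p <- 1 - exp(-f * table$dose)
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    sum(table$response * log(p) +
        (table$tested - table$response) * log1p(-p))
}

#' Single-hit Poisson limiting-dilution frequency estimate
#'
#' Fits \eqn{P(\mathrm{response} \mid d) = 1 - e^{-f d}} by maximum
#' likelihood through a binomial GLM with complementary log-log link and
#' offset \eqn{\log d}; the active-cell frequency is
#' \eqn{f = e^{\hat\beta_0}} with a 95\% Wald confidence interval on the
#' log scale. For a single dose the MLE reduces to the closed form
#' \eqn{f = -\log(1 - r/n)/d}. Saturated designs (every well responded, or
#' none did) have no interior MLE; they are flagged and a one-sided 95\%
#' likelihood bound is reported instead of a divergent fit.
#'
#' @param table \code{data.frame} with columns \code{dose} (cells per
#'   well), \code{tested} (wells), \code{response} (responding wells), and
#'   optionally \code{group}.
#' @param conf confidence level (default 0.95).
#' @return An [LDAEstimate-class].
#' @examples
#' tab <- data.frame(dose = c(100, 1000, 10000), tested = 6,
#'                   response = c(1, 4, 6))
#' estimateFrequency(tab)
#' @export
estimateFrequency <- function(table, conf = 0.95) {
    .checkLDATable(table)
    group <- if ("group" %in% colnames(table))
        as.character(table$group[1]) else ""
    alpha <- 1 - conf
    totalCells <- sum(table$tested * table$dose)

    if (sum(table$response) == 0) {
        # no well responded: MLE 0, one-sided upper bound from
        # P(no response | f) = alpha
        upper <- -log(alpha) / totalCells
        return(new("LDAEstimate", group = group, frequency = 0,
                   ciLower = 0, ciUpper = min(upper, 1),
                   saturation = "none_respond", logLik = NA_real_))
    }
    if (all(table$response == table$tested)) {
        # every well responded: likelihood increases in f, no finite MLE;
        # one-sided lower bound from P(all respond | f) = alpha
        fLow <- stats::uniroot(function(lf)
            .ldaLogLik(exp(lf), table) - log(alpha),
            lower = log(1e-12), upper = 0, tol = 1e-12)$root
        return(new("LDAEstimate", group = group, frequency = 1,
                   ciLower = min(exp(fLow), 1), ciUpper = 1,
                   saturation = "all_respond", logLik = NA_real_))
    }

    # high doses legitimately push fitted p to 1; the resulting glm.fit
    # warning is expected for single-hit designs with a saturating dose
    fit <- suppressWarnings(
        stats::glm(cbind(response, tested - response) ~ 1,
                   family = stats::binomial(link = "cloglog"),
                   offset = log(dose), data = table))
    beta <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    zq <- stats::qnorm(1 - alpha / 2)
    f <- exp(beta)
    new("LDAEstimate", group = group,
        frequency = min(f, 1),
        ciLower = min(exp(beta - zq * se), 1),
        ciUpper = min(exp(beta + zq * se), 1),
        saturation = "none",
        logLik = .ldaLogLik(f, table))
}

#' Likelihood-ratio comparison of limiting-dilution frequencies
#'
#' Tests equality of active-cell frequency across groups: the deviance of
#' a pooled single-frequency fit minus the summed deviances of per-group
#' fits, referred to a chi-squared distribution with
#' \code{groups - 1} degrees of freedom.
#'
#' @param tables either one \code{data.frame} with a \code{group} column or
#'   a named list of per-group tables.
#' @return List: \code{statistic}, \code{df}, \code{p_value},
#'   \code{estimates} (list of per-group [LDAEstimate-class] objects).
#' @export
compareFrequencies <- function(tables) {
    if (is.data.frame(tables)) {
        if (!"group" %in% colnames(tables))
            stop("a single table must carry a 'group' column")
        tables <- split(tables, tables$group)
    }
    if (length(tables) < 2) stop("at least two groups are required")
    lapply(tables, .checkLDATable)
    saturated <- vapply(tables, function(t)
        sum(t$response) == 0 || all(t$response == t$tested), logical(1))
    if (any(saturated))
        stop("saturated group(s) cannot enter the likelihood-ratio test: ",
             paste(names(tables)[saturated], collapse = ", "))

    estimates <- lapply(names(tables), function(g) {
        t <- tables[[g]]; t$group <- g
        estimateFrequency(t)
    })
    names(estimates) <- names(tables)

    pooled <- do.call(rbind, lapply(tables, function(t)
        t[, c("dose", "tested", "response")]))
    fitOne <- function(t) suppressWarnings(stats::glm(
        cbind(response, tested - response) ~ 1,
        family = stats::binomial(link = "cloglog"),
        offset = log(dose), data = t))
    devPooled <- stats::deviance(fitOne(pooled))
    devSep <- sum(vapply(tables, function(t)
        stats::deviance(fitOne(t)), numeric(1)))
    stat <- max(devPooled - devSep, 0)
    df <- length(tables) - 1L
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         estimates = estimates)
}

#' Read a limiting-dilution table from TSV
#'
#' Expected columns: \code{dose, tested, response} and optionally
#' \code{group}.
#'
#' @param path TSV file path.
#' @return Validated \code{data.frame}.
#' @export
readLDATable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .checkLDATable(tab)
    tab
}
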