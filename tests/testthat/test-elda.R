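test_that("single-dose estimates reduce to the closed form", {
    for (r in c(1, 3, 5)) {
        tab <- data.frame(dose = 200, tested = 6, response = r)
        est <- estimateFrequency(tab)
        expect_equal(frequency(est), -log(1 - r / 6) / 200,
                     tolerance = 1e-6)
        expect_equal(est@saturation, "none")
        ci <- frequencyCI(est)
        expect_lte(ci["lower"], frequency(est))
        expect_gte(ci["upper"], frequency(est))
    }
})

test_that("saturated designs are flagged with one-sided bounds", {
    allResp <- data.frame(dose = c(100, 1000), tested = 6,
                          response = c(6, 6))
    up <- estimateFrequency(allResp)
    expect_equal(up@saturation, "all_respond")
    expect_lt(up@ciLower, 1)
    expect_gt(up@ciLower, 0)
    # the bound satisfies P(all respond | f) = 0.05
    pAll <- prod((1 - exp(-up@ciLower * allResp$dose))^allResp$tested)
    expect_equal(pAll, 0.05, tolerance = 1e-6)

    noResp <- data.frame(dose = c(100, 1000), tested = 6, response = 0)
    lo <- estimateFrequency(noResp)
    expect_equal(lo@saturation, "none_respond")
    expect_equal(frequency(lo), 0)
    expect_equal(lo@ciUpper, -log(0.05) / sum(noResp$tested * noResp$dose))

    expect_error(estimateFrequency(data.frame(dose = numeric(0),
                                              tested = numeric(0),
                                              response = numeric(0))),
                 "empty")
    expect_error(estimateFrequency(data.frame(dose = -1, tested = 6,
                                              response = 2)), "positive")
    expect_error(estimateFrequency(data.frame(dose = 10, tested = 6,
                                              response = 7)),
                 "lie in")
})

test_that("the MLE matches a brute-force likelihood grid on a toy table", {
    tab <- data.frame(dose = c(100, 1000, 10000), tested = 6,
                      response = c(1, 4, 6))
    est <- estimateFrequency(tab)
    loglik <- function(f) {
        p <- 1 - exp(-f * tab$dose)
        sum(tab$response * log(p) +
            (tab$tested - tab$response) * log(1 - p))
    }
    grid <- exp(seq(log(1e-6), log(1e-1), length.out = 200000))
    fGrid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
    expect_equal(frequency(est), fGrid, tolerance = 1e-4)
})

test_that("frequency estimates are monotone and scale-consistent", {
    base <- data.frame(dose = c(100, 1000), tested = 10,
                       response = c(2, 6))
    f0 <- frequency(estimateFrequency(base))
    more <- base; more$response <- c(3, 6)
    expect_gte(frequency(estimateFrequency(more)), f0)

    scaled <- base; scaled$dose <- base$dose * 7
    expect_equal(frequency(estimateFrequency(scaled)), f0 / 7,
                 tolerance = 1e-9)
})

test_that("group comparison is null on identical tables and errors on
           saturated groups", {
    tab <- data.frame(dose = c(100, 1000), tested = 10, response = c(2, 6))
    cmp <- compareFrequencies(list(a = tab, b = tab))
    expect_equal(cmp$statistic, 0, tolerance = 1e-10)
    expect_equal(cmp$p_value, 1, tolerance = 1e-8)
    expect_equal(cmp$df, 1)
    expect_named(cmp$estimates, c("a", "b"))

    sat <- data.frame(dose = c(100, 1000), tested = 10, response = 0)
    expect_error(compareFrequencies(list(a = tab, b = sat)), "saturated")
    expect_error(compareFrequencies(list(a = tab)), "at least two")

    # single data.frame with a group column splits correctly
    tab2 <- rbind(cbind(tab, group = "a"), cbind(tab, group = "b"))
    cmp2 <- compareFrequencies(tab2)
    expect_equal(cmp2$statistic, cmp$statistic, tolerance = 1e-12)
})

test_that("limiting-dilution tables read from TSV are validated", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("dose\ttested\tresponse\tgroup",
                 "100\t6\t1\tms", "1000\t6\t4\tms"), path)
    tab <- readLDATable(path)
    expect_equal(nrow(tab), 2)
    expect_equal(tab$response, c(1, 4))
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("dose\ttested\tresponse", "100\t6\t9"), bad)
    expect_error(readLDATable(bad), "lie in")
})
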