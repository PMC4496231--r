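trueHill <- function() c(bottom = 0, top = 1000, ec50 = 1, hill = 2)

test_that("noiseless Hill data are recovered to 1e-6 relative", {
    d <- c(0, exp(seq(log(0.05), log(20), length.out = 7)))
    y <- hillResponse(trueHill(), d)
    fit <- fitDoseResponse(d, y)
    p <- hillParams(fit)
    expect_equal(unname(p["top"]), 1000, tolerance = 1e-6)
    expect_lt(abs(p[["bottom"]]) / 1000, 1e-6)  # relative to the scale
    expect_equal(unname(p["ec50"]), 1, tolerance = 1e-6)
    expect_equal(unname(p["hill"]), 2, tolerance = 1e-6)
})

test_that("the response at EC50 is the midpoint between top and bottom", {
    f <- HillFit(bottom = 120, top = 980, ec50 = 3.7, hill = 1.4)
    expect_equal(hillResponse(f, 3.7), (980 + 120) / 2, tolerance = 1e-12)
    expect_equal(inverseDose(f, (980 + 120) / 2), 3.7, tolerance = 1e-12)
})

test_that("EC50 is recovered within 20% under replicate noise", {
    d <- rep(c(0, exp(seq(log(0.1), log(16), length.out = 7))), each = 3)
    errs <- vapply(1:20, function(s) {
        set.seed(s)
        cv <- 0.1
        sdl <- sqrt(log(1 + cv^2))
        y <- hillResponse(trueHill(), d) * rlnorm(length(d), -sdl^2 / 2, sdl)
        abs(hillParams(fitDoseResponse(d, y))[["ec50"]] - 1)
    }, numeric(1))
    expect_lt(median(errs), 0.2)
    expect_lt(max(errs), 0.35)
})

test_that("unidentifiable or malformed dose series are rejected", {
    expect_error(fitDoseResponse(c(0, 1, 2), c(10, 9, 8)), "4 distinct")
    expect_error(fitDoseResponse(c(1, 2, 4, 8), c(10, 9, 8, 7)), "dose 0")
    set.seed(2)
    y <- 1000 + rnorm(8, 0, 30)
    expect_error(fitDoseResponse(c(0, 0.5, 1, 2, 4, 8, 16, 32), y),
                 "unidentifiable")
})

test_that("inverseDose round-trips random doses and rejects out-of-range effects", {
    f <- HillFit(bottom = 50, top = 900, ec50 = 2, hill = 1.7)
    set.seed(4)
    d <- exp(runif(50, log(0.01), log(100)))
    back <- inverseDose(f, hillResponse(f, d))
    expect_lt(max(abs(back - d) / d), 1e-9)
    expect_warning(out <- inverseDose(f, 900), "undefined")
    expect_true(is.na(out))
    expect_warning(out2 <- inverseDose(f, 20), "undefined")
    expect_true(is.na(out2))
})

test_that("a monotherapy well treated as a combination has CI = 1", {
    f <- trueHill()
    g <- c(0, 0.25, 0.5, 1, 2, 4)
    plate <- generateCombinationPlate(f, f, g, g, psi = 1, replicates = 1,
                                      noiseCv = 0, seed = 1)
    fit <- fitDoseResponse(g, hillResponse(f, g))
    ci <- ciValues(combinationIndex(plate, fit, fit))
    # first column: dose_b = 0, pure drug A wells
    expect_equal(unname(ci[-1, 1]), rep(1, 5), tolerance = 1e-6)
    expect_equal(unname(ci[1, -1]), rep(1, 5), tolerance = 1e-6)
})

test_that("an additive plate yields CI = 1 and a potency-shifted plate CI = 1/psi", {
    f <- trueHill()
    g <- c(0, 0.25, 0.5, 1, 2, 4)
    fit <- fitDoseResponse(g, hillResponse(f, g))
    plate1 <- generateCombinationPlate(f, f, g, g, psi = 1, replicates = 1,
                                       noiseCv = 0, seed = 1)
    ci1 <- ciValues(combinationIndex(plate1, fit, fit))
    expect_true(all(ci1[-1, -1] >= 0.99 & ci1[-1, -1] <= 1.01, na.rm = TRUE))
    plate2 <- generateCombinationPlate(f, f, g, g, psi = 2, replicates = 1,
                                       noiseCv = 0, seed = 1)
    res2 <- combinationIndex(plate2, fit, fit)
    inner <- ciValues(res2)[-1, -1]
    expect_equal(median(inner, na.rm = TRUE), 0.5, tolerance = 0.02)
    calls <- ciCalls(res2)[-1, -1]
    expect_true(all(calls[!is.na(ciValues(res2)[-1, -1])] == "synergistic"))
})

test_that("interaction calls follow the 0.8/1.2 thresholds", {
    f <- trueHill()
    g <- c(0, 0.25, 0.5, 1, 2, 4)
    fit <- fitDoseResponse(g, hillResponse(f, g))
    for (psi in c(0.5, 1, 2)) {
        plate <- generateCombinationPlate(f, f, g, g, psi = psi,
                                          replicates = 1, noiseCv = 0,
                                          seed = 1)
        res <- combinationIndex(plate, fit, fit)
        vals <- ciValues(res); calls <- ciCalls(res)
        def <- !is.na(vals)
        expect_true(all(calls[def & vals < 0.8] == "synergistic"))
        expect_true(all(calls[def & vals > 1.2] == "antagonistic"))
        expect_true(all(calls[def & vals >= 0.8 & vals <= 1.2] == "additive"))
        expect_true(all(calls[!def] == "undefined"))
    }
})

test_that("rescaling one drug's dose axis leaves every CI unchanged", {
    f <- trueHill()
    g <- c(0, 0.25, 0.5, 1, 2, 4)
    plate <- generateCombinationPlate(f, f, g, g, psi = 2, replicates = 3,
                                      noiseCv = 0.1, seed = 17)
    w <- plateWells(plate)
    monoA <- w[w$dose_b == 0, ]; monoB <- w[w$dose_a == 0, ]
    fitA <- fitDoseResponse(monoA$dose_a, monoA$viable_count)
    fitB <- fitDoseResponse(monoB$dose_b, monoB$viable_count)
    ci <- ciValues(combinationIndex(plate, fitA, fitB))
    # convert drug A's axis uM -> mM (x 1000) everywhere and redo
    k <- 1000
    w2 <- w; w2$dose_a <- w2$dose_a * k
    plate2 <- new("CombinationDataset", wells = w2, doseGridA = g * k,
                  doseGridB = g, drugNames = plate@drugNames,
                  truth = plate@truth)
    monoA2 <- w2[w2$dose_b == 0, ]
    fitA2 <- fitDoseResponse(monoA2$dose_a, monoA2$viable_count)
    ci2 <- ciValues(combinationIndex(plate2, fitA2, fitB))
    expect_lt(max(abs(ci2 - ci) / ci, na.rm = TRUE), 1e-9)
})

test_that("the pooled t-test matches the closed form to 1e-10", {
    a <- c(10, 12, 11); b <- c(20, 22, 21)
    res <- compareConditions(a, b)
    # textbook pooled-variance computation
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
    tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    pHand <- 2 * pt(-abs(tHand), length(a) + length(b) - 2)
    expect_equal(res$statistic, tHand, tolerance = 1e-10)
    expect_equal(res$p.value, pHand, tolerance = 1e-10)
    expect_identical(res$code, "***")
})

test_that("identical groups give t = 0, p = 1, ns", {
    res <- compareConditions(c(10, 12, 11), c(10, 12, 11))
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
    expect_identical(res$code, "ns")
    expect_error(compareConditions(5, c(1, 2)), "2 replicates")
})

test_that("significance codes follow the star legend", {
    # construct p close to 0.04 by direct search on a scaled pair
    set.seed(7)
    a <- c(10.0, 11.1, 10.6, 10.9)
    b <- c(11.2, 11.9, 11.4, 12.3)
    res <- compareConditions(a, b)
    expect_true(res$p.value < 0.05 && res$p.value >= 0.01)
    expect_identical(res$code, "*")
    welch <- compareConditions(a, b, welch = TRUE)
    expect_false(isTRUE(all.equal(welch$df, res$df)))
})

test_that("the CI heatmap is rendered to a non-empty file", {
    f <- trueHill()
    g <- c(0, 0.5, 1, 2, 4)
    plate <- generateCombinationPlate(f, f, g, g, psi = 2, replicates = 1,
                                      noiseCv = 0, seed = 1)
    fit <- fitDoseResponse(g, hillResponse(f, g))
    ci <- combinationIndex(plate, fit, fit)
    out <- tempfile(fileext = ".png")
    renderCIHeatmap(ci, out)
    expect_true(file.exists(out))
    expect_gt(file.size(out), 1000)
    out2 <- tempfile(fileext = ".png")
    renderCIHeatmap(ci, out2, palette = "cvd")
    expect_gt(file.size(out2), 1000)
})
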