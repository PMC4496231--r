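# independent oracle for the decision rule: exhaustive truth table over the
# 8 threshold octants (blue bright?, green high?, red positive?)
octantOracle <- function(bright, high, pos) {
    if (bright) return("DEAD")
    if (high && !pos) return("VIABLE")
    if (high && pos) return("DYING_YP_HIGH_DIOC")
    if (!high && pos) return("DYING_YP_LOW_DIOC")
    "DYING_LOW_DIOC_ONLY"
}

test_that("classification matches the exhaustive octant truth table", {
    gates <- GateSet(blueThreshold = 100, greenHighThreshold = 50,
                     redPositiveThreshold = 70, mode = "MICROSCOPY")
    grid <- expand.grid(bright = c(FALSE, TRUE), high = c(FALSE, TRUE),
                        pos = c(FALSE, TRUE))
    cells <- CellTable(S4Vectors::DataFrame(
        cell_id = seq_len(nrow(grid)),
        centroid_row = 0, centroid_col = 0, nucleus_area_px = 10L,
        mean_nuclear_blue = ifelse(grid$bright, 200, 20),
        mean_nuclear_red_orange = ifelse(grid$pos, 140, 10),
        mean_cytoplasm_green = ifelse(grid$high, 90, 5),
        border_flag = FALSE))
    got <- as.character(classifyPhenotypes(cells, gates))
    want <- mapply(octantOracle, grid$bright, grid$high, grid$pos)
    expect_identical(got, unname(want))
    # the 8 octants collapse onto exactly the 5 phenotype classes
    expect_setequal(unique(want), phenotypeLabels())
})

test_that("values exactly at a threshold are bright/positive (>= convention)", {
    gates <- GateSet(100, 50, 70, mode = "MICROSCOPY")
    mk <- function(blue, green, red) CellTable(S4Vectors::DataFrame(
        cell_id = 1L, centroid_row = 0, centroid_col = 0,
        nucleus_area_px = 10L, mean_nuclear_blue = blue,
        mean_nuclear_red_orange = red, mean_cytoplasm_green = green,
        border_flag = FALSE))
    expect_identical(as.character(classifyPhenotypes(mk(20, 90, 70), gates)),
                     "DYING_YP_HIGH_DIOC")    # red exactly at threshold
    expect_identical(as.character(classifyPhenotypes(mk(100, 90, 10), gates)),
                     "DEAD")                  # blue at threshold, precedence
    expect_identical(as.character(classifyPhenotypes(mk(20, 50, 10), gates)),
                     "VIABLE")                # green at threshold counts high
})

test_that("an all-zero red control still yields a positive threshold", {
    set.seed(1)
    exprs <- cbind(FSC = rnorm(200, 5e4, 5e3), SSC = rnorm(200, 3e4, 3e3),
                   ch_blue = rlnorm(200, log(50), 0.3),
                   ch_green = rlnorm(200, log(3000), 0.25),
                   ch_red_orange = 0)
    gates <- deriveGates(EventTable(exprs))
    expect_gt(gates@redPositiveThreshold, 0)
    labs <- classifyPhenotypes(EventTable(exprs), gates)
    expect_identical(sum(labs %in% c("DYING_YP_HIGH_DIOC",
                                     "DYING_YP_LOW_DIOC")), 0L)
})

test_that("control-derived gates classify the control itself as viable", {
    sim <- generateEvents(c(VIABLE = 1), 10000, seed = 5)
    gates <- deriveGates(sim$events, controlId = "ctl5")
    labs <- classifyPhenotypes(sim$events, gates)
    expect_gte(mean(labs == "VIABLE"), 0.98)
    expect_error(deriveGates(sim$events[1:20, ]), "at least 50")
})

test_that("gmm2 places the green threshold between the two component means", {
    set.seed(12)
    x <- c(rlnorm(500, 1, 0.4), rlnorm(500, 10, 0.4))
    exprs <- cbind(FSC = rnorm(1000, 5e4, 5e3), SSC = rnorm(1000, 3e4, 3e3),
                   ch_blue = rlnorm(1000, log(50), 0.3), ch_green = x,
                   ch_red_orange = rlnorm(1000, log(150), 0.3))
    gates <- deriveGates(EventTable(exprs), method = "gmm2")
    thrRaw <- sinh(gates@greenHighThreshold) * gates@scale$cofactor
    expect_gt(thrRaw, exp(1))
    expect_lt(thrRaw, exp(10))
    exprs[, "ch_green"] <- 1
    expect_error(deriveGates(EventTable(exprs), method = "gmm2"),
                 "constant channel")
})

test_that("partition conservation holds for arbitrary classified samples", {
    gates <- GateSet(100, 50, 70, mode = "CYTOMETRY",
                     scale = list(type = "linear", cofactor = NA))
    set.seed(33)
    for (rep in 1:20) {
        n <- sample(0:500, 1)
        exprs <- cbind(FSC = runif(n, 0, 1e5), SSC = runif(n, 0, 1e5),
                       ch_blue = runif(n, 0, 200),
                       ch_green = runif(n, 0, 100),
                       ch_red_orange = runif(n, 0, 140))
        labs <- classifyPhenotypes(EventTable(exprs), gates)
        expect_false(any(is.na(labs)))
        counts <- countPhenotypes(labs)
        expect_identical(sum(classCounts(counts)), as.numeric(n))
        if (n > 0) expect_equal(sum(classPercentages(counts)), 100)
    }
})

test_that("raising the red threshold never increases the YO-PRO-positive classes", {
    sim <- generateEvents(evenMix(), 2000, seed = 14)
    gates <- deriveGates(generateEvents(c(VIABLE = 1), 1000, seed = 1)$events)
    ypPlus <- function(thr) {
        g <- gates
        g@redPositiveThreshold <- thr
        sum(classifyPhenotypes(sim$events, g) %in%
            c("DYING_YP_HIGH_DIOC", "DYING_YP_LOW_DIOC"))
    }
    thrs <- seq(gates@redPositiveThreshold * 0.2,
                gates@redPositiveThreshold * 3, length.out = 12)
    counts <- vapply(thrs, ypPlus, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("counting handles degenerate input, even splits, border exclusion and density", {
    empty <- countPhenotypes(character())
    expect_identical(empty@total, 0)
    expect_true(all(classPercentages(empty) == 0))
    even <- countPhenotypes(rep(phenotypeLabels(), each = 10))
    expect_true(all(classPercentages(even) == 20))
    expect_equal(sum(classPercentages(even)), 100)
    expect_identical(viableAbsolute(even), 10)
    vol <- countPhenotypes(rep("VIABLE", 500), volumeUL = 100)
    expect_equal(vol@density, 5)
    expect_identical(vol@densityUnit, "events_per_uL")
    borders <- countPhenotypes(c("VIABLE", "VIABLE", "DEAD"),
                               borderFlags = c(FALSE, TRUE, FALSE))
    expect_identical(borders@total, 2)
    expect_error(countPhenotypes(c("VIABLE", "ZOMBIE")), "unknown phenotype")
})

test_that("per-class counts on a mixed synthetic field match ground truth", {
    gates <- controlGatesMicroscopy()
    sim <- generateField(evenMix(), 50, seed = 7)
    res <- analyzeField(sim$field)
    labs <- classifyPhenotypes(res$cells, gates)
    counts <- countPhenotypes(labs, borderFlags = res$cells$border_flag)
    truthCounts <- table(factor(truthCells(sim$truth)$phenotype,
                                phenotypeLabels()))
    # within a small classification/segmentation error budget
    expect_lte(max(abs(classCounts(counts) - as.numeric(truthCounts))), 3)
})

test_that("gate sets survive a JSON round trip", {
    sim <- generateEvents(c(VIABLE = 1), 1000, seed = 5)
    gates <- deriveGates(sim$events, controlId = "well_A1")
    f <- tempfile(fileext = ".json")
    writeGateSet(gates, f)
    back <- readGateSet(f)
    expect_equal(back@blueThreshold, gates@blueThreshold)
    expect_equal(back@greenHighThreshold, gates@greenHighThreshold)
    expect_equal(back@redPositiveThreshold, gates@redPositiveThreshold)
    expect_identical(back@mode, gates@mode)
    expect_identical(back@scale$type, gates@scale$type)
    expect_identical(back@controlId, "well_A1")
})
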