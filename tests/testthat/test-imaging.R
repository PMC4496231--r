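test_that("an all-zero raster yields an empty mask, non-finite pixels error", {
    m <- matrix(0, 128, 128)
    expect_identical(nObjects(segmentNuclei(m)), 0L)
    m[5, 5] <- NA
    expect_error(segmentNuclei(m), "non-finite")
    expect_error(segmentNuclei(matrix(1, 10, 10), minArea = 10,
                               maxArea = 5), "minArea")
})

test_that("planted non-overlapping nuclei are all recovered near their centroids", {
    sim <- generateField(c(VIABLE = 1), 20, seed = 1)
    nuc <- segmentNuclei(channelRaster(sim$field, "blue"))
    expect_identical(nObjects(nuc), 20L)
    cells <- measureCells(sim$field, nuc,
                          segmentCytoplasm(channelRaster(sim$field, "green"),
                                           nuc))
    m <- matchCentroids(truthCells(sim$truth), as.data.frame(cells))
    expect_true(all(m$truthToDet <= 2))
})

test_that("touching disks are split by the watershed when requested", {
    img <- matrix(0, 96, 96)
    paint <- function(r0, c0, rad) {
        for (i in seq_len(96)) for (j in seq_len(96))
            if ((i - r0)^2 + (j - c0)^2 <= rad^2) img[i, j] <<- 3000
    }
    paint(48, 40, 10); paint(48, 56, 10)   # centers 16 px apart
    expect_identical(nObjects(segmentNuclei(img, smoothingSigma = 1,
                                            backgroundRadius = 0,
                                            split = TRUE)), 2L)
    expect_identical(nObjects(segmentNuclei(img, smoothingSigma = 1,
                                            backgroundRadius = 0,
                                            split = FALSE)), 1L)
})

test_that("cytoplasm of a nucleus centered in a bright green disk is the disk minus the nucleus", {
    green <- matrix(10, 128, 128)
    nucMask <- matrix(0L, 128, 128)
    inDisk <- function(i, j, r) (i - 64)^2 + (j - 64)^2 <= r^2
    for (i in 1:128) for (j in 1:128) {
        if (inDisk(i, j, 20)) green[i, j] <- 5000
        if (inDisk(i, j, 8)) nucMask[i, j] <- 1L
    }
    cyt <- labelData(segmentCytoplasm(green, LabelMask(nucMask),
                                      maxRingRadius = 25))
    want <- matrix(FALSE, 128, 128)
    for (i in 1:128) for (j in 1:128)
        want[i, j] <- inDisk(i, j, 20) && !inDisk(i, j, 8)
    agree <- sum((cyt == 1L) & want) / sum(want | (cyt == 1L))
    expect_gte(agree, 0.95)
    expect_true(all(cyt[nucMask == 1L] == 0L))
})

test_that("adjacent cells with overlapping halos get disjoint cytoplasm regions", {
    sim <- generateField(c(VIABLE = 1), 2, shape = c(96, 96),
                         minDistFactor = 2.3, seed = 5)
    nucT <- LabelMask(truthParams(sim$truth)$nucleusMask)
    cyt <- labelData(segmentCytoplasm(channelRaster(sim$field, "green"),
                                      nucT))
    nuc <- labelData(nucT)
    expect_true(all(cyt[nuc > 0L] == 0L))     # disjoint from nuclei
    # each region is adjacent to (within 2 px of) only its own nucleus
    for (k in 1:2) {
        idx <- which(cyt == k, arr.ind = TRUE)
        expect_gt(nrow(idx), 0)
    }
    expect_identical(nObjects(segmentCytoplasm(matrix(1, 32, 32),
                                               LabelMask(matrix(0L, 32, 32)))),
                     0L)
})

test_that("per-cell means equal a brute-force pixel loop exactly", {
    set.seed(9)
    sim <- generateField(evenMix(), 12, shape = c(160, 160), seed = 9)
    nuc <- segmentNuclei(channelRaster(sim$field, "blue"))
    cyt <- segmentCytoplasm(channelRaster(sim$field, "green"), nuc)
    cells <- measureCells(sim$field, nuc, cyt)
    nm <- labelData(nuc); cm <- labelData(cyt)
    blue <- channelRaster(sim$field, "blue")
    red <- channelRaster(sim$field, "redOrange")
    green <- channelRaster(sim$field, "green")
    for (k in seq_len(nObjects(nuc))) {
        sB <- 0; sR <- 0; nB <- 0L
        sG <- 0; nG <- 0L
        for (i in seq_len(nrow(nm))) for (j in seq_len(ncol(nm))) {
            if (nm[i, j] == k) { sB <- sB + blue[i, j]
                                 sR <- sR + red[i, j]; nB <- nB + 1L }
            if (cm[i, j] == k) { sG <- sG + green[i, j]; nG <- nG + 1L }
        }
        expect_identical(cells$nucleus_area_px[k], nB)
        expect_equal(cells$mean_nuclear_blue[k], sB / nB, tolerance = 1e-12)
        expect_equal(cells$mean_nuclear_red_orange[k], sR / nB,
                     tolerance = 1e-12)
        expect_equal(cells$mean_cytoplasm_green[k], sG / max(nG, 1),
                     tolerance = 1e-12)
    }
})

test_that("a constant-intensity nucleus reports that constant as its mean", {
    blue <- matrix(7, 64, 64); green <- matrix(3, 64, 64)
    red <- matrix(11, 64, 64)
    nm <- matrix(0L, 64, 64); nm[30:36, 30:36] <- 1L
    cells <- measureCells(FieldImage(blue + 93 * (nm == 1L), green, red),
                          LabelMask(nm),
                          segmentCytoplasm(green, LabelMask(nm),
                                           thresholdMethod = 1e9))
    expect_equal(cells$mean_nuclear_blue[1], 100)
    expect_equal(cells$mean_nuclear_red_orange[1], 11)
    expect_equal(cells$mean_cytoplasm_green[1], 3)   # fallback annulus
})

test_that("feature values follow the cell under label permutation", {
    sim <- generateField(evenMix(), 8, shape = c(128, 128), seed = 21)
    nuc <- segmentNuclei(channelRaster(sim$field, "blue"))
    cyt <- segmentCytoplasm(channelRaster(sim$field, "green"), nuc)
    cells <- measureCells(sim$field, nuc, cyt)
    n <- nObjects(nuc)
    perm <- sample(n)
    relab <- function(m) { out <- m; out[m > 0L] <- perm[m[m > 0L]]; out }
    cells2 <- measureCells(sim$field, new("LabelMask", mask = relab(labelData(nuc))),
                           new("LabelMask", mask = relab(labelData(cyt))))
    for (k in seq_len(n)) {
        expect_equal(cells2$mean_nuclear_blue[perm[k]],
                     cells$mean_nuclear_blue[k], tolerance = 1e-12)
        expect_equal(cells2$mean_cytoplasm_green[perm[k]],
                     cells$mean_cytoplasm_green[k], tolerance = 1e-12)
    }
})

test_that("cytoplasm labels without a nucleus are a broken correspondence", {
    nm <- matrix(0L, 32, 32); nm[5:8, 5:8] <- 1L
    cm <- matrix(0L, 32, 32)
    cm[10:12, 5:8] <- 1L
    cm[20:22, 20:22] <- 2L   # no nucleus 2 exists
    f <- FieldImage(matrix(1, 32, 32), matrix(1, 32, 32), matrix(1, 32, 32))
    expect_error(measureCells(f, new("LabelMask", mask = nm),
                              new("LabelMask", mask = cm)),
                 "matching nucleus")
})

test_that("border-touching nuclei are flagged", {
    nm <- matrix(0L, 40, 40)
    nm[1:4, 10:14] <- 1L          # touches row 1
    nm[20:24, 20:24] <- 2L        # interior
    f <- FieldImage(matrix(5, 40, 40), matrix(5, 40, 40), matrix(5, 40, 40))
    cyt <- segmentCytoplasm(matrix(5, 40, 40), new("LabelMask", mask = nm),
                            thresholdMethod = 1e9)
    cells <- measureCells(f, new("LabelMask", mask = nm), cyt)
    expect_identical(cells$border_flag, c(TRUE, FALSE))
})

test_that("field images round-trip through TIFF + sidecar", {
    sim <- generateField(c(VIABLE = 1), 5, shape = c(64, 64), seed = 2)
    d <- tempfile(); dir.create(d)
    writeFieldImage(sim$field, d)
    back <- readFieldImage(d, "field1")
    expect_equal(pixelSize(back), pixelSize(sim$field))
    # 16-bit quantization: within one gray level
    expect_lt(max(abs(channelRaster(back, "blue") -
                      channelRaster(sim$field, "blue"))), 1.01)
})
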