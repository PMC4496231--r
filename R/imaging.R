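#' Segment nuclei on the blue (chromatin) channel
#'
#' Pipeline: Gaussian smoothing, background subtraction (the background is
#' estimated as a large-sigma Gaussian blur of the smoothed image, i.e. a
#' low-frequency illumination/background field, and subtracted with clipping
#' at zero), global Otsu threshold on the log intensities (robust to the
#' strongly bimodal dim/bright foreground), hole filling, optional
#' distance-transform watershed to split touching nuclei, then an area
#' filter. Labels are consecutive from 1.
#'
#' @param blue Non-negative 2D intensity raster (matrix).
#' @param smoothingSigma Gaussian smoothing sigma in pixels.
#' @param backgroundRadius Background estimation scale in pixels (sigma of
#'   the background blur); 0 disables background subtraction.
#' @param minArea,maxArea Retained object area range in pixels.
#' @param split Split touching nuclei by distance-transform watershed.
#' @return A \linkS4class{LabelMask}. An all-zero image yields an empty
#'   mask; non-finite pixels are an error.
#' @examples
#' sim <- generateField(c(VIABLE = 1), nCells = 8, shape = c(128, 128),
#'                      seed = 1)
#' nuc <- segmentNuclei(channelRaster(sim$field, "blue"))
#' nObjects(nuc)
#' @export
segmentNuclei <- function(blue, smoothingSigma = 2, backgroundRadius = 50,
                          minArea = 30, maxArea = 2500, split = TRUE) {
    blue <- as.matrix(blue)
    if (!length(blue)) stop("empty raster")
    if (!all(is.finite(blue))) stop("blue channel contains non-finite pixels")
    if (minArea <= 0 || minArea >= maxArea)
        stop("need 0 < minArea < maxArea")
    rng <- max(blue)
    if (rng <= 0) return(LabelMask(matrix(0L, nrow(blue), ncol(blue))))

    img <- EBImage::Image(blue / rng)
    sm <- if (smoothingSigma > 0)
        EBImage::gblur(img, sigma = smoothingSigma) else img
    # the background kernel must fit inside the image
    bgSigma <- min(backgroundRadius, (min(dim(blue)) - 3) / 7)
    if (bgSigma >= 1) {
        bgr <- EBImage::gblur(sm, sigma = bgSigma)
        sm <- EBImage::Image(pmax(as.matrix(sm) - as.matrix(bgr), 0))
    }
    # Otsu on log intensities: the raw histogram is trimodal (background,
    # chromatin-dim nuclei, chromatin-bright nuclei) and raw-scale Otsu
    # splits dim from bright; the log scale compresses the foreground modes
    # so the threshold falls between background and all nuclei
    v <- log1p(as.matrix(sm) * rng)
    if (max(v) <= min(v))
        return(LabelMask(matrix(0L, nrow(blue), ncol(blue))))
    thr <- EBImage::otsu(EBImage::Image(v), range = range(v))
    bw <- v > thr
    bw <- EBImage::fillHull(EBImage::Image(bw * 1))
    if (split) {
        dm <- EBImage::distmap(bw)
        lab <- EBImage::watershed(dm, tolerance = 1)
    } else {
        lab <- EBImage::bwlabel(bw)
    }
    lab <- as.matrix(EBImage::imageData(lab))
    storage.mode(lab) <- "integer"
    if (max(lab) > 0) {
        areas <- tabulate(lab[lab > 0L], nbins = max(lab))
        drop <- which(areas < minArea | areas > maxArea)
        if (length(drop)) lab[lab %in% drop] <- 0L
    }
    LabelMask(lab)
}

#' Assign a cytoplasmic region to every nucleus on the green channel
#'
#' Each nucleus seeds one cytoplasmic region grown over above-threshold
#' green pixels (global Otsu by default) within `maxRingRadius` of the
#' nucleus; competing nuclei split contested pixels by geodesic propagation
#' ([EBImage::propagate()]). Cells whose green signal is absent (DiOC6-low
#' phenotypes) fall back to a fixed-width annulus around the nucleus so
#' every cell still receives a cytoplasmic measurement. Cytoplasm pixels
#' never overlap nucleus pixels, and regions of different cells are
#' disjoint.
#'
#' @param green Non-negative 2D intensity raster.
#' @param nuclei \linkS4class{LabelMask} of nuclei (same shape).
#' @param maxRingRadius Maximum growth distance from the nucleus (px).
#' @param thresholdMethod "otsu" or a numeric threshold on the green scale.
#' @param fallbackWidth Annulus width (px) used where green is absent.
#' @return A \linkS4class{LabelMask} with cytoplasm label k matched to
#'   nucleus label k. Empty nuclei mask yields an empty cytoplasm mask.
#' @export
segmentCytoplasm <- function(green, nuclei, maxRingRadius = 20,
                             thresholdMethod = "otsu", fallbackWidth = 5) {
    green <- as.matrix(green)
    nuc <- labelData(nuclei)
    if (!identical(dim(green), dim(nuc)))
        stop("green raster and nuclei mask must share shape")
    n <- max(nuc)
    if (n == 0L) return(LabelMask(matrix(0L, nrow(green), ncol(green))))
    thr <- if (is.numeric(thresholdMethod)) thresholdMethod else {
        rng <- range(green)
        if (diff(rng) <= 0) Inf
        else EBImage::otsu(EBImage::Image(green), range = rng)
    }
    distToNuc <- as.matrix(EBImage::distmap(EBImage::Image((nuc == 0L) * 1)))
    # nearest-nucleus ownership for tie-breaking and the fallback annulus
    voronoi <- as.matrix(EBImage::imageData(EBImage::propagate(
        EBImage::Image(green / max(max(green), 1)), seeds = nuc)))
    storage.mode(voronoi) <- "integer"
    allowed <- (green >= thr & distToNuc <= maxRingRadius) | nuc > 0L
    grown <- as.matrix(EBImage::imageData(EBImage::propagate(
        EBImage::Image(green / max(max(green), 1)), seeds = nuc,
        mask = allowed)))
    storage.mode(grown) <- "integer"
    cyto <- grown
    cyto[nuc > 0L] <- 0L
    # a cell whose own perinuclear ring is mostly below threshold has no
    # DiOC6 signal of its own: any pixels it grew belong to a neighbour's
    # halo, so it falls back to its fixed-width annulus instead
    ring <- voronoi
    ring[!(nuc == 0L & distToNuc > 0 & distToNuc <= fallbackWidth)] <- 0L
    ringArea <- tabulate(ring[ring > 0L], nbins = n)
    ringAbove <- tabulate(ring[ring > 0L & green >= thr], nbins = n)
    coverage <- ifelse(ringArea > 0, ringAbove / pmax(ringArea, 1L), 0)
    lowSignal <- which(coverage < 0.5)
    if (length(lowSignal)) {
        cyto[cyto %in% lowSignal] <- 0L            # drop stolen pixels
        fall <- ring > 0L & matrix(ring %in% lowSignal, nrow(ring))
        cyto[fall] <- ring[fall]
        cyto[nuc > 0L] <- 0L
    }
    new("LabelMask", mask = .relabelPair(cyto, n))
}

# keep cytoplasm labels aligned with nucleus labels 1..n (no relabeling)
.relabelPair <- function(cyto, n) {
    cyto[cyto > n] <- 0L
    cyto
}

#' Measure the per-cell features used by the viability classification
#'
#' For every nucleus label: mean nuclear blue (chromatin) and nuclear
#' red/orange (YO-PRO-3) over the nucleus pixels, and mean cytoplasmic green
#' (DiOC6(3)) over the matched cytoplasm pixels — all on the raw,
#' unsmoothed channels — plus centroid (0-based row/col), nuclear area and
#' a flag for nuclei touching the image border (partial cells bias means
#' and are excluded from counts downstream by default).
#'
#' @param field A \linkS4class{FieldImage}.
#' @param nuclei,cytoplasm \linkS4class{LabelMask}s with matched labels
#'   (cytoplasm label k belongs to nucleus k).
#' @return A \linkS4class{CellTable}, one row per nucleus label.
#' @export
measureCells <- function(field, nuclei, cytoplasm) {
    stopifnot(is(field, "FieldImage"))
    nuc <- labelData(nuclei)
    cyt <- labelData(cytoplasm)
    if (!identical(dim(nuc), dim(field@blue)) ||
        !identical(dim(cyt), dim(field@blue)))
        stop("mask shapes must match the field channels")
    n <- max(nuc)
    extra <- setdiff(unique(cyt[cyt > 0L]), seq_len(n))
    if (length(extra))
        stop("cytoplasm labels without a matching nucleus: ",
             paste(extra, collapse = ", "))
    if (n == 0L) return(CellTable())
    idxN <- which(nuc > 0L)
    labN <- nuc[idxN]
    area <- tabulate(labN, nbins = n)
    splitN <- split(idxN, factor(labN, levels = seq_len(n)))
    splitC <- split(which(cyt > 0L), factor(cyt[cyt > 0L],
                                            levels = seq_len(n)))
    meanAt <- function(raster, idx) unname(vapply(idx, function(i)
        if (length(i)) mean(raster[i]) else 0, numeric(1)))
    rows <- ((idxN - 1L) %% nrow(nuc)) + 1L
    cols <- ((idxN - 1L) %/% nrow(nuc)) + 1L
    cenR <- .sumByLabel(rows, labN, n) / area
    cenC <- .sumByLabel(cols, labN, n) / area
    meanGreen <- meanAt(field@green, splitC)
    border <- rep(FALSE, n)
    edgeLabs <- unique(c(nuc[1, ], nuc[nrow(nuc), ], nuc[, 1], nuc[, ncol(nuc)]))
    edgeLabs <- edgeLabs[edgeLabs > 0L]
    border[edgeLabs] <- TRUE
    CellTable(DataFrame(
        cell_id = seq_len(n),
        centroid_row = cenR - 1,
        centroid_col = cenC - 1,
        nucleus_area_px = area,
        mean_nuclear_blue = meanAt(field@blue, splitN),
        mean_nuclear_red_orange = meanAt(field@redOrange, splitN),
        mean_cytoplasm_green = meanGreen,
        border_flag = border))
}

.sumByLabel <- function(values, labels, n) {
    as.numeric(rowsum(as.numeric(values),
                      factor(labels, levels = seq_len(n)), reorder = TRUE))
}

#' Segment and measure a field in one call
#'
#' Convenience wrapper: [segmentNuclei()] on the blue channel,
#' [segmentCytoplasm()] on the green channel, then [measureCells()].
#'
#' @param field A \linkS4class{FieldImage}.
#' @param ... Passed to [segmentNuclei()] and [segmentCytoplasm()]
#'   (matched by name).
#' @return List with `cells` (CellTable), `nuclei` and `cytoplasm`
#'   (LabelMasks).
#' @export
analyzeField <- function(field, ...) {
    args <- list(...)
    segArgs <- args[names(args) %in%
                    names(formals(segmentNuclei))[-1]]
    cytArgs <- args[names(args) %in%
                    names(formals(segmentCytoplasm))[-(1:2)]]
    nuclei <- do.call(segmentNuclei,
                      c(list(channelRaster(field, "blue")), segArgs))
    cytoplasm <- do.call(segmentCytoplasm,
                         c(list(channelRaster(field, "green"), nuclei),
                           cytArgs))
    list(cells = measureCells(field, nuclei, cytoplasm), nuclei = nuclei,
         cytoplasm = cytoplasm)
}
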