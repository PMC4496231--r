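#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' The five viability phenotypes
#'
#' Canonical labels, in reporting order, for the five-phenotype viability
#' scheme: healthy cells (chromatin-dim / DiOC6(3)-high / YO-PRO-3-negative),
#' dead cells (chromatin-bright or exclusion-dye positive), and the three
#' intermediate dying states defined by YO-PRO-3 positivity and/or loss of
#' the DiOC6(3) signal.
#'
#' @return Character vector of the five phenotype labels.
#' @examples
#' phenotypeLabels()
#' @export
phenotypeLabels <- function() {
    c("VIABLE", "DEAD", "DYING_YP_HIGH_DIOC", "DYING_YP_LOW_DIOC",
      "DYING_LOW_DIOC_ONLY")
}

.canonicalChannels <- c("FSC", "SSC", "ch_blue", "ch_green", "ch_red_orange")

.cellTableColumns <- c("cell_id", "centroid_row", "centroid_col",
                       "nucleus_area_px", "mean_nuclear_blue",
                       "mean_nuclear_red_orange", "mean_cytoplasm_green",
                       "border_flag")

#' FieldImage: one three-channel microscope field
#'
#' Container for a single epifluorescence field: three co-registered 2D
#' intensity rasters (blue = chromatin dye, green = DiOC6(3),
#' red/orange = YO-PRO-3) plus the pixel size in micrometers.
#'
#' @slot blue,green,redOrange Numeric matrices of identical dimension with
#'   finite, non-negative intensities.
#' @slot pixelSizeUm Pixel edge length in micrometers (> 0).
#' @slot fieldId Character identifier of the field.
#' @export
setClass("FieldImage",
    representation(blue = "matrix", green = "matrix", redOrange = "matrix",
                   pixelSizeUm = "numeric", fieldId = "character"))

setValidity("FieldImage", function(object) {
    msg <- character()
    dims <- list(dim(object@blue), dim(object@green), dim(object@redOrange))
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
        msg <- c(msg, "all three channel rasters must share the same shape")
    for (ch in c("blue", "green", "redOrange")) {
        v <- slot(object, ch)
        if (!all(is.finite(v)))
            msg <- c(msg, sprintf("channel '%s' contains non-finite pixels", ch))
        else if (any(v < 0))
            msg <- c(msg, sprintf("channel '%s' contains negative intensities", ch))
    }
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
        msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' @describeIn FieldImage Constructor.
#' @param blue,green,redOrange Numeric matrices (equal shape).
#' @param pixelSizeUm Pixel size in micrometers.
#' @param fieldId Field identifier.
#' @export
FieldImage <- function(blue, green, redOrange, pixelSizeUm = 1,
                       fieldId = "field") {
    new("FieldImage", blue = as.matrix(blue), green = as.matrix(green),
        redOrange = as.matrix(redOrange),
        pixelSizeUm = as.numeric(pixelSizeUm), fieldId = as.character(fieldId))
}

#' LabelMask: integer object-label raster
#'
#' A 2D integer raster in which 0 marks background and k >= 1 marks the
#' pixels of object k. Labels are consecutive from 1.
#'
#' @slot mask Integer matrix of labels.
#' @export
setClass("LabelMask", representation(mask = "matrix"))

setValidity("LabelMask", function(object) {
    m <- object@mask
    if (!is.numeric(m)) return("mask must be numeric/integer")
    labs <- sort(unique(as.vector(m)))
    labs <- labs[labs != 0]
    if (length(labs) && !identical(as.integer(labs), seq_len(length(labs))))
        return("labels must be consecutive integers starting at 1")
    if (any(m < 0)) return("labels must be non-negative")
    TRUE
})

#' @describeIn LabelMask Constructor (relabels to consecutive integers).
#' @param mask Integer matrix (0 = background).
#' @export
LabelMask <- function(mask) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "integer"
    labs <- sort(unique(as.vector(mask)))
    labs <- labs[labs != 0L]
    if (length(labs) && !identical(labs, seq_along(labs))) {
        lut <- integer(max(labs))
        lut[labs] <- seq_along(labs)
        pos <- mask != 0L
        mask[pos] <- lut[mask[pos]]
    }
    new("LabelMask", mask = mask)
}

#' CellTable: per-cell features from a segmented field
#'
#' One row per retained nucleus, holding the three intensity features the
#' viability classification uses (mean nuclear blue, mean nuclear
#' red/orange, mean cytoplasmic green) plus centroid (0-based row/col),
#' nuclear area in pixels and a border flag.
#'
#' @export
setClass("CellTable", contains = "DFrame")

setValidity("CellTable", function(object) {
    missing <- setdiff(.cellTableColumns, colnames(object))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    num <- c("mean_nuclear_blue", "mean_nuclear_red_orange",
             "mean_cytoplasm_green")
    for (cn in num)
        if (nrow(object) && any(object[[cn]] < 0, na.rm = TRUE))
            return(sprintf("column '%s' must be non-negative", cn))
    TRUE
})

#' @describeIn CellTable Constructor from a data.frame-like object.
#' @param x data.frame or DataFrame with the required per-cell columns.
#' @export
CellTable <- function(x = NULL) {
    if (is.null(x)) {
        x <- DataFrame(cell_id = integer(), centroid_row = numeric(),
                       centroid_col = numeric(), nucleus_area_px = integer(),
                       mean_nuclear_blue = numeric(),
                       mean_nuclear_red_orange = numeric(),
                       mean_cytoplasm_green = numeric(),
                       border_flag = logical())
    }
    new("CellTable", DataFrame(x))
}

#' EventTable: flow-cytometry events
#'
#' Events-by-channels matrix with the canonical channels FSC, SSC, ch_blue,
#' ch_green and ch_red_orange, the acquisition volume in microliters (NA
#' when the instrument did not meter volume) and a record of any channel
#' transforms applied.
#'
#' @slot exprs Numeric matrix, one row per event, named columns.
#' @slot volumeUL Acquisition volume in microliters, or NA.
#' @slot transforms Named list recording per-channel transforms.
#' @export
setClass("EventTable",
    representation(exprs = "matrix", volumeUL = "numeric",
                   transforms = "list"))

setValidity("EventTable", function(object) {
    msg <- character()
    if (is.null(colnames(object@exprs)) && ncol(object@exprs) > 0)
        msg <- c(msg, "channels must be named")
    if (length(object@volumeUL) != 1L)
        msg <- c(msg, "volumeUL must be a single value (NA allowed)")
    else if (!is.na(object@volumeUL) && object@volumeUL < 0)
        msg <- c(msg, "volumeUL must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn EventTable Constructor.
#' @param exprs Numeric events-by-channels matrix with column names.
#' @param volumeUL Acquisition volume (microliters) or NA.
#' @param transforms Named list of transform descriptors.
#' @export
EventTable <- function(exprs, volumeUL = NA_real_, transforms = list()) {
    exprs <- as.matrix(exprs)
    new("EventTable", exprs = exprs, volumeUL = as.numeric(volumeUL),
        transforms = transforms)
}

#' GroundTruth: known per-cell/event truth for synthetic data
#'
#' @slot cells DataFrame with one row per simulated cell or event
#'   (centroid/mask id or event index, phenotype label).
#' @slot params List of the generating parameters (presets, Hill curves,
#'   interaction factor psi, ...).
#' @slot seed The seed the dataset was generated from.
#' @export
setClass("GroundTruth",
    representation(cells = "DFrame", params = "list", seed = "numeric"))

GroundTruth <- function(cells, params = list(), seed = NA_real_) {
    new("GroundTruth", cells = DataFrame(cells), params = params,
        seed = as.numeric(seed))
}

#' GateSet: thresholds of the five-phenotype decision rule
#'
#' Thresholds separating chromatin dim/bright (microscopy) or exclusion-dye
#' -/+ (cytometry), DiOC6(3) low/high and YO-PRO-3 -/+, together with the
#' scale they live on and the method and control sample that produced them.
#'
#' @slot blueThreshold Chromatin bright (microscopy) or exclusion-dye
#'   positive (cytometry) threshold.
#' @slot greenHighThreshold DiOC6(3) high/low floor.
#' @slot redPositiveThreshold YO-PRO-3 positivity threshold.
#' @slot mode "MICROSCOPY" or "CYTOMETRY".
#' @slot scale List: type ("linear" or "asinh") and cofactor.
#' @slot method Derivation method ("quantile", "otsu" or "gmm2").
#' @slot controlId Identifier of the control sample used.
#' @export
setClass("GateSet",
    representation(blueThreshold = "numeric", greenHighThreshold = "numeric",
                   redPositiveThreshold = "numeric", mode = "character",
                   scale = "list", method = "character",
                   controlId = "character"))

setValidity("GateSet", function(object) {
    msg <- character()
    thr <- c(object@blueThreshold, object@greenHighThreshold,
             object@redPositiveThreshold)
    if (length(thr) != 3L || !all(is.finite(thr)))
        msg <- c(msg, "all three thresholds must be single finite values")
    if (!object@mode %in% c("MICROSCOPY", "CYTOMETRY"))
        msg <- c(msg, "mode must be MICROSCOPY or CYTOMETRY")
    if (length(msg)) msg else TRUE
})

#' @describeIn GateSet Constructor.
#' @param blueThreshold,greenHighThreshold,redPositiveThreshold Thresholds.
#' @param mode "MICROSCOPY" or "CYTOMETRY".
#' @param scale,method,controlId Provenance fields.
#' @export
GateSet <- function(blueThreshold, greenHighThreshold, redPositiveThreshold,
                    mode, scale = list(type = "linear", cofactor = NA_real_),
                    method = "quantile", controlId = "control") {
    new("GateSet", blueThreshold = blueThreshold,
        greenHighThreshold = greenHighThreshold,
        redPositiveThreshold = redPositiveThreshold, mode = mode,
        scale = scale, method = method, controlId = controlId)
}

#' PhenotypeCounts: per-sample phenotype tally
#'
#' Absolute counts and percentages for the five phenotypes, the absolute
#' number of viable cells, and (when area or volume is known) a density in
#' cells per imaged mm^2 or events per microliter.
#'
#' @slot counts Named numeric of length 5 (one per phenotype).
#' @slot percentages Named numeric of length 5 (sum 100 when total > 0).
#' @slot total Total classified records.
#' @slot viableAbsolute Count of the VIABLE class.
#' @slot density Viable cells per mm^2 or per microliter (NA if unknown).
#' @slot densityUnit "cells_per_mm2", "events_per_uL" or "unknown".
#' @export
setClass("PhenotypeCounts",
    representation(counts = "numeric", percentages = "numeric",
                   total = "numeric", viableAbsolute = "numeric",
                   density = "numeric", densityUnit = "character"))

setValidity("PhenotypeCounts", function(object) {
    msg <- character()
    if (!identical(names(object@counts), phenotypeLabels()))
        msg <- c(msg, "counts must be named by the five phenotype labels")
    if (abs(sum(object@counts) - object@total) > 1e-8)
        msg <- c(msg, "class counts must sum to the total")
    if (object@total > 0 && abs(sum(object@percentages) - 100) > 1e-6)
        msg <- c(msg, "percentages must sum to 100")
    if (length(msg)) msg else TRUE
})

#' HillFit: four-parameter log-logistic dose-response fit
#'
#' Decreasing Hill curve E(d) = bottom + (top - bottom) / (1 + (d/ec50)^h)
#' fitted to viable counts: top is the count at dose 0, bottom the count at
#' saturating dose, ec50 the half-maximal dose and h > 0 the slope.
#'
#' @slot bottom,top,ec50,hill Parameter estimates.
#' @slot cov 4x4 covariance matrix of the estimates (NA if unavailable).
#' @slot doseUnit Unit string for doses.
#' @export
setClass("HillFit",
    representation(bottom = "numeric", top = "numeric", ec50 = "numeric",
                   hill = "numeric", cov = "matrix", doseUnit = "character"))

setValidity("HillFit", function(object) {
    msg <- character()
    if (object@ec50 <= 0) msg <- c(msg, "ec50 must be positive")
    if (object@hill <= 0) msg <- c(msg, "hill slope must be positive")
    if (!(object@top > object@bottom) || object@bottom < 0)
        msg <- c(msg, "need top > bottom >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn HillFit Constructor.
#' @param bottom,top,ec50,hill Parameters of the decreasing Hill curve.
#' @param cov Covariance matrix of the estimates.
#' @param doseUnit Dose unit string.
#' @export
HillFit <- function(bottom, top, ec50, hill,
                    cov = matrix(NA_real_, 4, 4), doseUnit = "") {
    dimnames(cov) <- list(c("bottom", "top", "ec50", "hill"),
                          c("bottom", "top", "ec50", "hill"))
    new("HillFit", bottom = bottom, top = top, ec50 = ec50, hill = hill,
        cov = cov, doseUnit = doseUnit)
}

#' CombinationDataset: a two-drug checkerboard of viable counts
#'
#' Long-format well table (dose_a, dose_b, replicate, viable_count) over a
#' dose grid that includes 0 for both drugs, plus the generating truth when
#' the plate is synthetic.
#'
#' @slot wells data.frame with columns well, dose_a, dose_b, replicate,
#'   viable_count.
#' @slot doseGridA,doseGridB Ascending dose grids including 0.
#' @slot drugNames Names of drug A and drug B.
#' @slot truth List with hillA, hillB, psi and seed for synthetic plates.
#' @export
setClass("CombinationDataset",
    representation(wells = "data.frame", doseGridA = "numeric",
                   doseGridB = "numeric", drugNames = "character",
                   truth = "list"))

setValidity("CombinationDataset", function(object) {
    msg <- character()
    need <- c("well", "dose_a", "dose_b", "replicate", "viable_count")
    if (!all(need %in% colnames(object@wells)))
        msg <- c(msg, paste("wells must have columns",
                            paste(need, collapse = ", ")))
    for (g in list(object@doseGridA, object@doseGridB)) {
        if (is.unsorted(g, strictly = TRUE))
            msg <- c(msg, "dose grids must be strictly increasing")
        if (length(g) && g[1] != 0)
            msg <- c(msg, "dose grids must include 0")
    }
    if (length(msg)) msg else TRUE
})

#' CIMatrix: combination indexes over a dose grid
#'
#' Pointwise Loewe combination index for every combination well, the
#' synergy/additivity/antagonism call at the stated thresholds, and the
#' estimator that produced the values. CI < lower threshold (default 0.8)
#' is called synergistic, CI > upper threshold (default 1.2) antagonistic.
#'
#' @slot ci Numeric matrix (rows = doses of drug A, cols = doses of drug B);
#'   NA marks wells where the observed effect lies outside a fitted range.
#' @slot call Character matrix of interaction calls.
#' @slot thresholds Lower/upper CI thresholds.
#' @slot estimator Description of the estimator used.
#' @export
setClass("CIMatrix",
    representation(ci = "matrix", call = "matrix", thresholds = "numeric",
                   estimator = "character"))

setValidity("CIMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@ci), dim(object@call)))
        msg <- c(msg, "ci and call matrices must share dimensions")
    if (any(object@ci <= 0, na.rm = TRUE))
        msg <- c(msg, "defined CI values must be positive")
    if (length(object@thresholds) != 2L ||
        object@thresholds[1] >= object@thresholds[2])
        msg <- c(msg, "thresholds must be (lower, upper) with lower < upper")
    if (length(msg)) msg else TRUE
})
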