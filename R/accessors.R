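#' Accessors for viaquant containers
#'
#' Small accessor generics used across the package: channel rasters and
#' pixel size of a \linkS4class{FieldImage}, the label raster of a
#' \linkS4class{LabelMask}, the event matrix, channel names, event count and
#' acquisition volume of an \linkS4class{EventTable}, counts and percentages
#' of a \linkS4class{PhenotypeCounts}, Hill parameters of a
#' \linkS4class{HillFit} and the CI value/call matrices of a
#' \linkS4class{CIMatrix}.
#'
#' @param x An object of the documented class.
#' @param channel For `channelRaster`, one of "blue", "green", "redOrange".
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelRaster", function(x, channel) standardGeneric("channelRaster"))
#' @rdname accessors
#' @export
setMethod("channelRaster", "FieldImage", function(x, channel) {
    channel <- match.arg(channel, c("blue", "green", "redOrange"))
    slot(x, channel)
})

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "FieldImage", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setMethod("labelData", "LabelMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setMethod("nObjects", "LabelMask", function(x) max(x@mask))

#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))
#' @rdname accessors
#' @export
setMethod("eventData", "EventTable", function(x) x@exprs)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EventTable", function(x) colnames(x@exprs))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@exprs))

#' @rdname accessors
#' @export
setGeneric("acquisitionVolume", function(x) standardGeneric("acquisitionVolume"))
#' @rdname accessors
#' @export
setMethod("acquisitionVolume", "EventTable", function(x) x@volumeUL)

#' @rdname accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname accessors
#' @export
setMethod("truthCells", "GroundTruth", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))
#' @rdname accessors
#' @export
setMethod("truthParams", "GroundTruth", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setMethod("classCounts", "PhenotypeCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("classPercentages", function(x) standardGeneric("classPercentages"))
#' @rdname accessors
#' @export
setMethod("classPercentages", "PhenotypeCounts", function(x) x@percentages)

#' @rdname accessors
#' @export
setGeneric("viableAbsolute", function(x) standardGeneric("viableAbsolute"))
#' @rdname accessors
#' @export
setMethod("viableAbsolute", "PhenotypeCounts", function(x) x@viableAbsolute)

#' @rdname accessors
#' @export
setGeneric("hillParams", function(x) standardGeneric("hillParams"))
#' @rdname accessors
#' @export
setMethod("hillParams", "HillFit", function(x)
    c(bottom = x@bottom, top = x@top, ec50 = x@ec50, hill = x@hill))

#' @rdname accessors
#' @export
setGeneric("ciValues", function(x) standardGeneric("ciValues"))
#' @rdname accessors
#' @export
setMethod("ciValues", "CIMatrix", function(x) x@ci)

#' @rdname accessors
#' @export
setGeneric("ciCalls", function(x) standardGeneric("ciCalls"))
#' @rdname accessors
#' @export
setMethod("ciCalls", "CIMatrix", function(x) x@call)

#' @rdname accessors
#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))
#' @rdname accessors
#' @export
setMethod("plateWells", "CombinationDataset", function(x) x@wells)

setMethod("show", "FieldImage", function(object) {
    d <- dim(object@blue)
    cat("FieldImage '", object@fieldId, "': ", d[1], " x ", d[2],
        " px, 3 channels (blue/green/redOrange), ",
        object@pixelSizeUm, " um/px\n", sep = "")
})

setMethod("show", "LabelMask", function(object) {
    cat("LabelMask: ", nrow(object@mask), " x ", ncol(object@mask),
        " px, ", max(object@mask), " objects\n", sep = "")
})

setMethod("show", "EventTable", function(object) {
    cat("EventTable: ", nrow(object@exprs), " events x ",
        ncol(object@exprs), " channels (",
        paste(colnames(object@exprs), collapse = ", "), ")\n", sep = "")
    vol <- object@volumeUL
    cat("  acquisition volume: ",
        if (is.na(vol)) "unknown" else paste0(vol, " uL"), "\n", sep = "")
    if (length(object@transforms))
        cat("  transforms: ",
            paste(names(object@transforms), collapse = ", "), "\n", sep = "")
})

setMethod("show", "GateSet", function(object) {
    cat("GateSet (", object@mode, ", method = ", object@method,
        ", scale = ", object@scale$type, ")\n", sep = "")
    cat(sprintf("  blue (bright/positive) >= %.4g\n", object@blueThreshold))
    cat(sprintf("  green (DiOC6 high)     >= %.4g\n", object@greenHighThreshold))
    cat(sprintf("  red (YO-PRO-3 +)       >= %.4g\n", object@redPositiveThreshold))
})

setMethod("show", "PhenotypeCounts", function(object) {
    cat("PhenotypeCounts: total =", object@total, "\n")
    df <- data.frame(count = object@counts,
                     percent = round(object@percentages, 2))
    print(df)
    cat("viable (absolute):", object@viableAbsolute, "\n")
    if (!is.na(object@density))
        cat("density:", signif(object@density, 4), object@densityUnit, "\n")
})

setMethod("show", "HillFit", function(object) {
    cat("HillFit (decreasing 4-parameter log-logistic)\n")
    print(signif(hillParams(object), 6))
})

setMethod("show", "CIMatrix", function(object) {
    cat("CIMatrix: ", nrow(object@ci), " x ", ncol(object@ci),
        " combination wells (", object@estimator, ")\n", sep = "")
    tab <- table(factor(object@call,
                        c("synergistic", "additive", "antagonistic",
                          "undefined")))
    print(tab)
})

setMethod("show", "CombinationDataset", function(object) {
    cat("CombinationDataset: ", length(object@doseGridA), " x ",
        length(object@doseGridB), " dose grid (",
        paste(object@drugNames, collapse = " + "), "), ",
        nrow(object@wells), " wells\n", sep = "")
})
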