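.recordChannels <- function(records) {
    if (is(records, "CellTable"))
        return(list(mode = "MICROSCOPY",
                    blue = records$mean_nuclear_blue,
                    green = records$mean_cytoplasm_green,
                    red = records$mean_nuclear_red_orange,
                    n = nrow(records)))
    if (is(records, "EventTable")) {
        mat <- eventData(records)
        need <- c("ch_blue", "ch_green", "ch_red_orange")
        miss <- setdiff(need, colnames(mat))
        if (length(miss))
            stop("missing channel(s): ", paste(miss, collapse = ", "))
        return(list(mode = "CYTOMETRY",
                    blue = mat[, "ch_blue"], green = mat[, "ch_green"],
                    red = mat[, "ch_red_orange"], n = nrow(mat),
                    transforms = records@transforms))
    }
    stop("records must be a CellTable or an EventTable")
}

# classic 1D Otsu on a fixed-bin histogram
.otsu1d <- function(x, nbins = 256) {
    r <- range(x)
    if (diff(r) <= 0) stop("constant channel: threshold underivable")
    h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = nbins + 1),
                        plot = FALSE)
    w <- h$counts / sum(h$counts)
    mids <- h$mids
    omega <- cumsum(w)
    mu <- cumsum(w * mids)
    muT <- mu[length(mu)]
    sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
    sigmaB[!is.finite(sigmaB)] <- 0
    mids[which.max(sigmaB)]
}

# two-component Gaussian mixture threshold on the log scale: the point
# between the component means where the weighted densities are equal
.gmm2Threshold <- function(x) {
    x <- x[x > 0]
    if (length(unique(x)) < 3 || sd(log(x)) == 0)
        stop("constant channel: gmm2 threshold underivable")
    mclustBIC <- mclust::mclustBIC   # Mclust resolves this in caller scope
    fit <- mclust::Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) stop("gmm2 fit failed")
    mu <- fit$parameters$mean
    s <- sqrt(fit$parameters$variance$sigmasq)
    if (length(s) == 1) s <- rep(s, 2)
    pr <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; s <- s[o]; pr <- pr[o]
    f <- function(t) pr[1] * dnorm(t, mu[1], s[1]) -
        pr[2] * dnorm(t, mu[2], s[2])
    thr <- tryCatch(
        uniroot(f, c(mu[1] + 1e-9, mu[2] - 1e-9), tol = 1e-10)$root,
        error = function(e) mean(mu))
    exp(thr)
}

#' Derive gating thresholds from an untreated control sample
#'
#' The three thresholds of the five-phenotype rule are set from a control
#' sample (expected to be essentially all viable). With the default
#' quantile method, the chromatin-bright / exclusion-dye and YO-PRO-3
#' positivity thresholds are placed at the control q-quantile (default
#' q = 0.99) times a positivity margin (default 1.5), so at most (1 - q) of
#' the control exceeds them while the margin keeps the threshold clear of
#' the control tail; the DiOC6(3)-high floor is the control 0.05 quantile
#' divided by the margin. Alternatives: per-channel 1D Otsu ("otsu") and a
#' two-component log-Gaussian mixture ("gmm2"), both data-driven splits for
#' mixed samples. For cytometry records the thresholds are derived and
#' stored on the asinh gating scale (cofactor 150 by default); for
#' microscopy on the raw intensity scale.
#'
#' @param control A \linkS4class{CellTable} or \linkS4class{EventTable}
#'   from an untreated control with at least 50 records.
#' @param method "quantile" (default), "otsu" or "gmm2".
#' @param q Control quantile for the positivity thresholds.
#' @param greenQuantile Control quantile for the DiOC6(3)-high floor.
#' @param margin Multiplicative clearance applied on the raw scale.
#' @param cofactor asinh cofactor for cytometry gating.
#' @param controlId Identifier stored as provenance.
#' @return A \linkS4class{GateSet}.
#' @examples
#' sim <- generateEvents(c(VIABLE = 1), 1000, seed = 5)
#' deriveGates(sim$events)
#' @export
deriveGates <- function(control, method = c("quantile", "otsu", "gmm2"),
                        q = 0.99, greenQuantile = 0.05, margin = 1.5,
                        cofactor = 150, controlId = "control") {
    method <- match.arg(method)
    ch <- .recordChannels(control)
    if (ch$n < 50)
        stop("need at least 50 control cells/events to derive gates")
    thrRaw <- switch(method,
        quantile = c(blue = unname(quantile(ch$blue, q)) * margin,
                     green = unname(quantile(ch$green, greenQuantile)) / margin,
                     red = unname(quantile(ch$red, q)) * margin),
        otsu = c(blue = .otsu1d(ch$blue), green = .otsu1d(ch$green),
                 red = .otsu1d(ch$red)),
        gmm2 = c(blue = .gmm2Threshold(ch$blue),
                 green = .gmm2Threshold(ch$green),
                 red = .gmm2Threshold(ch$red)))
    thrRaw <- pmax(thrRaw, 1e-8)   # positivity thresholds stay positive
    if (ch$mode == "CYTOMETRY") {
        thr <- asinh(thrRaw / cofactor)
        scale <- list(type = "asinh", cofactor = cofactor)
    } else {
        thr <- thrRaw
        scale <- list(type = "linear", cofactor = NA_real_)
    }
    GateSet(blueThreshold = unname(thr["blue"]),
            greenHighThreshold = unname(thr["green"]),
            redPositiveThreshold = unname(thr["red"]),
            mode = ch$mode, scale = scale,
            method = sprintf("%s(q=%g, greenQuantile=%g, margin=%g)",
                             method, q, greenQuantile, margin),
            controlId = controlId)
}

#' Classify cells/events into the five viability phenotypes
#'
#' Decision rule: records at or above the chromatin-bright (microscopy) or
#' exclusion-dye-positive (cytometry) blue threshold are DEAD regardless of
#' the other channels (a fully permeabilized cell can carry aberrant dye
#' levels); all remaining records are split by DiOC6(3) high/low and
#' YO-PRO-3 -/+ into VIABLE (high, -), DYING_YP_HIGH_DIOC (high, +),
#' DYING_YP_LOW_DIOC (low, +) and DYING_LOW_DIOC_ONLY (low, -). All
#' comparisons use >=, so a value exactly at a threshold is bright/positive.
#' The function is total: every record receives exactly one label.
#'
#' @param records A \linkS4class{CellTable} or \linkS4class{EventTable};
#'   the type must match `gates@mode`.
#' @param gates A \linkS4class{GateSet}. For cytometry gates on the asinh
#'   scale, raw event values are transformed internally (already-transformed
#'   channels are detected from the table's transform record).
#' @return Factor of phenotype labels, one per record.
#' @examples
#' sim <- generateEvents(c(VIABLE = 0.5, DEAD = 0.5), 500, seed = 2)
#' gates <- deriveGates(generateEvents(c(VIABLE = 1), 500, seed = 1)$events)
#' table(classifyPhenotypes(sim$events, gates))
#' @export
classifyPhenotypes <- function(records, gates) {
    stopifnot(is(gates, "GateSet"))
    ch <- .recordChannels(records)
    if (ch$mode != gates@mode)
        stop("gates.mode (", gates@mode, ") does not match record type (",
             ch$mode, ")")
    blue <- ch$blue; green <- ch$green; red <- ch$red
    if (gates@scale$type == "asinh") {
        cf <- gates@scale$cofactor
        tfs <- if (!is.null(ch$transforms)) ch$transforms else list()
        already <- function(name) !is.null(tfs[[name]]) &&
            tfs[[name]]$type == "asinh"
        if (!already("ch_blue")) blue <- asinh(blue / cf)
        if (!already("ch_green")) green <- asinh(green / cf)
        if (!already("ch_red_orange")) red <- asinh(red / cf)
    }
    lab <- ifelse(blue >= gates@blueThreshold, "DEAD",
           ifelse(green >= gates@greenHighThreshold,
                  ifelse(red >= gates@redPositiveThreshold,
                         "DYING_YP_HIGH_DIOC", "VIABLE"),
                  ifelse(red >= gates@redPositiveThreshold,
                         "DYING_YP_LOW_DIOC", "DYING_LOW_DIOC_ONLY")))
    factor(lab, levels = phenotypeLabels())
}

#' Tally phenotype labels into absolute counts and percentages
#'
#' Produces per-class counts and percentages, the absolute number of viable
#' cells and, when the imaged area (mm^2) or acquired volume (microliters)
#' is provided, the viable-cell density per mm^2 or per microliter.
#' Border-flagged cells are excluded before counting when `excludeBorder`
#' is on (the default for microscopy, where partial border cells bias the
#' means). Degenerate inputs (no records) yield all-zero counts with
#' percentages reported as 0.
#'
#' @param labels Factor/character phenotype labels (from
#'   [classifyPhenotypes()]).
#' @param areaMm2 Imaged area in mm^2 (microscopy), or NA.
#' @param volumeUL Acquired volume in microliters (cytometry), or NA.
#' @param borderFlags Optional logical vector marking border cells.
#' @param excludeBorder Drop border-flagged cells before counting.
#' @return A \linkS4class{PhenotypeCounts}.
#' @examples
#' countPhenotypes(rep(phenotypeLabels(), each = 10))
#' @export
countPhenotypes <- function(labels, areaMm2 = NA_real_, volumeUL = NA_real_,
                            borderFlags = NULL, excludeBorder = TRUE) {
    labels <- as.character(labels)
    if (!is.null(borderFlags) && excludeBorder) {
        stopifnot(length(borderFlags) == length(labels))
        labels <- labels[!borderFlags]
    }
    bad <- setdiff(unique(labels), phenotypeLabels())
    if (length(bad))
        stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
    counts <- table(factor(labels, levels = phenotypeLabels()))
    counts <- setNames(as.numeric(counts), phenotypeLabels())
    total <- sum(counts)
    pct <- if (total > 0) 100 * counts / total else counts * 0
    viable <- counts[["VIABLE"]]
    if (!is.na(volumeUL) && volumeUL > 0) {
        density <- viable / volumeUL; unit <- "events_per_uL"
    } else if (!is.na(areaMm2) && areaMm2 > 0) {
        density <- viable / areaMm2; unit <- "cells_per_mm2"
    } else {
        density <- NA_real_; unit <- "unknown"
    }
    new("PhenotypeCounts", counts = counts, percentages = pct,
        total = total, viableAbsolute = viable, density = density,
        densityUnit = unit)
}

#' Serialize a GateSet to/from JSON
#'
#' @param gates A \linkS4class{GateSet}.
#' @param path JSON path.
#' @return `writeGateSet` the path invisibly; `readGateSet` a
#'   \linkS4class{GateSet}.
#' @export
writeGateSet <- function(gates, path) {
    stopifnot(is(gates, "GateSet"))
    jsonlite::write_json(list(
        blue_threshold = gates@blueThreshold,
        green_high_threshold = gates@greenHighThreshold,
        red_positive_threshold = gates@redPositiveThreshold,
        mode = gates@mode, scale = gates@scale, method = gates@method,
        control_id = gates@controlId), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGateSet
#' @export
readGateSet <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    GateSet(x$blue_threshold, x$green_high_threshold,
            x$red_positive_threshold, mode = x$mode,
            scale = list(type = x$scale$type,
                         cofactor = as.numeric(x$scale$cofactor)),
            method = x$method, controlId = x$control_id)
}

#' Write per-cell features or phenotype counts as CSV
#'
#' Fixed, documented column orders: cells as (cell_id, centroid_row,
#' centroid_col, nucleus_area_px, mean_nuclear_blue,
#' mean_nuclear_red_orange, mean_cytoplasm_green, border_flag); counts as
#' one row per sample with (sample, total, one count and one percentage
#' column per phenotype, viable_absolute, density, density_unit).
#'
#' @param cells A \linkS4class{CellTable}.
#' @param counts A named list of \linkS4class{PhenotypeCounts} (names are
#'   sample ids) or a single object.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
writeCellTable <- function(cells, path) {
    stopifnot(is(cells, "CellTable"))
    df <- as.data.frame(cells)[, .cellTableColumns, drop = FALSE]
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCellTable
#' @export
writeCounts <- function(counts, path) {
    if (is(counts, "PhenotypeCounts")) counts <- list(sample = counts)
    rows <- lapply(names(counts), function(id) {
        x <- counts[[id]]
        df <- data.frame(sample = id, total = x@total)
        for (cl in phenotypeLabels()) {
            df[[paste0("count_", tolower(cl))]] <- x@counts[[cl]]
            df[[paste0("pct_", tolower(cl))]] <- x@percentages[[cl]]
        }
        df$viable_absolute <- x@viableAbsolute
        df$density <- x@density
        df$density_unit <- x@densityUnit
        df
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}
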