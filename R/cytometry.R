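#' @describeIn EventTable Row (event) subsetting; channel metadata,
#'   acquisition volume and transform records are preserved.
#' @param x,i,j,drop Standard subsetting arguments (j/drop ignored).
#' @param ... Ignored.
#' @export
setMethod("[", "EventTable", function(x, i, j, ..., drop = FALSE) {
    EventTable(x@exprs[i, , drop = FALSE], volumeUL = x@volumeUL,
               transforms = x@transforms)
})

#' Robust forward/side-scatter pre-gate
#'
#' Retains events inside a robust-covariance ellipse on (FSC, SSC): the
#' location and scatter of the main population are estimated by the
#' minimum-covariance-determinant method (or the classical moments), and
#' events whose squared Mahalanobis distance is within the chi-squared
#' (2 df) quantile at the requested coverage are kept. This removes debris
#' and aberrant-scatter events before fluorescence gating, without a
#' manual polygon. Row order is preserved; the input is not modified.
#'
#' @param events An \linkS4class{EventTable} with FSC and SSC channels.
#' @param coverage Target coverage fraction of the main population
#'   (0 < coverage < 1; default 0.99).
#' @param method "mcd" (robust, default) or "classical".
#' @return List with `events` (gated \linkS4class{EventTable}), `keep`
#'   (logical vector over input rows) and `gate` (center, covariance,
#'   coverage, Mahalanobis cutoff, retained fraction) for audit.
#' @examples
#' sim <- generateEvents(c(VIABLE = 1), 1000, debrisFraction = 0.1, seed = 3)
#' g <- scatterGate(sim$events)
#' g$gate$retainedFraction
#' @export
scatterGate <- function(events, coverage = 0.99,
                        method = c("mcd", "classical")) {
    method <- match.arg(method)
    stopifnot(is(events, "EventTable"))
    if (coverage <= 0 || coverage >= 1)
        stop("coverage must be strictly between 0 and 1")
    mat <- eventData(events)
    if (!all(c("FSC", "SSC") %in% colnames(mat)))
        stop("events must carry FSC and SSC channels")
    if (nrow(mat) < 10)
        stop("scatter gate unfittable: fewer than 10 events")
    xy <- mat[, c("FSC", "SSC")]
    est <- if (method == "mcd") MASS::cov.rob(xy, method = "mcd")
           else list(center = colMeans(xy), cov = stats::cov(xy))
    cutoff <- stats::qchisq(coverage, df = 2)
    md <- stats::mahalanobis(xy, est$center, est$cov)
    keep <- md <= cutoff
    list(events = events[keep, ], keep = keep,
         gate = list(center = est$center, cov = est$cov,
                     coverage = coverage, method = method,
                     mahalanobisCutoff = cutoff,
                     nInput = nrow(mat), nRetained = sum(keep),
                     retainedFraction = mean(keep)))
}

.transformSpec <- function(spec) {
    norm <- lapply(spec, function(s) {
        if (is.character(s)) s <- list(type = s)
        if (is.null(s$type)) stop("transform spec entries need a 'type'")
        if (!s$type %in% c("linear", "log10", "asinh"))
            stop("unknown transform '", s$type,
                 "' (use linear, log10 or asinh)")
        if (s$type == "asinh" && is.null(s$cofactor)) s$cofactor <- 150
        if (s$type == "log10" && is.null(s$floor)) s$floor <- 1
        s
    })
    if (is.null(names(norm)) || any(names(norm) == ""))
        stop("transform spec must be named by channel")
    norm
}

#' Per-channel display/gating transforms
#'
#' Applies an invertible transform to selected channels: `linear`
#' (identity), `log10` (values are floored at a configurable positive floor
#' first, default 1), or `asinh` with a cofactor (default 150; the usual
#' gating scale for fluorescence, linear near zero and logarithmic for
#' bright signals). The applied transforms are recorded in the table's
#' metadata; [inverseTransformChannels()] restores the original scale
#' (exactly, except below the log10 floor).
#'
#' @param events An \linkS4class{EventTable}.
#' @param spec Named list/character vector: channel -> "linear", "log10",
#'   "asinh", or list(type=, cofactor=/floor=).
#' @return A new \linkS4class{EventTable}; the input is not modified.
#' @examples
#' sim <- generateEvents(c(VIABLE = 1), 50, seed = 1)
#' tr <- transformChannels(sim$events, list(ch_blue = "asinh"))
#' @export
transformChannels <- function(events, spec) {
    stopifnot(is(events, "EventTable"))
    spec <- .transformSpec(spec)
    mat <- eventData(events)
    unknown <- setdiff(names(spec), colnames(mat))
    if (length(unknown))
        stop("unknown channel(s): ", paste(unknown, collapse = ", "))
    for (ch in names(spec)) {
        s <- spec[[ch]]
        mat[, ch] <- switch(s$type,
            linear = mat[, ch],
            log10 = log10(pmax(mat[, ch], s$floor)),
            asinh = asinh(mat[, ch] / s$cofactor))
    }
    tf <- events@transforms
    tf[names(spec)] <- spec
    EventTable(mat, volumeUL = events@volumeUL, transforms = tf)
}

#' @rdname transformChannels
#' @export
inverseTransformChannels <- function(events) {
    stopifnot(is(events, "EventTable"))
    mat <- eventData(events)
    for (ch in names(events@transforms)) {
        s <- events@transforms[[ch]]
        mat[, ch] <- switch(s$type,
            linear = mat[, ch],
            log10 = 10^mat[, ch],
            asinh = sinh(mat[, ch]) * s$cofactor)
    }
    EventTable(mat, volumeUL = events@volumeUL, transforms = list())
}
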