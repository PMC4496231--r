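# Minimal FCS 3.1 list-mode reader/writer (float32 or integer data).
# Scope: one dataset per file, $DATATYPE F or I, no parameter-value
# escaping inside keywords (the writer never produces any).

.fcsHeader <- function(con) {
    hdr <- readChar(con, 58, useBytes = TRUE)
    if (nchar(hdr) < 58) stop("FCS parse error: truncated header")
    version <- substr(hdr, 1, 6)
    if (!version %in% c("FCS3.0", "FCS3.1"))
        stop("unsupported FCS version: ", version)
    off <- suppressWarnings(as.numeric(c(
        substr(hdr, 11, 18), substr(hdr, 19, 26), substr(hdr, 27, 34),
        substr(hdr, 35, 42), substr(hdr, 43, 50), substr(hdr, 51, 58))))
    if (any(is.na(off[1:2])))
        stop("FCS parse error: unreadable TEXT segment offsets")
    list(version = version, textBegin = off[1], textEnd = off[2],
         dataBegin = off[3], dataEnd = off[4])
}

#' Read an FCS 3.0/3.1 file into an EventTable
#'
#' Supports list-mode datasets with `$DATATYPE` F (float32) or I
#' (unsigned integer). Channel names come from `$PnN`; the acquisition
#' volume is taken from the standard `$VOL` keyword (nanoliters) when
#' present. Missing mandatory keywords and truncated DATA segments raise
#' descriptive parse errors.
#'
#' @param path Path to the FCS file.
#' @return An \linkS4class{EventTable}.
#' @seealso [writeFCS()]
#' @export
readFCS <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- .fcsHeader(con)
    seek(con, hdr$textBegin)
    txt <- readChar(con, hdr$textEnd - hdr$textBegin + 1, useBytes = TRUE)
    delim <- substr(txt, 1, 1)
    parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
    if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
    kw <- setNames(parts[seq(2, length(parts), 2)],
                   toupper(trimws(parts[seq(1, length(parts), 2)])))
    need <- c("$PAR", "$TOT", "$DATATYPE", "$MODE", "$BYTEORD")
    miss <- setdiff(need, names(kw))
    if (length(miss))
        stop("FCS parse error: missing mandatory keyword(s) ",
             paste(miss, collapse = ", "))
    if (kw[["$MODE"]] != "L")
        stop("FCS parse error: only list mode ($MODE L) is supported")
    dtype <- kw[["$DATATYPE"]]
    if (!dtype %in% c("F", "I"))
        stop("FCS parse error: unsupported $DATATYPE '", dtype,
             "' (only F and I are supported)")
    npar <- as.integer(kw[["$PAR"]])
    ntot <- as.numeric(kw[["$TOT"]])
    names_n <- vapply(seq_len(npar), function(i) {
        key <- sprintf("$P%dN", i)
        if (!key %in% names(kw))
            stop("FCS parse error: missing mandatory keyword ", key)
        kw[[key]]
    }, character(1))
    bits <- vapply(seq_len(npar), function(i) {
        key <- sprintf("$P%dB", i)
        if (!key %in% names(kw))
            stop("FCS parse error: missing mandatory keyword ", key)
        as.integer(kw[[key]])
    }, integer(1))
    endian <- switch(kw[["$BYTEORD"]],
                     "1,2,3,4" = "little", "4,3,2,1" = "big",
                     stop("FCS parse error: unsupported $BYTEORD ",
                          kw[["$BYTEORD"]]))
    dataBegin <- hdr$dataBegin
    dataEnd <- hdr$dataEnd
    if (is.na(dataBegin) || dataBegin == 0) {
        if (!all(c("$BEGINDATA", "$ENDDATA") %in% names(kw)))
            stop("FCS parse error: DATA segment offsets unavailable")
        dataBegin <- as.numeric(kw[["$BEGINDATA"]])
        dataEnd <- as.numeric(kw[["$ENDDATA"]])
    }
    nValues <- npar * ntot
    mat <- matrix(numeric(0), 0, npar, dimnames = list(NULL, names_n))
    if (nValues > 0) {
        seek(con, dataBegin)
        if (dtype == "F") {
            if (any(bits != 32))
                stop("FCS parse error: $DATATYPE F requires $PnB 32")
            vals <- readBin(con, "numeric", n = nValues, size = 4,
                            endian = endian)
        } else {
            if (length(unique(bits)) != 1)
                stop("FCS parse error: mixed $PnB widths not supported")
            vals <- readBin(con, "integer", n = nValues, size = bits[1] / 8,
                            signed = bits[1] <= 16, endian = endian)
        }
        if (length(vals) < nValues)
            stop("FCS parse error: truncated DATA segment (expected ",
                 nValues, " values, read ", length(vals), ")")
        mat <- matrix(vals, ncol = npar, byrow = TRUE,
                      dimnames = list(NULL, names_n))
    }
    vol <- if ("$VOL" %in% names(kw))
        as.numeric(kw[["$VOL"]]) / 1000 else NA_real_
    EventTable(mat, volumeUL = vol)
}

#' Write an EventTable as FCS 3.1
#'
#' Writes a single list-mode dataset with `$DATATYPE` F (float32, little
#' endian), `$PnN` from the channel names, and the acquisition volume as
#' the standard `$VOL` keyword (nanoliters) when known.
#'
#' @param events An \linkS4class{EventTable} with at least one channel and
#'   finite values.
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(events, path) {
    stopifnot(is(events, "EventTable"))
    mat <- eventData(events)
    if (ncol(mat) == 0) stop("cannot write an FCS file with no channels")
    if (length(mat) && !all(is.finite(mat)))
        stop("cannot write non-finite event values")
    npar <- ncol(mat); ntot <- nrow(mat)
    kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%010d", 0),
            "$ENDDATA", sprintf("%010d", 0),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0", "$PAR", as.character(npar),
            "$TOT", as.character(ntot))
    if (!is.na(acquisitionVolume(events)))
        kv <- c(kv, "$VOL",
                sprintf("%.6g", acquisitionVolume(events) * 1000))
    for (i in seq_len(npar))
        kv <- c(kv, sprintf("$P%dN", i), colnames(mat)[i],
                sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
                sprintf("$P%dR", i), "262144")
    delim <- "/"
    buildText <- function(kv) paste0(delim, paste(kv, collapse = delim), delim)
    txt <- buildText(kv)
    headerLen <- 58
    textBegin <- headerLen
    textEnd <- textBegin + nchar(txt, type = "bytes") - 1
    dataBegin <- textEnd + 1
    dataEnd <- if (ntot > 0) dataBegin + 4 * npar * ntot - 1 else 0
    kv[which(kv == "$BEGINDATA") + 1] <- sprintf("%010d", dataBegin)
    kv[which(kv == "$ENDDATA") + 1] <- sprintf("%010d", max(dataEnd, 0))
    txt <- buildText(kv)
    fmtOff <- function(x) formatC(x, width = 8, format = "d", flag = " ")
    header <- paste0("FCS3.1    ", fmtOff(textBegin), fmtOff(textEnd),
                     if (dataEnd <= 99999999 && ntot > 0)
                         paste0(fmtOff(dataBegin), fmtOff(dataEnd))
                     else paste0(fmtOff(0), fmtOff(0)),
                     fmtOff(0), fmtOff(0))
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL, useBytes = TRUE)
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
    if (ntot > 0)
        writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
    invisible(path)
}

#' Read/write an EventTable as CSV
#'
#' Plain-text mirror of the FCS representation: one column per channel plus
#' an optional `volume_uL` comment header line.
#'
#' @param events An \linkS4class{EventTable}.
#' @param path CSV path.
#' @return `writeEventCSV` the path invisibly; `readEventCSV` an
#'   \linkS4class{EventTable}.
#' @export
writeEventCSV <- function(events, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# volume_uL=%s", acquisitionVolume(events)), con)
    write.csv(as.data.frame(eventData(events)), con, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEventCSV
#' @export
readEventCSV <- function(path) {
    first <- readLines(path, n = 1)
    vol <- NA_real_
    skip <- 0
    if (startsWith(first, "# volume_uL=")) {
        vol <- suppressWarnings(as.numeric(sub("# volume_uL=", "", first)))
        skip <- 1
    }
    df <- read.csv(path, skip = skip, check.names = FALSE)
    EventTable(as.matrix(df), volumeUL = vol)
}
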