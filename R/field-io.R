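#' Write/read a FieldImage as per-channel 16-bit TIFF plus JSON sidecar
#'
#' Each channel goes to `<fieldId>_<channel>.tif` (16-bit grayscale); the
#' sidecar `<fieldId>.json` records the field id, pixel size, the
#' channel-to-fluorochrome map and the intensity range, so a field
#' round-trips losslessly at 16-bit resolution.
#'
#' @param field A \linkS4class{FieldImage}.
#' @param dir Output directory (created if needed).
#' @param fieldId Field id for `readFieldImage` (the sidecar base name).
#' @return `writeFieldImage` the sidecar path invisibly; `readFieldImage`
#'   a \linkS4class{FieldImage}.
#' @export
writeFieldImage <- function(field, dir) {
    stopifnot(is(field, "FieldImage"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    maxI <- 65535
    chans <- c(blue = "blue", green = "green", redOrange = "redOrange")
    files <- list()
    for (ch in names(chans)) {
        f <- file.path(dir, sprintf("%s_%s.tif", field@fieldId, ch))
        m <- pmin(slot(field, ch), maxI) / maxI
        EBImage::writeImage(EBImage::Image(m), f, type = "tiff",
                            bits.per.sample = 16L)
        files[[ch]] <- basename(f)
    }
    sidecar <- file.path(dir, paste0(field@fieldId, ".json"))
    jsonlite::write_json(list(
        field_id = field@fieldId, pixel_size_um = field@pixelSizeUm,
        max_intensity = maxI,
        channels = list(blue = list(file = files$blue,
                                    fluor = "Hoechst33342/DAPI"),
                        green = list(file = files$green, fluor = "DiOC6(3)"),
                        redOrange = list(file = files$redOrange,
                                         fluor = "YO-PRO-3"))),
        sidecar, auto_unbox = TRUE, digits = NA)
    invisible(sidecar)
}

#' @rdname writeFieldImage
#' @export
readFieldImage <- function(dir, fieldId) {
    sidecar <- file.path(dir, paste0(fieldId, ".json"))
    if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rd <- function(f) {
        img <- EBImage::readImage(file.path(dir, f))
        as.matrix(EBImage::imageData(img)) * meta$max_intensity
    }
    FieldImage(rd(meta$channels$blue$file), rd(meta$channels$green$file),
               rd(meta$channels$redOrange$file),
               pixelSizeUm = meta$pixel_size_um, fieldId = meta$field_id)
}
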