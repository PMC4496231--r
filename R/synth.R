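#' Intensity presets for the synthetic viability assay
#'
#' Class-conditional intensity models for the five phenotypes. Fluorescence
#' is log-normal per channel per class (fluorescence intensities are
#' right-skewed); the "default" preset separates the dim/bright, high/low
#' and -/+ bands by 10-fold geometric means, the "hard" preset by 3-fold
#' for stress testing. Microscopy blue uses chromatin dim/bright bands; in
#' cytometry the blue channel is either an exclusion dye (DAPI mode,
#' negative/positive) or the chromatin dye (HOECHST mode).
#'
#' @param name "default" (10x band separation) or "hard" (3x).
#' @return A list with per-channel band geometric means and log-sd values,
#'   nuclear/cytoplasm morphology, scatter-population parameters and the
#'   microscopy camera model (background offset, 16-bit range).
#' @examples
#' p <- phenotypePreset("default")
#' p$bands$green
#' @export
phenotypePreset <- function(name = c("default", "hard")) {
    name <- match.arg(name)
    sep <- if (name == "default") 10 else 3
    list(
        name = name,
        separation = sep,
        bands = list(
            blue = c(dim = 400, bright = 400 * sep),
            blue_exclusion = c(neg = 50, pos = 50 * sep * 4),
            green = c(low = 3000 / sep, high = 3000),
            red = c(neg = 150, pos = 150 * sep)),
        sdlog = c(blue = 0.25, blue_exclusion = 0.35, green = 0.25,
                  red = 0.30),
        morphology = list(nucleusRadiusMean = 8, nucleusRadiusSd = 1,
                          deadRadiusFactor = 0.7,
                          cytoplasmRadiusFactor = 2.2),
        scatter = list(fscMain = c(mean = 50000, sd = 8000),
                       sscMain = c(mean = 30000, sd = 6000),
                       fscDebris = c(mean = 8000, sd = 3000),
                       sscDebris = c(mean = 5000, sd = 2500),
                       debrisFluorGm = 50, debrisFluorSdlog = 0.5),
        camera = list(background = 80, maxIntensity = 65535)
    )
}

# level each phenotype occupies on each channel axis
.classLevels <- function() {
    rbind(VIABLE              = c(blue = "dim",    green = "high", red = "neg"),
          DEAD                = c(blue = "bright", green = "low",  red = "pos"),
          DYING_YP_HIGH_DIOC  = c(blue = "dim",    green = "high", red = "pos"),
          DYING_YP_LOW_DIOC   = c(blue = "dim",    green = "low",  red = "pos"),
          DYING_LOW_DIOC_ONLY = c(blue = "dim",    green = "low",  red = "neg"))
}

# per-class log-normal (meanlog, sdlog) for the three fluorescence channels.
# mode: MICROSCOPY/HOECHST -> chromatin dim/bright blue; DAPI -> exclusion
# -/+ blue.
.classParams <- function(preset, mode = "MICROSCOPY") {
    lev <- .classLevels()
    blueBand <- if (mode == "DAPI") preset$bands$blue_exclusion else
        preset$bands$blue
    blueMap <- if (mode == "DAPI") c(dim = "neg", bright = "pos") else
        c(dim = "dim", bright = "bright")
    blueSd <- if (mode == "DAPI") preset$sdlog[["blue_exclusion"]] else
        preset$sdlog[["blue"]]
    out <- lapply(rownames(lev), function(cl) {
        list(blue = c(meanlog = log(blueBand[[blueMap[[lev[cl, "blue"]]]]]),
                      sdlog = blueSd),
             green = c(meanlog = log(preset$bands$green[[lev[cl, "green"]]]),
                       sdlog = preset$sdlog[["green"]]),
             red = c(meanlog = log(preset$bands$red[[lev[cl, "red"]]]),
                     sdlog = preset$sdlog[["red"]]))
    })
    names(out) <- rownames(lev)
    out
}

.checkMix <- function(phenotypeMix) {
    labs <- phenotypeLabels()
    if (is.null(names(phenotypeMix)))
        stop("phenotypeMix must be named by phenotype labels")
    if (!all(names(phenotypeMix) %in% labs))
        stop("unknown phenotype labels: ",
             paste(setdiff(names(phenotypeMix), labs), collapse = ", "))
    mix <- setNames(numeric(length(labs)), labs)
    mix[names(phenotypeMix)] <- phenotypeMix
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
        stop("phenotypeMix proportions must be non-negative and sum to 1")
    mix
}

.resolvePreset <- function(preset) {
    if (is.character(preset)) phenotypePreset(preset) else preset
}

# linear indices of the disk of radius r around (row, col) clipped to dims
.diskIndices <- function(row, col, r, dims) {
    r0 <- max(1L, floor(row - r)); r1 <- min(dims[1], ceiling(row + r))
    c0 <- max(1L, floor(col - r)); c1 <- min(dims[2], ceiling(col + r))
    rr <- r0:r1; cc <- c0:c1
    dr <- outer(rr - row, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - col)
    inside <- (dr * dr + dc * dc) <= r * r
    idx <- (rep(cc, each = length(rr)) - 1L) * dims[1] +
        rep(rr, times = length(cc))
    idx[as.vector(inside)]
}

#' Simulate one three-channel microscope field with known ground truth
#'
#' Places non-overlapping round nuclei (blue disk; for DEAD cells a smaller,
#' brighter disk mimicking chromatin condensation) surrounded by a
#' cytoplasmic annulus (green, DiOC6(3)) with nuclear red/orange (YO-PRO-3)
#' per phenotype, on a uniform background with Gaussian read noise and
#' optional Poisson shot noise, clipped to the 16-bit camera range.
#'
#' @param phenotypeMix Named proportions over the five phenotype labels
#'   (must sum to 1; omitted labels get 0).
#' @param nCells Number of cells to place (>= 0).
#' @param shape Field size in pixels, c(rows, cols).
#' @param noiseSd Additive Gaussian read-noise sd (intensity units).
#' @param poissonNoise If TRUE, Poisson shot noise replaces the rendered
#'   mean in each pixel before read noise is added.
#' @param preset Preset name ("default"/"hard") or a preset list.
#' @param minDistFactor Minimum nucleus center distance as a multiple of the
#'   mean nucleus radius (default 2.2: the non-overlapping regime).
#' @param pixelSizeUm Pixel size in micrometers.
#' @param fieldId Field identifier.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `field` (a \linkS4class{FieldImage}) and `truth` (a
#'   \linkS4class{GroundTruth} whose cells hold centroid, nucleus mask id
#'   and phenotype; the nucleus label raster and generating class parameters
#'   are in `truthParams()`).
#' @examples
#' sim <- generateField(c(VIABLE = 1), nCells = 5, shape = c(128, 128),
#'                      seed = 1)
#' sim$field
#' @export
generateField <- function(phenotypeMix, nCells, shape = c(512, 512),
                          noiseSd = 8, poissonNoise = FALSE,
                          preset = "default", minDistFactor = 2.2,
                          pixelSizeUm = 0.65, fieldId = "field1",
                          seed = NULL) {
    mix <- .checkMix(phenotypeMix)
    if (nCells < 0) stop("nCells must be >= 0")
    preset <- .resolvePreset(preset)
    if (!is.null(seed)) set.seed(seed)
    dims <- as.integer(shape)
    morph <- preset$morphology
    bg <- preset$camera$background
    blue <- matrix(bg, dims[1], dims[2])
    green <- matrix(bg, dims[1], dims[2])
    red <- matrix(bg, dims[1], dims[2])
    mask <- matrix(0L, dims[1], dims[2])
    labs <- phenotypeLabels()
    cls <- .classParams(preset, "MICROSCOPY")

    if (nCells > 0) {
        phen <- sample(labs, nCells, replace = TRUE, prob = mix)
        radius <- pmin(pmax(rnorm(nCells, morph$nucleusRadiusMean,
                                  morph$nucleusRadiusSd), 4), 12)
        radius[phen == "DEAD"] <- radius[phen == "DEAD"] * morph$deadRadiusFactor
        minDist <- minDistFactor * morph$nucleusRadiusMean
        margin <- ceiling(max(radius)) + 2
        if (2 * margin >= min(dims))
            stop("field shape too small for the requested nucleus radii")
        centers <- matrix(NA_real_, nCells, 2)
        placed <- 0L
        attempts <- 0L
        maxAttempts <- 500L * nCells
        while (placed < nCells) {
            attempts <- attempts + 1L
            if (attempts > maxAttempts)
                stop(sprintf(paste0(
                    "could not place %d cells in a %d x %d field at minimum ",
                    "center distance %.1f px: reduce nCells, minDistFactor ",
                    "or enlarge the field"), nCells, dims[1], dims[2], minDist))
            cand <- c(runif(1, margin, dims[1] - margin),
                      runif(1, margin, dims[2] - margin))
            if (placed == 0L ||
                min((centers[seq_len(placed), 1] - cand[1])^2 +
                    (centers[seq_len(placed), 2] - cand[2])^2) >= minDist^2) {
                placed <- placed + 1L
                centers[placed, ] <- cand
            }
        }
        for (i in seq_len(nCells)) {
            p <- cls[[phen[i]]]
            vB <- rlnorm(1, p$blue[1], p$blue[2])
            vG <- rlnorm(1, p$green[1], p$green[2])
            vR <- rlnorm(1, p$red[1], p$red[2])
            nuc <- .diskIndices(centers[i, 1], centers[i, 2], radius[i], dims)
            nuc <- nuc[mask[nuc] == 0L]   # keep masks pairwise disjoint
            mask[nuc] <- i
            blue[nuc] <- bg + vB
            red[nuc] <- bg + vR
            outer <- .diskIndices(centers[i, 1], centers[i, 2],
                                  radius[i] * morph$cytoplasmRadiusFactor,
                                  dims)
            ann <- setdiff(outer, .diskIndices(centers[i, 1], centers[i, 2],
                                               radius[i], dims))
            green[ann] <- pmax(green[ann], bg + vG)
        }
        truthDf <- DataFrame(cell_id = seq_len(nCells),
                             centroid_row = centers[, 1] - 1,
                             centroid_col = centers[, 2] - 1,
                             radius_px = radius, phenotype = phen)
    } else {
        truthDf <- DataFrame(cell_id = integer(), centroid_row = numeric(),
                             centroid_col = numeric(), radius_px = numeric(),
                             phenotype = character())
    }

    addNoise <- function(m) {
        if (poissonNoise) m <- matrix(rpois(length(m), m), nrow(m))
        m <- m + rnorm(length(m), 0, noiseSd)
        pmin(pmax(m, 0), preset$camera$maxIntensity)
    }
    if (noiseSd > 0 || poissonNoise) {
        blue <- addNoise(blue); green <- addNoise(green); red <- addNoise(red)
    }
    field <- FieldImage(blue, green, red, pixelSizeUm = pixelSizeUm,
                        fieldId = fieldId)
    truth <- GroundTruth(truthDf,
                         params = list(preset = preset$name,
                                       classParams = cls,
                                       nucleusMask = mask,
                                       background = bg, noiseSd = noiseSd),
                         seed = if (is.null(seed)) NA_real_ else seed)
    list(field = field, truth = truth)
}

#' Simulate flow-cytometry events with known ground truth
#'
#' Draws forward/side scatter from a main cell population plus an optional
#' debris fraction at low FSC/SSC, and the three fluorescence channels from
#' the class-conditional log-normal models of the preset. In DAPI mode the
#' blue channel behaves as an exclusion dye (bimodal negative/positive); in
#' HOECHST mode as a chromatin dye (dim/bright).
#'
#' @param phenotypeMix Named proportions over the five phenotypes (sum 1).
#' @param nEvents Number of events (>= 0); debris events are added within
#'   this total.
#' @param mode "DAPI" or "HOECHST" behaviour of the blue channel.
#' @param volumeUL Acquired volume in microliters (NA if the instrument does
#'   not meter volume).
#' @param debrisFraction Fraction of events planted as low-scatter debris.
#' @param preset Preset name or list (see [phenotypePreset()]).
#' @param seed Integer seed.
#' @return List with `events` (an \linkS4class{EventTable}) and `truth`
#'   (phenotype per event, with debris marked `DEBRIS`).
#' @examples
#' sim <- generateEvents(c(VIABLE = 1), nEvents = 100, seed = 3)
#' sim$events
#' @export
generateEvents <- function(phenotypeMix, nEvents, mode = c("DAPI", "HOECHST"),
                           volumeUL = 100, debrisFraction = 0,
                           preset = "default", seed = NULL) {
    mode <- match.arg(mode)
    mix <- .checkMix(phenotypeMix)
    if (nEvents < 0) stop("nEvents must be >= 0")
    if (!is.na(volumeUL) && volumeUL < 0)
        stop("acquisition volume must be non-negative")
    if (debrisFraction < 0 || debrisFraction >= 1)
        stop("debrisFraction must be in [0, 1)")
    preset <- .resolvePreset(preset)
    if (!is.null(seed)) set.seed(seed)
    cls <- .classParams(preset, mode)
    sc <- preset$scatter

    if (nEvents == 0) {
        exprs <- matrix(numeric(0), 0, 5,
                        dimnames = list(NULL, .canonicalChannels))
        return(list(events = EventTable(exprs, volumeUL = volumeUL),
                    truth = GroundTruth(DataFrame(event_id = integer(),
                                                  phenotype = character(),
                                                  is_debris = logical()),
                                        params = list(preset = preset$name,
                                                      classParams = cls,
                                                      mode = mode),
                                        seed = if (is.null(seed)) NA_real_
                                               else seed)))
    }

    nDebris <- round(debrisFraction * nEvents)
    phen <- c(rep("DEBRIS", nDebris),
              sample(phenotypeLabels(), nEvents - nDebris, replace = TRUE,
                     prob = mix))
    phen <- sample(phen)
    debris <- phen == "DEBRIS"

    fsc <- ssc <- chB <- chG <- chR <- numeric(nEvents)
    nMain <- sum(!debris)
    fsc[!debris] <- pmax(rnorm(nMain, sc$fscMain[1], sc$fscMain[2]), 1)
    ssc[!debris] <- pmax(rnorm(nMain, sc$sscMain[1], sc$sscMain[2]), 1)
    fsc[debris] <- pmax(rnorm(nDebris, sc$fscDebris[1], sc$fscDebris[2]), 1)
    ssc[debris] <- pmax(rnorm(nDebris, sc$sscDebris[1], sc$sscDebris[2]), 1)
    chB[debris] <- rlnorm(nDebris, log(sc$debrisFluorGm), sc$debrisFluorSdlog)
    chG[debris] <- rlnorm(nDebris, log(sc$debrisFluorGm), sc$debrisFluorSdlog)
    chR[debris] <- rlnorm(nDebris, log(sc$debrisFluorGm), sc$debrisFluorSdlog)
    for (cl in phenotypeLabels()) {
        idx <- which(phen == cl)
        if (!length(idx)) next
        p <- cls[[cl]]
        chB[idx] <- rlnorm(length(idx), p$blue[1], p$blue[2])
        chG[idx] <- rlnorm(length(idx), p$green[1], p$green[2])
        chR[idx] <- rlnorm(length(idx), p$red[1], p$red[2])
    }
    exprs <- cbind(FSC = fsc, SSC = ssc, ch_blue = chB, ch_green = chG,
                   ch_red_orange = chR)
    truth <- GroundTruth(DataFrame(event_id = seq_len(nEvents),
                                   phenotype = phen, is_debris = debris),
                         params = list(preset = preset$name, classParams = cls,
                                       mode = mode,
                                       debrisFraction = debrisFraction),
                         seed = if (is.null(seed)) NA_real_ else seed)
    list(events = EventTable(exprs, volumeUL = volumeUL), truth = truth)
}
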