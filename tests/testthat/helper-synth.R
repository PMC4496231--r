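# shared fixtures: an even five-class mix and a pooled-control microscopy
# gate derivation used by several test files
evenMix <- function() {
    setNames(rep(0.2, 5), phenotypeLabels())
}

controlGatesMicroscopy <- function(seeds = 101:103, nCells = 50) {
    cells <- do.call(rbind, lapply(seeds, function(s)
        analyzeField(generateField(c(VIABLE = 1), nCells, seed = s)$field)$cells))
    deriveGates(CellTable(cells))
}

# match detected centroids to planted ones; returns per-detection nearest
# truth index and distances in both directions
matchCentroids <- function(truth, cells) {
    nt <- nrow(truth); nc <- nrow(cells)
    d <- as.matrix(dist(rbind(cbind(truth$centroid_row, truth$centroid_col),
                              cbind(cells$centroid_row, cells$centroid_col))))
    d <- d[seq_len(nt), nt + seq_len(nc), drop = FALSE]
    list(truthToDet = apply(d, 1, min), detToTruth = apply(d, 2, min),
         assign = apply(d, 2, which.min))
}
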