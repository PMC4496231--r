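#' Compare viable counts between two conditions
#'
#' Two-tailed unpaired Student's t-test on replicate viable counts. The
#' classical pooled-variance (equal-variance) form is the default; the
#' Welch form is available via `welch = TRUE`. The significance code uses
#' the conventional star scale: ns (p >= 0.05), * (p < 0.05), ** (p < 0.01),
#' *** (p < 0.001).
#'
#' @param countsA,countsB Numeric replicate vectors (each length >= 2).
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `statistic` (t), `df`, `p.value` (two-sided) and
#'   `code`.
#' @examples
#' compareConditions(c(10, 12, 11), c(20, 22, 21))
#' @export
compareConditions <- function(countsA, countsB, welch = FALSE) {
    if (length(countsA) < 2 || length(countsB) < 2)
        stop("each condition needs at least 2 replicates")
    ht <- stats::t.test(countsA, countsB, var.equal = !welch,
                        alternative = "two.sided")
    p <- ht$p.value
    code <- if (p < 0.001) "***" else if (p < 0.01) "**" else
        if (p < 0.05) "*" else "ns"
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = p, code = code)
}

#' Render a combination-index heatmap
#'
#' Dose-grid heatmap of combination indexes in the conventional colouring:
#' synergistic wells (CI below the lower threshold) green, antagonistic
#' wells (CI above the upper threshold) red, additive wells neutral grey;
#' undefined wells are crossed out. A colour-vision-safe palette
#' (blue/orange) is available.
#'
#' @param ci A \linkS4class{CIMatrix}.
#' @param path Output file (.png or .pdf, decided by extension).
#' @param palette "classic" (green/red) or "cvd" (blue/orange).
#' @param width,height Device size in inches.
#' @return The path, invisibly.
#' @export
renderCIHeatmap <- function(ci, path, palette = c("classic", "cvd"),
                            width = 6, height = 5) {
    stopifnot(is(ci, "CIMatrix"))
    palette <- match.arg(palette)
    m <- ciValues(ci)
    if (!length(m)) stop("empty CI matrix")
    cols <- if (palette == "classic")
        c(synergistic = "#1a9641", additive = "#bdbdbd",
          antagonistic = "#d7191c", undefined = "#f7f7f7")
    else
        c(synergistic = "#0571b0", additive = "#bdbdbd",
          antagonistic = "#e66101", undefined = "#f7f7f7")
    df <- expand.grid(doseA = rownames(m), doseB = colnames(m),
                      KEEP.OUT.ATTRS = FALSE)
    df$ci <- as.vector(m)
    df$call <- factor(as.vector(ciCalls(ci)), names(cols))
    df$label <- ifelse(is.na(df$ci), "x", sprintf("%.2f", df$ci))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$doseB, y = .data$doseA,
                                          fill = .data$call)) +
        ggplot2::geom_tile(color = "white", linewidth = 0.4) +
        ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
        ggplot2::scale_fill_manual(values = cols, drop = FALSE,
                                   name = "interaction") +
        ggplot2::labs(x = "dose drug B", y = "dose drug A",
                      title = sprintf(
                          "Combination index (synergy < %.2g, antagonism > %.2g)",
                          ci@thresholds[1], ci@thresholds[2])) +
        ggplot2::theme_minimal(base_size = 11)
    ext <- tolower(tools::file_ext(path))
    dev <- switch(ext, png = grDevices::png, pdf = grDevices::pdf,
                  stop("unsupported heatmap format: ", ext))
    if (ext == "png") dev(path, width = width * 100, height = height * 100)
    else dev(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
    invisible(path)
}
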