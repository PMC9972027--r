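## Primary-screen analysis: blank/DMSO viability normalization, per-line
## z-scoring of growth inhibition across the whole library, and the
## cancer-selective hit rule (z > 2 in >= 2 cancer lines, z <= 2 in the
## normal trophoblast control line).

## Per-well viability for sample and positive-control wells:
## (od - blank mean) / (DMSO mean - blank mean), blanks pooled per plate
## and DMSO negative controls per (plate, cell line); clamped at 0.
wellViability <- function(plates, cellLines = NULL) {
    plates <- validatePlateTable(plates, cellLines)
    isBlank <- plates$role == "blank"
    isNeg <- plates$role == "negative_control"
    blankMean <- tapply(plates$od[isBlank], plates$plate_id[isBlank], mean)
    negKey <- paste(plates$plate_id, plates$cell_line, sep = "\r")
    negMean <- tapply(plates$od[isNeg], negKey[isNeg], mean)
    negN <- tapply(plates$od[isNeg], negKey[isNeg], length)
    usePlates <- unique(plates$plate_id[plates$role %in%
        c("sample", "positive_control")])
    noBlank <- setdiff(usePlates, names(blankMean))
    if (length(noBlank))
        stop("plate ", noBlank[1], " has no blank wells")
    useKeys <- unique(negKey[plates$role %in%
        c("sample", "positive_control")])
    noNeg <- setdiff(useKeys, names(negMean)[negN >= 2])
    if (length(noNeg))
        stop("plate ", sub("\r.*", "", noNeg[1]),
             " has fewer than 2 DMSO negative-control wells for line ",
             sub(".*\r", "", noNeg[1]))
    denom <- negMean[useKeys] - blankMean[sub("\r.*", "", useKeys)]
    degenerate <- useKeys[denom <= 0]
    if (length(degenerate))
        stop("degenerate plate ", sub("\r.*", "", degenerate[1]),
             ": DMSO mean does not exceed blank mean")
    keep <- plates$role %in% c("sample", "positive_control")
    out <- plates[keep, , drop = FALSE]
    key <- negKey[keep]
    v <- (out$od - blankMean[out$plate_id]) /
        (negMean[key] - blankMean[out$plate_id])
    out$viability <- pmax(0, unname(v))
    rownames(out) <- NULL
    out
}

#' Normalize plate optical densities to viability fractions
#'
#' For every sample well, viability is
#' `(od - mean(od_blank)) / (mean(od_DMSO) - mean(od_blank))` using the
#' well's own plate (blanks) and plate x cell line (DMSO negative
#' controls), clamped at 0. Requires >= 1 blank and >= 2 negative-control
#' wells per plate and line; a plate whose DMSO mean does not exceed its
#' blank mean is reported as degenerate. Replicate sample wells for the
#' same compound and line are averaged.
#'
#' @param plates long-format plate measurements (see [readPlateTable()]).
#' @param cellLines column order of the result; defaults to order of
#'   appearance.
#' @return A [ScreenMatrix-class] of kind `viability_fraction`.
#' @export
#' @examples
#' plates <- data.frame(
#'     plate_id = "P1", well = c("B1", "C1", "A12", "A1"),
#'     compound_id = c(NA, NA, NA, "cmp1"), cell_line = "JAR",
#'     dose = c(NA, NA, NA, 10),
#'     role = c("negative_control", "negative_control", "blank", "sample"),
#'     od = c(1, 1, 0, 0.5))
#' screenValues(normalizeViability(plates))
normalizeViability <- function(plates, cellLines = NULL) {
    wells <- wellViability(plates, cellLines)
    wells <- wells[wells$role == "sample", , drop = FALSE]
    if (!nrow(wells)) stop("no sample wells to normalize")
    if (is.null(cellLines)) cellLines <- unique(wells$cell_line)
    m <- tapply(wells$viability,
        list(factor(wells$compound_id, levels = sort(unique(wells$compound_id))),
             factor(wells$cell_line, levels = cellLines)),
        mean)
    ScreenMatrix(unclass(m), "viability_fraction")
}

#' Convert viability fractions to percent growth inhibition
#'
#' `inhibition = 100 * (1 - viability)`, so larger values mean stronger
#' growth inhibition.
#'
#' @param x a `ScreenMatrix` of kind `viability_fraction`.
#' @return A `ScreenMatrix` of kind `inhibition_percent`.
#' @export
asInhibition <- function(x) {
    stopifnot(is(x, "ScreenMatrix"))
    if (valueKind(x) == "inhibition_percent") return(x)
    if (valueKind(x) != "viability_fraction")
        stop("cannot convert ", valueKind(x), " to inhibition_percent")
    ScreenMatrix(100 * (1 - screenValues(x)), "inhibition_percent")
}

#' Per-cell-line z-scores of growth inhibition
#'
#' Standardizes each cell line's inhibition values against the mean and
#' sample SD (n - 1 denominator) of the whole library in that line -- the
#' usual single-point HTS convention, so positive z means stronger
#' inhibition than the library bulk.
#'
#' @param x a `ScreenMatrix` of kind `inhibition_percent` (>= 3 compounds).
#' @return A `ScreenMatrix` of kind `z_score`.
#' @export
computeZScores <- function(x) {
    stopifnot(is(x, "ScreenMatrix"))
    if (valueKind(x) != "inhibition_percent")
        stop("computeZScores expects inhibition_percent values; ",
             "see asInhibition()")
    m <- screenValues(x)
    if (nrow(m) < 3L) stop("need >= 3 compounds per line to z-score")
    if (anyNA(m)) stop("missing values in the screen matrix")
    sds <- apply(m, 2L, sd)
    zero <- colnames(m)[sds < .Machine$double.eps^0.5]
    if (length(zero))
        stop("degenerate distribution: zero inhibition variance in line ",
             zero[1])
    z <- scale(m)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    ScreenMatrix(unclass(z), "z_score")
}

#' Call cancer-selective hits from a z-score matrix
#'
#' A compound is a hit in a cancer line when its z-score strictly exceeds
#' `threshold`; it passes the control filter when its control-line z-score
#' is at most `threshold` (non-strict). A compound is *selective* when it
#' is a hit in at least `minCancerLines` cancer lines and passes the
#' control filter.
#'
#' @param z a `ScreenMatrix` of kind `z_score`.
#' @param cancerLines,controlLine disjoint line sets present in `z`.
#' @param threshold z-score cutoff (default 2).
#' @param minCancerLines minimum cancer lines hit (default 2).
#' @return An [S4Vectors::DataFrame] with one row per compound:
#'   `compound_id`, matrix columns `z` (all lines) and `hit` (cancer
#'   lines), `nCancerLinesHit`, `controlPass`, `selective`.
#' @export
callSelectiveHits <- function(z, cancerLines = cancerCellLines(),
                              controlLine = controlCellLine(),
                              threshold = 2, minCancerLines = 2L) {
    stopifnot(is(z, "ScreenMatrix"))
    if (valueKind(z) != "z_score")
        stop("callSelectiveHits expects z_score values")
    zm <- screenValues(z)
    if (!controlLine %in% colnames(zm))
        stop("configuration error: control line '", controlLine,
             "' absent from the matrix")
    missing <- setdiff(cancerLines, colnames(zm))
    if (length(missing))
        stop("configuration error: cancer line '", missing[1],
             "' absent from the matrix")
    if (controlLine %in% cancerLines)
        stop("configuration error: control line among cancer lines")
    hit <- zm[, cancerLines, drop = FALSE] > threshold
    nHit <- as.integer(rowSums(hit))
    controlPass <- zm[, controlLine] <= threshold
    DataFrame(
        compound_id = rownames(zm),
        z = I(zm), hit = I(hit),
        nCancerLinesHit = nHit,
        controlPass = unname(controlPass),
        selective = unname(nHit >= minCancerLines & controlPass),
        row.names = NULL)
}

#' Venn-region counts of per-line hits
#'
#' Counts compounds in each of the 7 non-empty regions of the three-line
#' Venn diagram of cancer-line hits, plus the total of compounds hitting
#' at least two cancer lines while passing the control filter (the
#' selective set).
#'
#' @param hits the DataFrame returned by [callSelectiveHits()] (its three
#'   cancer-line hit flags are used).
#' @return A list with `regions` (named integer vector of the 7 regions),
#'   `unionSize`, and `selectiveTotal`.
#' @export
intersectHits <- function(hits) {
    hm <- hits$hit
    if (is.null(hm) || ncol(hm) != 3L)
        stop("expected hit flags for exactly 3 cancer lines")
    lines <- colnames(hm)
    code <- hm %*% c(1L, 2L, 4L)
    combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
    regions <- vapply(combos, function(ix) {
        sum(code == sum(c(1L, 2L, 4L)[ix]))
    }, numeric(1))
    names(regions) <- vapply(combos, function(ix)
        paste(lines[ix], collapse = " & "), character(1))
    storage.mode(regions) <- "integer"
    list(regions = regions,
         unionSize = as.integer(sum(code > 0)),
         selectiveTotal = as.integer(sum(hits$selective)))
}

#' Compounds with notable inhibition in any line
#'
#' Selects compounds whose z-score exceeds `threshold` in at least one
#' cell line (the reporting heatmap subset), ordered by maximum z
#' descending with ties broken by compound id.
#'
#' @param z a `ScreenMatrix` of kind `z_score`.
#' @param threshold z cutoff (default 1).
#' @return data.frame with `compound_id`, `max_z`, `n_lines_above`.
#' @export
heatmapSubset <- function(z, threshold = 1) {
    stopifnot(is(z, "ScreenMatrix"))
    if (valueKind(z) != "z_score")
        stop("heatmapSubset expects z_score values")
    zm <- screenValues(z)
    maxZ <- apply(zm, 1L, max)
    nAbove <- as.integer(rowSums(zm > threshold))
    keep <- maxZ > threshold
    out <- data.frame(compound_id = rownames(zm)[keep],
        max_z = unname(maxZ[keep]), n_lines_above = nAbove[keep],
        stringsAsFactors = FALSE)
    out[order(-out$max_z, out$compound_id), , drop = FALSE]
}
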