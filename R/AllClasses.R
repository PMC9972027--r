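## S4 classes shared across the pipeline.

#' LibrarySpec: design of a synthetic single-point screen
#'
#' Describes the compound library and planted ground truth for the
#' synthetic primary screen: library size, numbers of planted
#' cancer-selective and pan-toxic compounds, the planted effect size
#' (in units of the well-level noise SD), the noise SD itself (on the
#' viability-fraction scale) and the RNG seed.
#'
#' @slot nCompounds library size (default 1271, a standard approved-drug
#'   collection).
#' @slot nPlantedSelective number of true cancer-selective hits.
#' @slot nPlantedPanToxic number of compounds toxic to all four lines.
#' @slot effectSizeSd planted inhibition shift, in multiples of `noiseSd`.
#' @slot noiseSd well-level Gaussian noise SD on the viability fraction.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("LibrarySpec",
    representation(
        nCompounds = "integer",
        nPlantedSelective = "integer",
        nPlantedPanToxic = "integer",
        effectSizeSd = "numeric",
        noiseSd = "numeric",
        seed = "integer"
    )
)

setValidity("LibrarySpec", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && !is.na(x)
    if (!one(object@nCompounds) || object@nCompounds < 1L)
        msg <- c(msg, "nCompounds must be a single positive integer")
    if (!one(object@nPlantedSelective) || object@nPlantedSelective < 0L)
        msg <- c(msg, "nPlantedSelective must be a non-negative integer")
    if (!one(object@nPlantedPanToxic) || object@nPlantedPanToxic < 0L)
        msg <- c(msg, "nPlantedPanToxic must be a non-negative integer")
    if (one(object@nPlantedSelective) && one(object@nPlantedPanToxic) &&
        one(object@nCompounds) &&
        object@nPlantedSelective + object@nPlantedPanToxic > object@nCompounds)
        msg <- c(msg, "planted compounds exceed nCompounds")
    if (!one(object@effectSizeSd) || object@effectSizeSd <= 0)
        msg <- c(msg, "effectSizeSd must be > 0")
    if (!one(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (!one(object@seed)) msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Construct a LibrarySpec
#'
#' @param nCompounds library size.
#' @param nPlantedSelective planted cancer-selective hits.
#' @param nPlantedPanToxic planted pan-toxic compounds.
#' @param effectSizeSd planted shift in units of the noise SD.
#' @param noiseSd well-level viability noise SD.
#' @param seed RNG seed.
#' @return A validated [LibrarySpec-class] object.
#' @export
#' @examples
#' librarySpec(nCompounds = 100, nPlantedSelective = 5, seed = 7)
librarySpec <- function(nCompounds = 1271L, nPlantedSelective = 40L,
                        nPlantedPanToxic = 10L, effectSizeSd = 3.5,
                        noiseSd = 0.1, seed = 1L) {
    new("LibrarySpec",
        nCompounds = as.integer(nCompounds),
        nPlantedSelective = as.integer(nPlantedSelective),
        nPlantedPanToxic = as.integer(nPlantedPanToxic),
        effectSizeSd = as.numeric(effectSizeSd),
        noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}

setMethod("show", "LibrarySpec", function(object) {
    cat("LibrarySpec:", object@nCompounds, "compounds |",
        object@nPlantedSelective, "selective,",
        object@nPlantedPanToxic, "pan-toxic planted |",
        "effect", object@effectSizeSd, "SD, noise SD", object@noiseSd,
        "| seed", object@seed, "\n")
})

#' GroundTruth: planted truth behind a synthetic screen
#'
#' Bookkeeping object pairing each synthetic compound with its class label
#' (`inert`, `selective_hit`, `pan_toxic`) and its true mean viability
#' fraction in every cell line, used by recovery tests.
#'
#' @slot labels named character vector, one label per compound id.
#' @slot trueViability numeric matrix, compounds x cell lines.
#' @slot cancerLines,controlLine the line partition used when planting.
#'
#' @export
setClass("GroundTruth",
    representation(
        labels = "character",
        trueViability = "matrix",
        cancerLines = "character",
        controlLine = "character"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!all(object@labels %in% c("inert", "selective_hit", "pan_toxic")))
        msg <- c(msg, "unknown truth label")
    if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
        msg <- c(msg, "labels must be uniquely named by compound id")
    if (!identical(rownames(object@trueViability), names(object@labels)))
        msg <- c(msg, "trueViability rows must match label names")
    if (!object@controlLine %in% colnames(object@trueViability) ||
        !all(object@cancerLines %in% colnames(object@trueViability)))
        msg <- c(msg, "cell-line columns must cover cancer and control lines")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    tab <- table(factor(object@labels,
        levels = c("inert", "selective_hit", "pan_toxic")))
    cat("GroundTruth:", length(object@labels), "compounds (",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        ") across", ncol(object@trueViability), "cell lines\n")
})

#' @rdname GroundTruth-class
#' @param object,x a `GroundTruth`.
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname GroundTruth-class
#' @export
setMethod("truthLabels", "GroundTruth", function(x) x@labels)

#' @rdname GroundTruth-class
#' @export
setGeneric("trueViability", function(x) standardGeneric("trueViability"))

#' @rdname GroundTruth-class
#' @export
setMethod("trueViability", "GroundTruth", function(x) x@trueViability)

.screenValueKinds <- c("viability_fraction", "inhibition_percent", "z_score")

#' ScreenMatrix: compound-by-cell-line screen values
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' holding one assay of screen values -- normalized viability fractions,
#' percent growth inhibition, or per-line z-scores -- with compounds as rows
#' and cell lines as columns. The `valueKind` slot records which of the
#' three scales the assay is on, so stage functions can refuse inputs on
#' the wrong scale.
#'
#' @slot valueKind one of `"viability_fraction"`, `"inhibition_percent"`,
#'   `"z_score"`.
#'
#' @seealso [normalizeViability()], [asInhibition()], [computeZScores()]
#' @export
setClass("ScreenMatrix",
    contains = "SummarizedExperiment",
    representation(valueKind = "character")
)

setValidity("ScreenMatrix", function(object) {
    msg <- character()
    if (length(object@valueKind) != 1L ||
        !object@valueKind %in% .screenValueKinds)
        msg <- c(msg, paste("valueKind must be one of:",
            paste(.screenValueKinds, collapse = ", ")))
    if (length(assayNames(object)) != 1L)
        msg <- c(msg, "a ScreenMatrix holds exactly one assay")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "compound ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell-line names (colnames) must be present and unique")
    if (length(msg) == 0L && object@valueKind == "viability_fraction" &&
        any(assay(object) < 0, na.rm = TRUE))
        msg <- c(msg, "viability fractions must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenMatrix
#'
#' @param values numeric matrix, compounds (rows) x cell lines (columns),
#'   with dimnames set.
#' @param valueKind scale of the values; see [ScreenMatrix-class].
#' @return A `ScreenMatrix`.
#' @export
#' @examples
#' m <- matrix(c(0.9, 0.2, 1.0, 0.95), 2, 2,
#'     dimnames = list(c("c1", "c2"), c("JAR", "HTR-8/SVneo")))
#' ScreenMatrix(m, "viability_fraction")
ScreenMatrix <- function(values, valueKind = "viability_fraction") {
    se <- SummarizedExperiment(assays = setNames(list(values), valueKind))
    new("ScreenMatrix", se, valueKind = valueKind)
}

#' @rdname ScreenMatrix-class
#' @param x,object a `ScreenMatrix`.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname ScreenMatrix-class
#' @export
setMethod("valueKind", "ScreenMatrix", function(x) x@valueKind)

#' @rdname ScreenMatrix-class
#' @export
setGeneric("screenValues", function(x) standardGeneric("screenValues"))

#' @rdname ScreenMatrix-class
#' @export
setMethod("screenValues", "ScreenMatrix", function(x) assay(x, 1L))

setMethod("show", "ScreenMatrix", function(object) {
    cat("ScreenMatrix [", object@valueKind, "]: ",
        nrow(object), " compounds x ", ncol(object), " cell lines (",
        paste(colnames(object), collapse = ", "), ")\n", sep = "")
})

#' DoseResponseFit: fitted four-parameter logistic curve
#'
#' Result of [fit4PL()]: the declining-viability 4PL
#' \eqn{v(d) = bottom + (top - bottom) / (1 + (d/IC50)^{hill})}
#' with asymptotes `bottom`/`top` (viability fractions), a positive Hill
#' slope, and the midpoint `ic50` in concentration units. Standard errors
#' come from the least-squares information matrix; the IC50 uncertainty is
#' carried on the log10 scale (slot `se["log10_ic50"]`).
#'
#' @slot bottom,top,hill,ic50 fitted parameters (NA when not converged).
#' @slot se named numeric: standard errors for bottom, top, hill and
#'   log10_ic50.
#' @slot converged logical; `FALSE` for degenerate/flat input or optimizer
#'   failure (no exception is thrown).
#' @slot residualSd residual standard deviation of the fit.
#' @slot nObs number of observations fitted.
#' @slot doseRange range of the fitted doses.
#' @slot extrapolated `TRUE` when the fitted IC50 falls outside `doseRange`.
#'
#' @export
setClass("DoseResponseFit",
    representation(
        bottom = "numeric", top = "numeric", hill = "numeric",
        ic50 = "numeric", se = "numeric", converged = "logical",
        residualSd = "numeric", nObs = "integer",
        doseRange = "numeric", extrapolated = "logical"
    )
)

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (isTRUE(object@converged)) {
        if (!(object@top > object@bottom))
            msg <- c(msg, "converged fit requires top > bottom")
        if (!(object@hill > 0))
            msg <- c(msg, "converged fit requires hill > 0")
        if (!(object@ic50 > 0))
            msg <- c(msg, "converged fit requires ic50 > 0")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname DoseResponseFit-class
#' @param x,object a `DoseResponseFit`.
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' @rdname DoseResponseFit-class
#' @export
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

#' @rdname DoseResponseFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname DoseResponseFit-class
#' @export
setMethod("isConverged", "DoseResponseFit", function(x) x@converged)

#' @rdname DoseResponseFit-class
#' @export
setMethod("coef", "DoseResponseFit", function(object)
    c(bottom = object@bottom, top = object@top,
      hill = object@hill, ic50 = object@ic50))

#' Evaluate a fitted 4PL curve
#'
#' @param object a converged `DoseResponseFit`.
#' @param doses concentrations at which to evaluate the curve.
#' @param ... unused.
#' @return Predicted viability fractions.
#' @export
setMethod("predict", "DoseResponseFit", function(object, doses, ...) {
    fourPL(doses, object@bottom, object@top, object@hill, object@ic50)
})

setMethod("show", "DoseResponseFit", function(object) {
    if (object@converged) {
        cat(sprintf(
            "DoseResponseFit: IC50 = %.4g (bottom %.3f, top %.3f, hill %.3f)\n",
            object@ic50, object@bottom, object@top, object@hill))
        cat(sprintf("  residual SD %.4g on %d observations%s\n",
            object@residualSd, object@nObs,
            if (object@extrapolated) " [IC50 extrapolated]" else ""))
    } else {
        cat("DoseResponseFit: not converged\n")
    }
})
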