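## Synthetic-data generators: every input the pipeline consumes, with
## known ground truth. The single-point screen is simulated directly on
## the normalized viability-fraction scale and mapped to optical densities
## by an invertible affine map (configurable blank and DMSO means), so the
## planted truth stays interpretable while the normalizer is exercised.

.categoryWeights <- c(
    oncology = 0.22, infectiology = 0.20, cardiovascular = 0.12,
    neuropsychiatry = 0.12, metabolism = 0.10, gastroenterology = 0.07,
    dermatology = 0.06, allergology = 0.05, other = 0.06)

#' Generate a synthetic compound library with planted ground truth
#'
#' Builds a compound annotation table (unique ids, a therapeutic-category
#' label, and semicolon-joined triage flags on a configurable subset) plus
#' the [GroundTruth-class] behind it. Planted cancer-selective hits have
#' their true mean viability lowered by `effectSizeSd * noiseSd` in a
#' randomly chosen subset of 2-3 of the 3 cancer lines (subset size drawn
#' uniformly from {2, 3}); pan-toxic compounds are lowered in all four
#' lines; inert compounds sit at viability 1 everywhere.
#'
#' @param spec a [LibrarySpec-class].
#' @param nTopoisomerase,nCardiacGlycoside numbers of compounds to tag with
#'   the `topoisomerase_class` / `cardiac_glycoside_class` triage flags
#'   (drawn from the planted selective hits first, so triage has hits to
#'   act on).
#' @param cancerLines,controlLine cell-line panel.
#' @return A list with elements `annotations` (data.frame: `compound_id`,
#'   `name`, `category`, `flags`) and `truth` (a `GroundTruth`).
#' @export
#' @examples
#' lib <- generateLibrary(librarySpec(nCompounds = 50, nPlantedSelective = 3,
#'     nPlantedPanToxic = 1, seed = 11))
#' table(truthLabels(lib$truth))
generateLibrary <- function(spec, nTopoisomerase = 0L, nCardiacGlycoside = 0L,
                            cancerLines = cancerCellLines(),
                            controlLine = controlCellLine()) {
    stopifnot(is(spec, "LibrarySpec"))
    validObject(spec)
    if (nTopoisomerase < 0L || nCardiacGlycoside < 0L)
        stop("flag counts must be non-negative")
    n <- spec@nCompounds
    lines <- c(cancerLines, controlLine)
    ids <- sprintf("CMP%05d", seq_len(n))
    withSeed(spec@seed, {
        category <- sample(names(.categoryWeights), n, replace = TRUE,
            prob = .categoryWeights)
        labels <- rep("inert", n)
        planted <- sample.int(n, spec@nPlantedSelective + spec@nPlantedPanToxic)
        sel <- planted[seq_len(spec@nPlantedSelective)]
        pan <- setdiff(planted, sel)
        labels[sel] <- "selective_hit"
        labels[pan] <- "pan_toxic"
        effect <- spec@effectSizeSd * spec@noiseSd
        viab <- matrix(1, n, length(lines), dimnames = list(ids, lines))
        for (i in sel) {
            k <- sample(2:3, 1L)
            hitLines <- sample(cancerLines, k)
            viab[i, hitLines] <- 1 - effect
        }
        viab[pan, ] <- 1 - effect
        flags <- rep("", n)
        flagPool <- c(sel, setdiff(seq_len(n), sel))
        nFlag <- nTopoisomerase + nCardiacGlycoside
        if (nFlag > n) stop("more flags requested than compounds")
        take <- flagPool[seq_len(nFlag)]
        flags[take[seq_len(nTopoisomerase)]] <- "topoisomerase_class"
        if (nCardiacGlycoside > 0L)
            flags[take[nTopoisomerase + seq_len(nCardiacGlycoside)]] <-
                "cardiac_glycoside_class"
    })
    names(labels) <- ids
    annotations <- data.frame(
        compound_id = ids,
        name = sprintf("drug-%05d", seq_len(n)),
        category = category,
        flags = flags,
        stringsAsFactors = FALSE)
    truth <- new("GroundTruth", labels = labels, trueViability = viab,
        cancerLines = cancerLines, controlLine = controlLine)
    list(annotations = annotations, truth = truth)
}

#' Simulate the single-point primary screen as plate-reader tables
#'
#' Lays the library out on 96-well plates (one cell line per plate; column
#' 1 holds DMSO negative controls, column 12 blanks, columns 2-11 the
#' compounds at 10 uM) and emits one long-format optical-density row per
#' well. Sample and DMSO viabilities are drawn from
#' `Normal(true mean, noiseSd)` truncated at 0, then mapped to OD by
#' `od = odBlank + viability * (odDmso - odBlank)`; blank wells sit at
#' `odBlank` exactly.
#'
#' @param truth a [GroundTruth-class] from [generateLibrary()].
#' @param spec the [LibrarySpec-class] used to generate `truth`.
#' @param noiseSd well-level noise SD; defaults to `spec`'s value. Pass 0
#'   to obtain the noiseless limit (the planted shifts, which were sized
#'   from `spec`'s noise SD, are retained).
#' @param odBlank,odDmso affine map from viability fractions to OD.
#' @param dose screen concentration in uM.
#' @param controlWells,blankWells control/blank wells per plate (>= 2
#'   negative controls and >= 1 blank are required downstream).
#' @param seed RNG seed; defaults to a child of `spec`'s seed.
#' @return A data.frame of plate measurements with columns `plate_id`,
#'   `well`, `compound_id`, `cell_line`, `dose`, `role`, `od`.
#' @export
#' @examples
#' lib <- generateLibrary(librarySpec(nCompounds = 20, seed = 3,
#'     nPlantedSelective = 2, nPlantedPanToxic = 0))
#' plates <- simulatePrimaryPlates(lib$truth, librarySpec(nCompounds = 20,
#'     seed = 3, nPlantedSelective = 2, nPlantedPanToxic = 0))
#' head(plates)
simulatePrimaryPlates <- function(truth, spec, noiseSd = spec@noiseSd,
                                  odBlank = 0.05, odDmso = 1.0, dose = 10,
                                  controlWells = 8L, blankWells = 8L,
                                  seed = childSeed(spec@seed, 1L)) {
    stopifnot(is(truth, "GroundTruth"), is(spec, "LibrarySpec"))
    validObject(truth)
    if (controlWells < 2L || controlWells > 8L)
        stop("configuration error: need 2-8 negative-control wells per plate")
    if (blankWells < 1L || blankWells > 8L)
        stop("configuration error: need 1-8 blank wells per plate")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (odDmso <= odBlank) stop("odDmso must exceed odBlank")
    ids <- rownames(truth@trueViability)
    lines <- colnames(truth@trueViability)
    n <- length(ids)
    perPlate <- 80L                     # columns 2-11 x rows A-H
    plateOf <- (seq_len(n) - 1L) %/% perPlate + 1L
    within <- (seq_len(n) - 1L) %% perPlate
    sampleWell <- paste0(LETTERS[within %% 8L + 1L], 2L + within %/% 8L)
    nPlates <- max(plateOf)
    withSeed(seed, {
        out <- lapply(lines, function(ln) {
            plateIds <- sprintf("%s-P%02d", gsub("[^A-Za-z0-9]", "", ln),
                plateOf)
            v <- pmax(0, rnorm(n, truth@trueViability[, ln], noiseSd))
            samples <- data.frame(
                plate_id = plateIds, well = sampleWell, compound_id = ids,
                cell_line = ln, dose = dose, role = "sample",
                od = odBlank + v * (odDmso - odBlank),
                stringsAsFactors = FALSE)
            uPlates <- sprintf("%s-P%02d", gsub("[^A-Za-z0-9]", "", ln),
                seq_len(nPlates))
            nNeg <- nPlates * controlWells
            vNeg <- pmax(0, rnorm(nNeg, 1, noiseSd))
            negs <- data.frame(
                plate_id = rep(uPlates, each = controlWells),
                well = paste0(LETTERS[seq_len(controlWells)], 1L),
                compound_id = NA_character_, cell_line = ln,
                dose = NA_real_, role = "negative_control",
                od = odBlank + vNeg * (odDmso - odBlank),
                stringsAsFactors = FALSE)
            blanks <- data.frame(
                plate_id = rep(uPlates, each = blankWells),
                well = paste0(LETTERS[seq_len(blankWells)], 12L),
                compound_id = NA_character_, cell_line = ln,
                dose = NA_real_, role = "blank", od = odBlank,
                stringsAsFactors = FALSE)
            rbind(samples, negs, blanks)
        })
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Four-parameter logistic curve
#'
#' The declining-viability parameterization
#' \eqn{v(d) = bottom + (top - bottom) / (1 + (d/ic50)^{hill})}:
#' viability tends to `top` as the dose tends to 0 and to `bottom` at
#' saturating dose; at `d = ic50` it is exactly `(top + bottom) / 2`.
#'
#' @param dose concentration(s), same units as `ic50`.
#' @param bottom,top lower/upper viability asymptotes.
#' @param hill Hill slope (> 0).
#' @param ic50 curve midpoint.
#' @return Viability fraction(s).
#' @export
#' @examples
#' fourPL(c(0.1, 1, 10), bottom = 0, top = 1, hill = 1, ic50 = 1)
fourPL <- function(dose, bottom, top, hill, ic50) {
    bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Simulate a replicated dose-response experiment
#'
#' Draws viability readings from a true 4PL curve plus Gaussian noise,
#' truncated to `[0, 1.2 * max(top, bottom)]` (optical densities below
#' blank are physically noise). Default design: 8 log-spaced doses
#' spanning 0.01-100 uM in triplicate.
#'
#' @param ic50,bottom,top,hill true curve parameters (see [fourPL()]).
#' @param doses dose grid in uM (strictly positive).
#' @param replicates replicate wells per dose (>= 1).
#' @param noiseSd Gaussian noise SD on the viability scale.
#' @param seed RNG seed.
#' @return data.frame with columns `dose`, `replicate`, `viability`.
#' @export
#' @examples
#' dr <- simulateDoseResponse(ic50 = 1.16, seed = 2)
#' fit4PL(dr$dose, dr$viability)
simulateDoseResponse <- function(ic50, bottom = 0, top = 1, hill = 1,
                                 doses = 10^seq(log10(0.01), log10(100),
                                     length.out = 8L),
                                 replicates = 3L, noiseSd = 0.05, seed = 1L) {
    if (any(doses <= 0)) stop("doses must be strictly positive")
    if (replicates < 1L) stop("replicates must be >= 1")
    if (ic50 <= 0) stop("ic50 must be > 0")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    d <- rep(doses, each = replicates)
    mu <- fourPL(d, bottom, top, hill, ic50)
    withSeed(seed, v <- mu + rnorm(length(d), 0, noiseSd))
    v <- pmin(pmax(v, 0), 1.2 * max(top, bottom))
    data.frame(dose = d, replicate = rep(seq_len(replicates), length(doses)),
        viability = v)
}

#' Simulate xenograft tumor growth under treatment
#'
#' Per-animal log-linear growth of true volume with multiplicative
#' log-normal measurement noise; the treated arm's growth rate is reduced
#' by `effect` (0 = null, 1 = complete growth suppression). Caliper
#' (length, width) pairs are emitted so that the modified ellipsoid
#' formula `length * width^2 * 0.5` recovers the simulated volume exactly.
#'
#' @param nPerArm animals per arm (>= 1).
#' @param days measurement days.
#' @param baselineVolume starting volume, mm^3.
#' @param growthRate vehicle-arm exponential growth rate per day.
#' @param effect fractional growth-rate reduction in the treated arm.
#' @param noiseSd SD of the log-scale measurement noise.
#' @param aspectRatio tumor length/width ratio used to derive calipers.
#' @param seed RNG seed.
#' @return data.frame with columns `animal_id`, `arm`, `day`, `length_mm`,
#'   `width_mm`.
#' @export
#' @examples
#' g <- simulateTumorGrowth(nPerArm = 5, seed = 4)
#' head(growthCurveAnalysis(g))
simulateTumorGrowth <- function(nPerArm = 5L, days = seq(0, 14, by = 2),
                                baselineVolume = 100, growthRate = 0.18,
                                effect = 0.6, noiseSd = 0.15,
                                aspectRatio = 1.4, seed = 1L) {
    if (nPerArm < 1L) stop("nPerArm must be >= 1")
    if (effect < 0 || effect > 1) stop("effect must be in [0, 1]")
    if (baselineVolume <= 0 || aspectRatio < 1)
        stop("baselineVolume must be > 0 and aspectRatio >= 1")
    arms <- c(vehicle = growthRate, treated = growthRate * (1 - effect))
    withSeed(seed, {
        rows <- lapply(names(arms), function(arm) {
            grid <- expand.grid(animal = seq_len(nPerArm), day = days)
            vol <- baselineVolume * exp(arms[[arm]] * grid$day) *
                exp(rnorm(nrow(grid), 0, noiseSd))
            width <- (2 * vol / aspectRatio)^(1 / 3)
            data.frame(
                animal_id = sprintf("%s-%02d", arm, grid$animal),
                arm = arm, day = grid$day,
                length_mm = aspectRatio * width, width_mm = width,
                stringsAsFactors = FALSE)
        })
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out[order(out$arm, out$animal_id, out$day), , drop = FALSE]
}

#' Simulate a qPCR Ct panel for a treatment contrast
#'
#' Reference-gene Cts are centred identically in both conditions; each
#' target gene's treated-condition Ct is shifted by `-log2(foldChange)`
#' cycles relative to control (a halving of expression costs one extra
#' cycle). Gaussian cycle noise is added to every well.
#'
#' @param genes target gene names.
#' @param foldChanges true treated/control expression fold change per gene
#'   (recycled; must be > 0).
#' @param replicates replicates per gene and condition.
#' @param ctNoiseSd per-well Ct noise SD, cycles.
#' @param referenceGene housekeeping gene name.
#' @param baselineCt,referenceCt control-condition mean Cts for targets and
#'   the reference gene.
#' @param seed RNG seed.
#' @return data.frame with columns `sample_id`, `condition`, `gene`,
#'   `replicate`, `ct`.
#' @export
#' @examples
#' ct <- simulateCtPanel(c("GPX4", "NRF2"), foldChanges = c(0.4, 0.5),
#'     seed = 5)
#' ddctFoldChange(ct, "GPX4")
simulateCtPanel <- function(genes, foldChanges = 0.5, replicates = 3L,
                            ctNoiseSd = 0.15, referenceGene = "GAPDH",
                            baselineCt = 24, referenceCt = 18, seed = 1L) {
    if (any(foldChanges <= 0)) stop("fold changes must be > 0")
    if (replicates < 1L) stop("replicates must be >= 1")
    fc <- rep_len(foldChanges, length(genes))
    conditions <- c("control", "treated")
    grid <- expand.grid(replicate = seq_len(replicates),
        gene = c(genes, referenceGene), condition = conditions,
        stringsAsFactors = FALSE)
    mu <- ifelse(grid$gene == referenceGene, referenceCt,
        baselineCt - ifelse(grid$condition == "treated",
            log2(fc[match(grid$gene, genes)]), 0))
    withSeed(seed, ct <- mu + rnorm(nrow(grid), 0, ctNoiseSd))
    data.frame(
        sample_id = sprintf("%s-%d", grid$condition, grid$replicate),
        condition = grid$condition, gene = grid$gene,
        replicate = grid$replicate, ct = ct,
        stringsAsFactors = FALSE)
}
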