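## Downstream quantifications: delta-delta-Ct relative expression, the
## modified ellipsoid tumor volume with per-timepoint growth-curve
## comparison, and immunohistochemistry positive-fraction statistics.
## Group comparisons use the classical equal-variance Student's t-test
## (Welch available behind a flag), significance called at p < 0.05.

#' Relative expression by the delta-delta-Ct (Livak) method
#'
#' Per condition, `dCt = mean ct(target) - mean ct(reference)`; the
#' contrast is `ddCt = dCt(treated) - dCt(control)` and the fold change
#' `2^(-ddCt)` (amplification efficiency fixed at 2, i.e. no efficiency
#' correction). Replicate spread is propagated to a standard error on the
#' log2 fold change by summing the squared SEMs of the four per-gene,
#' per-condition means.
#'
#' @param ct Ct table with columns `condition` (`control`/`treated`),
#'   `gene`, `ct` (cycles, > 0), and optionally `replicate`/`sample_id`.
#' @param targetGene gene to quantify.
#' @param referenceGene housekeeping gene (default GAPDH).
#' @return One-row data.frame: `target`, `reference`, `dct_control`,
#'   `dct_treated`, `ddct`, `fold_change`, `log2_fold_change`,
#'   `se_log2_fold`.
#' @export
#' @examples
#' ct <- simulateCtPanel("GPX4", foldChanges = 0.5, ctNoiseSd = 0, seed = 1)
#' ddctFoldChange(ct, "GPX4")$fold_change   # exactly 0.5
ddctFoldChange <- function(ct, targetGene, referenceGene = "GAPDH") {
    need <- c("condition", "gene", "ct")
    missing <- setdiff(need, names(ct))
    if (length(missing))
        stop("Ct table missing columns: ", paste(missing, collapse = ", "))
    if (any(is.na(ct$ct)) || any(ct$ct <= 0))
        stop("Ct values must be positive and non-missing")
    conditions <- c("control", "treated")
    if (!all(conditions %in% ct$condition))
        stop("need both control and treated conditions")
    cellStats <- function(gene, condition) {
        x <- ct$ct[ct$gene == gene & ct$condition == condition]
        if (!length(x))
            stop("gene ", gene, " not measured in condition ", condition)
        c(mean = mean(x),
          sem2 = if (length(x) > 1L) var(x) / length(x) else NA_real_)
    }
    tC <- cellStats(targetGene, "control"); tT <- cellStats(targetGene, "treated")
    rC <- cellStats(referenceGene, "control"); rT <- cellStats(referenceGene, "treated")
    dctC <- tC[["mean"]] - rC[["mean"]]
    dctT <- tT[["mean"]] - rT[["mean"]]
    ddct <- dctT - dctC
    seLog2 <- sqrt(tC[["sem2"]] + tT[["sem2"]] + rC[["sem2"]] + rT[["sem2"]])
    data.frame(target = targetGene, reference = referenceGene,
        dct_control = dctC, dct_treated = dctT, ddct = ddct,
        fold_change = 2^(-ddct), log2_fold_change = -ddct,
        se_log2_fold = seLog2, stringsAsFactors = FALSE)
}

#' Tumor volume by the modified ellipsoid formula
#'
#' `volume = length * width^2 * 0.5`, with the caliper pair canonicalized
#' first (length = the larger dimension) because field recordings swap
#' axes and the formula is orientation-sensitive.
#'
#' @param length,width caliper dimensions in mm (> 0; vectorized).
#' @return Volume(s) in mm^3.
#' @export
#' @examples
#' tumorVolume(10, 5)   # 125
#' tumorVolume(5, 10)   # canonicalized: also 125
tumorVolume <- function(length, width) {
    if (any(is.na(length)) || any(is.na(width)) ||
        any(length <= 0) || any(width <= 0))
        stop("caliper dimensions must be positive")
    L <- pmax(length, width)
    W <- pmin(length, width)
    L * W^2 * 0.5
}

.significanceTier <- function(p) {
    ifelse(is.na(p), NA_character_,
        ifelse(p < 0.001, "***",
        ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

#' Two-sample comparison by Student's t-test
#'
#' Classical pooled-variance two-sided t-test (the package-wide default);
#' `welch = TRUE` switches to the unequal-variance form. Significance is
#' labelled at p < 0.05 with the usual `*`/`**`/`***` tiers.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @param welch use Welch's correction instead of the pooled variance.
#' @return One-row data.frame: `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `significant`, `tier`.
#' @export
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))
compareGroups <- function(a, b, welch = FALSE) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("need >= 2 observations per group")
    if (!welch && var(a) + var(b) == 0)
        stop("degenerate variance: both groups are constant")
    ht <- t.test(a, b, var.equal = !welch)
    p <- ht$p.value
    data.frame(mean_a = mean(a), mean_b = mean(b),
        t = unname(ht$statistic), df = unname(ht$parameter), p = p,
        significant = p < 0.05, tier = .significanceTier(p),
        stringsAsFactors = FALSE)
}

#' Per-timepoint growth-curve comparison between two arms
#'
#' Computes every animal's tumor volume via [tumorVolume()], then for each
#' measurement day reports the per-arm mean and SEM and the two-arm
#' Student's t-test with significance tiers. Timepoints are treated as
#' opaque ordered labels; no multiplicity correction is applied across
#' days (set `adjust = "holm"` to turn it on).
#'
#' @param records growth table with columns `animal_id`, `arm` (exactly
#'   two levels), `day`, `length_mm`, `width_mm`.
#' @param adjust p-value adjustment across timepoints (`"none"` or any
#'   [stats::p.adjust] method).
#' @param welch passed to [compareGroups()].
#' @return data.frame with one row per day: per-arm n/mean/SEM, `t`, `p`,
#'   `tier`.
#' @export
growthCurveAnalysis <- function(records, adjust = "none", welch = FALSE) {
    need <- c("animal_id", "arm", "day", "length_mm", "width_mm")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("growth table missing columns: ",
             paste(missing, collapse = ", "))
    arms <- sort(unique(records$arm))
    if (length(arms) != 2L)
        stop("need exactly two arms to compare, got ", length(arms))
    records$volume <- tumorVolume(records$length_mm, records$width_mm)
    days <- sort(unique(records$day))
    rows <- lapply(days, function(d) {
        a <- records$volume[records$day == d & records$arm == arms[1]]
        b <- records$volume[records$day == d & records$arm == arms[2]]
        cmp <- tryCatch(compareGroups(a, b, welch = welch),
            error = function(e) data.frame(mean_a = mean(a), mean_b = mean(b),
                t = NA_real_, df = NA_real_, p = NA_real_,
                significant = NA, tier = NA_character_))
        data.frame(day = d,
            n_a = length(a), mean_a = cmp$mean_a,
            sem_a = if (length(a) > 1) sd(a) / sqrt(length(a)) else NA_real_,
            n_b = length(b), mean_b = cmp$mean_b,
            sem_b = if (length(b) > 1) sd(b) / sqrt(length(b)) else NA_real_,
            t = cmp$t, p = cmp$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out) <- sub("_a$", paste0("_", arms[1]), names(out))
    names(out) <- sub("_b$", paste0("_", arms[2]), names(out))
    if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
    out$significant <- out$p < 0.05
    out$tier <- .significanceTier(out$p)
    out
}

#' Compare immunohistochemistry positive fractions between arms
#'
#' Per marker, reports each arm's mean positive fraction with SEM over
#' animals and the two-arm Student's t-test.
#'
#' @param fractions table with columns `animal_id`, `arm` (two levels),
#'   `marker`, `fraction` (in `[0, 1]`).
#' @param marker optional subset of markers (default: all present).
#' @param welch passed to [compareGroups()].
#' @return data.frame with one row per marker: per-arm n/mean/SEM, `t`,
#'   `p`, `significant`, `tier`.
#' @export
comparePositiveFractions <- function(fractions, marker = NULL,
                                     welch = FALSE) {
    need <- c("animal_id", "arm", "marker", "fraction")
    missing <- setdiff(need, names(fractions))
    if (length(missing))
        stop("fraction table missing columns: ",
             paste(missing, collapse = ", "))
    if (any(is.na(fractions$fraction)) || any(fractions$fraction < 0) ||
        any(fractions$fraction > 1))
        stop("fractions must lie in [0, 1]")
    arms <- sort(unique(fractions$arm))
    if (length(arms) != 2L)
        stop("need exactly two arms to compare, got ", length(arms))
    markers <- if (is.null(marker)) unique(fractions$marker) else marker
    rows <- lapply(markers, function(mk) {
        sub <- fractions[fractions$marker == mk, , drop = FALSE]
        if (!nrow(sub)) stop("no rows for marker ", mk)
        a <- sub$fraction[sub$arm == arms[1]]
        b <- sub$fraction[sub$arm == arms[2]]
        cmp <- compareGroups(a, b, welch = welch)
        data.frame(marker = mk,
            n_a = length(a), mean_a = cmp$mean_a,
            sem_a = sd(a) / sqrt(length(a)),
            n_b = length(b), mean_b = cmp$mean_b,
            sem_b = sd(b) / sqrt(length(b)),
            t = cmp$t, p = cmp$p, significant = cmp$significant,
            tier = cmp$tier, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out) <- sub("_a$", paste0("_", arms[1]), names(out))
    names(out) <- sub("_b$", paste0("_", arms[2]), names(out))
    out
}
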