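## Secondary screen: triplicate confirmation of primary hits against a
## cisplatin positive control, and concentration dependence via 4PL
## dose-response fitting with multistart Levenberg-Marquardt least squares.

#' Summarize a replicated secondary screen against cisplatin
#'
#' Normalizes wells per [normalizeViability()] rules, then reports each
#' listed compound's per-line replicate mean and SEM of percent growth
#' inhibition. A compound is superior to the positive control when its
#' mean inhibition, averaged (unweighted) over the cancer lines, strictly
#' exceeds the same statistic for the cisplatin positive-control wells;
#' set `perLine = TRUE` to require superiority in every cancer line
#' instead.
#'
#' @param plates long-format plate measurements; cisplatin wells carry
#'   `role = "positive_control"`.
#' @param hitIds compound ids to summarize (each needs >= 2 replicates per
#'   cancer line).
#' @param cancerLines cancer lines entering the comparison.
#' @param perLine use the per-line rather than the averaged superiority
#'   criterion.
#' @return A list with `byLine` (compound x line means/SEMs/replicate
#'   counts), `positiveControl` (cisplatin per-line summary) and
#'   `verdicts` (`superior_to_positive_control` per compound).
#' @export
summarizeSecondary <- function(plates, hitIds,
                               cancerLines = cancerCellLines(),
                               perLine = FALSE) {
    wells <- wellViability(plates)
    pos <- wells[wells$role == "positive_control" &
                 wells$cell_line %in% cancerLines, , drop = FALSE]
    if (!nrow(pos))
        stop("configuration error: no cisplatin positive-control wells")
    missingPos <- setdiff(cancerLines, unique(pos$cell_line))
    if (length(missingPos))
        stop("configuration error: no cisplatin wells for line ",
             missingPos[1])
    smp <- wells[wells$role == "sample" &
                 wells$compound_id %in% hitIds &
                 wells$cell_line %in% cancerLines, , drop = FALSE]
    absent <- setdiff(hitIds, unique(smp$compound_id))
    if (length(absent))
        stop("no secondary-screen wells for compound ", absent[1])
    smp$inhibition <- 100 * (1 - smp$viability)
    pos$inhibition <- 100 * (1 - pos$viability)
    agg <- function(df, by) {
        n <- tapply(df$inhibition, by, length)
        mu <- tapply(df$inhibition, by, mean)
        sem <- tapply(df$inhibition, by, function(x)
            if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_)
        data.frame(key = names(mu), mean_inhibition = unname(mu),
            sem_inhibition = unname(sem), n_replicates = unname(as.integer(n)),
            stringsAsFactors = FALSE)
    }
    key <- paste(smp$compound_id, smp$cell_line, sep = "\r")
    byLine <- agg(smp, key)
    byLine$compound_id <- sub("\r.*", "", byLine$key)
    byLine$cell_line <- sub(".*\r", "", byLine$key)
    byLine$key <- NULL
    byLine <- byLine[, c("compound_id", "cell_line", "mean_inhibition",
        "sem_inhibition", "n_replicates")]
    few <- byLine[byLine$n_replicates < 2L, , drop = FALSE]
    if (nrow(few))
        stop("compound ", few$compound_id[1], " has < 2 replicates in line ",
             few$cell_line[1])
    missingLine <- setdiff(
        as.vector(outer(hitIds, cancerLines, paste, sep = "\r")),
        paste(byLine$compound_id, byLine$cell_line, sep = "\r"))
    if (length(missingLine))
        stop("compound ", sub("\r.*", "", missingLine[1]),
             " has no wells in line ", sub(".*\r", "", missingLine[1]))
    posSummary <- agg(pos, pos$cell_line)
    names(posSummary)[1] <- "cell_line"
    posByLine <- setNames(posSummary$mean_inhibition, posSummary$cell_line)
    cmpMeans <- tapply(byLine$mean_inhibition, byLine$compound_id, mean)
    if (perLine) {
        sup <- vapply(names(cmpMeans), function(cid) {
            b <- byLine[byLine$compound_id == cid, ]
            all(b$mean_inhibition > posByLine[b$cell_line])
        }, logical(1))
    } else {
        posOverall <- mean(posByLine[cancerLines])
        sup <- cmpMeans > posOverall
    }
    verdicts <- data.frame(
        compound_id = names(cmpMeans),
        mean_inhibition_cancer = unname(cmpMeans),
        positive_control_inhibition = mean(posByLine[cancerLines]),
        superior_to_positive_control = unname(sup),
        stringsAsFactors = FALSE)
    rownames(verdicts) <- NULL
    list(byLine = byLine, positiveControl = posSummary, verdicts = verdicts)
}

## Single nlsLM attempt for the 4PL on log10-dose; returns NULL on failure.
.try4PL <- function(logd, y, start, lower, upper) {
    fit <- try(suppressWarnings(nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (logd - logIc50))),
        data = data.frame(logd = logd, y = y),
        start = start, lower = lower, upper = upper,
        control = nls.lm.control(maxiter = 300))), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [fourPL()] on log10-dose with viability as the
#' response, constrained to `bottom >= 0`, `top <= 1.2` (tolerating
#' super-control noise) and `hill > 0`. Initialization is multistart: the
#' midpoint is started at every observed dose (and the grid centre), the
#' Hill slope at 0.5/1/2, and the asymptotes at the extreme-dose means;
#' the lowest-deviance successful fit wins. The reported IC50 is the
#' relative EC50 (curve midpoint). Optimizer failure or an unresolvable
#' curve (fitted window `top - bottom` below 0.1 viability units, e.g. a
#' flat curve) yields `converged = FALSE` rather than an error.
#'
#' @param dose dose vector (uM, strictly positive), or a data.frame with
#'   columns `dose` and `viability`.
#' @param viability viability fractions (ignored when `dose` is a
#'   data.frame).
#' @return A [DoseResponseFit-class].
#' @export
#' @examples
#' dr <- simulateDoseResponse(ic50 = 0.96, seed = 8)
#' fit <- fit4PL(dr)
#' ic50(fit)
fit4PL <- function(dose, viability = NULL) {
    if (is.data.frame(dose)) {
        viability <- dose$viability
        dose <- dose$dose
    }
    if (any(is.na(dose)) || any(is.na(viability)))
        stop("missing values in dose-response data")
    if (any(dose <= 0)) stop("doses must be strictly positive")
    if (length(dose) != length(viability))
        stop("dose and viability lengths differ")
    uDoses <- sort(unique(dose))
    if (length(uDoses) < 4L)
        stop("insufficient data: need >= 4 distinct doses")
    logd <- log10(dose)
    dr <- range(uDoses)
    failed <- new("DoseResponseFit",
        bottom = NA_real_, top = NA_real_, hill = NA_real_, ic50 = NA_real_,
        se = c(bottom = NA_real_, top = NA_real_, hill = NA_real_,
               log10_ic50 = NA_real_),
        converged = FALSE, residualSd = NA_real_,
        nObs = length(dose), doseRange = dr, extrapolated = FALSE)
    if (diff(range(viability)) < 1e-10) return(failed)
    topInit <- min(max(mean(viability[dose == uDoses[1]]), 0), 1.2)
    botInit <- min(max(mean(viability[dose == uDoses[length(uDoses)]]), 0), 1.2)
    if (topInit <= botInit) { topInit <- max(viability); botInit <- min(viability) }
    lower <- c(bottom = 0, top = 0, hill = 1e-3, logIc50 = min(logd) - 2)
    upper <- c(bottom = 1.2, top = 1.2, hill = 10, logIc50 = max(logd) + 2)
    best <- NULL
    for (li in c(log10(uDoses), mean(range(logd)))) {
        for (h0 in c(0.5, 1, 2)) {
            start <- list(bottom = botInit, top = topInit, hill = h0,
                logIc50 = li)
            fit <- .try4PL(logd, viability, start, lower, upper)
            if (is.null(fit)) next
            dv <- sum(resid(fit)^2)
            if (is.null(best) || dv < best$dv - 1e-12)
                best <- list(dv = dv, fit = fit)
        }
    }
    if (is.null(best)) return(failed)
    co <- coef(best$fit)
    se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
        error = function(e) rep(NA_real_, 4L))
    names(se) <- names(co)
    n <- length(dose)
    residSd <- sqrt(best$dv / max(n - 4L, 1L))
    est <- c(bottom = unname(co[["bottom"]]), top = unname(co[["top"]]),
        hill = unname(co[["hill"]]), ic50 = unname(10^co[["logIc50"]]))
    ok <- (est[["top"]] - est[["bottom"]] > 0.1) && est[["hill"]] > 0 &&
        all(is.finite(se))
    if (!ok) return(failed)
    fitted <- new("DoseResponseFit",
        bottom = est[["bottom"]], top = est[["top"]],
        hill = est[["hill"]], ic50 = est[["ic50"]],
        se = c(bottom = unname(se[["bottom"]]), top = unname(se[["top"]]),
               hill = unname(se[["hill"]]),
               log10_ic50 = unname(se[["logIc50"]])),
        converged = TRUE, residualSd = residSd, nObs = n, doseRange = dr,
        extrapolated = !(est[["ic50"]] >= dr[1] && est[["ic50"]] <= dr[2]))
    validObject(fitted)
    fitted
}

#' Wald confidence interval for a fitted IC50
#'
#' Interval on log10(IC50) using the least-squares standard error and a
#' t quantile with `nObs - 4` degrees of freedom, back-transformed to the
#' concentration scale.
#'
#' @param fit a converged [DoseResponseFit-class].
#' @param level confidence level (default 0.95).
#' @return Named numeric: `lower`, `estimate`, `upper`.
#' @export
ic50WithCI <- function(fit, level = 0.95) {
    stopifnot(is(fit, "DoseResponseFit"))
    if (!isConverged(fit)) stop("confidence interval requires a converged fit")
    if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
    se <- fit@se[["log10_ic50"]]
    df <- max(fit@nObs - 4L, 1L)
    q <- qt(1 - (1 - level) / 2, df)
    l10 <- log10(fit@ic50)
    c(lower = 10^(l10 - q * se), estimate = fit@ic50,
      upper = 10^(l10 + q * se))
}
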