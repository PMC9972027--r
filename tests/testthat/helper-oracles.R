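# Independent oracles and small fixture builders used across tests.

# Exhaustive re-evaluation of the selective-hit rule, written directly from
# the rule text (z from per-line mean/sample-SD; strict > for cancer lines,
# non-strict <= for the control line), independent of callSelectiveHits().
oracleSelectiveCalls <- function(inhib, cancerLines, controlLine,
                                 threshold = 2, minCancerLines = 2) {
    vapply(rownames(inhib), function(cid) {
        nHit <- 0L
        for (ln in cancerLines) {
            col <- inhib[, ln]
            zz <- (inhib[cid, ln] - mean(col)) / sd(col)
            if (zz > threshold) nHit <- nHit + 1L
        }
        colc <- inhib[, controlLine]
        zc <- (inhib[cid, controlLine] - mean(colc)) / sd(colc)
        nHit >= minCancerLines && zc <= threshold
    }, logical(1))
}

# Textbook pooled-variance two-sample t-test.
oraclePooledT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# One-plate fixture: 2 DMSO wells at odDmso, 1 blank at odBlank, then one
# sample well per (compound, od) pair, all on a single cell line.
makePlate <- function(sampleOds, compoundIds = sprintf("c%02d",
                          seq_along(sampleOds)),
                      cellLine = "JAR", plateId = "P1",
                      odDmso = 1, odBlank = 0) {
    wells <- paste0(LETTERS[seq_along(sampleOds) %% 8 + 1],
        2 + (seq_along(sampleOds) - 1) %/% 8)
    rbind(
        data.frame(plate_id = plateId, well = c("A1", "B1"),
            compound_id = NA_character_, cell_line = cellLine,
            dose = NA_real_, role = "negative_control", od = odDmso),
        data.frame(plate_id = plateId, well = "A12",
            compound_id = NA_character_, cell_line = cellLine,
            dose = NA_real_, role = "blank", od = odBlank),
        data.frame(plate_id = plateId, well = wells,
            compound_id = compoundIds, cell_line = cellLine,
            dose = 10, role = "sample", od = sampleOds))
}

# Multi-line screen fixture: same compounds on one plate per line, sample
# ODs supplied as a compounds x lines matrix (blank 0 / DMSO 1 so that
# od = viability).
makeScreenPlates <- function(odMatrix) {
    do.call(rbind, lapply(colnames(odMatrix), function(ln)
        makePlate(odMatrix[, ln], compoundIds = rownames(odMatrix),
            cellLine = ln, plateId = paste0(gsub("[^A-Za-z0-9]", "", ln),
                "-P1"))))
}

# z-score ScreenMatrix straight from a named z matrix (for rule tests).
zMatrixOf <- function(zm) {
    sm <- ScreenMatrix(zm, "z_score")
    sm
}
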