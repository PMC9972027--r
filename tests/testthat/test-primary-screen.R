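test_that("normalizeViability interpolates between blank and DMSO means", {
    plate <- makePlate(c(0.5, 1.0, -0.0), compoundIds = c("c1", "c2", "c3"),
        odDmso = 1, odBlank = 0)
    plate$od[plate$role == "sample"] <- c(0.5, 1.0, 0)
    sm <- normalizeViability(plate)
    v <- screenValues(sm)
    expect_s4_class(sm, "ScreenMatrix")
    expect_equal(valueKind(sm), "viability_fraction")
    expect_equal(unname(v[c("c1", "c2", "c3"), "JAR"]), c(0.5, 1.0, 0))

    # nonzero blank: viability = (od - blank) / (dmso - blank)
    shifted <- makePlate(c(0.6), odDmso = 1.1, odBlank = 0.1)
    expect_equal(unname(screenValues(normalizeViability(shifted))[1, 1]), 0.5)

    # below-blank OD clamps to 0
    low <- makePlate(c(0.02), odDmso = 1, odBlank = 0.05)
    expect_equal(unname(screenValues(normalizeViability(low))[1, 1]), 0)
})

test_that("normalizeViability rejects degenerate or under-controlled plates", {
    degen <- makePlate(c(0.5), odDmso = 0.05, odBlank = 0.5)
    expect_error(normalizeViability(degen), "degenerate plate P1")
    oneCtrl <- makePlate(c(0.5))
    oneCtrl <- oneCtrl[oneCtrl$well != "B1", ]
    expect_error(normalizeViability(oneCtrl), "fewer than 2")
    noBlank <- makePlate(c(0.5))
    noBlank <- noBlank[noBlank$role != "blank", ]
    expect_error(normalizeViability(noBlank), "no blank")
})

test_that("computeZScores standardizes each line to mean 0, sample SD 1", {
    m <- matrix(c(10, 20, 30), 3, 1,
        dimnames = list(c("a", "b", "c"), "JAR"))
    z <- screenValues(computeZScores(ScreenMatrix(m, "inhibition_percent")))
    expect_equal(unname(z[, 1]), c(-1, 0, 1))

    set.seed(11)
    for (i in 1:25) {
        rm <- matrix(rnorm(40 * 4, 50, 20), 40, 4,
            dimnames = list(sprintf("c%02d", 1:40), screenCellLines()))
        z <- screenValues(computeZScores(ScreenMatrix(rm,
            "inhibition_percent")))
        expect_true(all(abs(colMeans(z)) < 1e-9))
        expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
    }

    flat <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("JAR", "BeWo")))
    expect_error(computeZScores(ScreenMatrix(flat, "inhibition_percent")),
        "zero inhibition variance")
    expect_error(computeZScores(ScreenMatrix(m / 100, "viability_fraction")),
        "inhibition_percent")
})

test_that("callSelectiveHits applies the z>2 / control<=2 rule with its
           boundary conventions", {
    zm <- rbind(
        sel  = c(JAR = 2.5, `JEG-3` = 2.1, BeWo = 0.5, `HTR-8/SVneo` = 1.0),
        one  = c(2.5, 1.9, 0.5, 1.0),          # only one cancer line
        edge = c(2.5, 2.1, 0.5, 2.0))          # control exactly at 2
    colnames(zm) <- screenCellLines()
    hits <- callSelectiveHits(zMatrixOf(zm))
    expect_equal(hits$selective, c(TRUE, FALSE, TRUE))
    expect_equal(hits$nCancerLinesHit, c(2L, 1L, 2L))
    expect_true(hits$controlPass[3])            # non-strict control bound
    # strict > on cancer lines: z exactly 2 is not a hit
    zm2 <- zm; zm2["one", "JEG-3"] <- 2.0
    expect_equal(callSelectiveHits(zMatrixOf(zm2))$nCancerLinesHit[2], 1L)
    expect_error(callSelectiveHits(zMatrixOf(zm), controlLine = "MCF7"),
        "configuration error")
})

test_that("callSelectiveHits agrees with an exhaustive rule oracle", {
    set.seed(23)
    for (i in 1:30) {
        n <- sample(5:20, 1)
        inhib <- matrix(rnorm(n * 4, 20, 15), n, 4,
            dimnames = list(sprintf("c%02d", seq_len(n)), screenCellLines()))
        z <- computeZScores(ScreenMatrix(inhib, "inhibition_percent"))
        thr <- runif(1, 0.5, 2.5)
        mink <- sample(1:3, 1)
        got <- callSelectiveHits(z, threshold = thr, minCancerLines = mink)
        want <- oracleSelectiveCalls(inhib, cancerCellLines(),
            controlCellLine(), threshold = thr, minCancerLines = mink)
        expect_equal(got$selective, unname(want))
    }
})

test_that("hit sets are monotone in threshold and minCancerLines", {
    set.seed(31)
    inhib <- matrix(rnorm(200 * 4, 30, 12), 200, 4,
        dimnames = list(sprintf("c%03d", 1:200), screenCellLines()))
    z <- computeZScores(ScreenMatrix(inhib, "inhibition_percent"))
    loose <- callSelectiveHits(z, threshold = 1)
    tight <- callSelectiveHits(z, threshold = 2)
    # per-line hits at t=2 are a subset of hits at t=1
    expect_true(all(tight$hit <= loose$hit))
    # selective set shrinks weakly as minCancerLines rises
    k2 <- callSelectiveHits(z, minCancerLines = 2)
    k3 <- callSelectiveHits(z, minCancerLines = 3)
    expect_true(all(k3$selective <= k2$selective))
})

test_that("intersectHits partitions the hit union into Venn regions", {
    mk <- function(a, b, c3) {
        hm <- cbind(JAR = a, `JEG-3` = b, BeWo = c3)
        rownames(hm) <- sprintf("c%02d", seq_len(nrow(hm)))
        S4Vectors::DataFrame(compound_id = rownames(hm), hit = I(hm),
            selective = rowSums(hm) >= 2)
    }
    # disjoint singletons: no pairwise/triple overlap
    disj <- mk(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
               c(FALSE, FALSE, TRUE))
    r <- intersectHits(disj)
    expect_equal(unname(r$regions), c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
    # identical hit sets of size k: everything in the triple region
    same <- mk(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE),
               c(TRUE, TRUE, FALSE))
    r <- intersectHits(same)
    expect_equal(unname(r$regions[7]), 2L)
    expect_equal(sum(r$regions), r$unionSize)
    # partition identity on random flag matrices
    set.seed(5)
    for (i in 1:20) {
        hm <- matrix(runif(30) > 0.5, 10, 3)
        r <- intersectHits(mk(hm[, 1], hm[, 2], hm[, 3]))
        expect_equal(sum(r$regions), sum(rowSums(hm) > 0))
    }
})

test_that("heatmapSubset thresholds, nests and breaks ties by id", {
    zm <- rbind(
        c05 = c(0.5, 0.2, 0.1, 0.0),
        a   = c(1.5, 0.0, 0.0, 0.0),
        b   = c(0.0, 1.5, 0.0, 0.0),
        big = c(2.5, 2.2, 0.0, 0.0))
    colnames(zm) <- screenCellLines()
    sub <- heatmapSubset(zMatrixOf(zm), threshold = 1)
    expect_equal(sub$compound_id, c("big", "a", "b"))  # ties a/b by id
    expect_equal(nrow(heatmapSubset(zMatrixOf(zm), threshold = 3)), 0L)
    # selective hits always appear in the z>1 reporting subset
    hits <- callSelectiveHits(zMatrixOf(zm))
    expect_true(all(hits$compound_id[hits$selective] %in% sub$compound_id))
})
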