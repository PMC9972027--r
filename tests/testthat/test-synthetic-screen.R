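test_that("generateLibrary sizes, labels and determinism", {
    spec <- librarySpec(seed = 7L)
    lib <- generateLibrary(spec)
    expect_equal(nrow(lib$annotations), 1271L)
    expect_false(anyDuplicated(lib$annotations$compound_id) > 0)
    tab <- table(truthLabels(lib$truth))
    expect_equal(unname(tab[["selective_hit"]]), 40L)
    expect_equal(unname(tab[["pan_toxic"]]), 10L)

    # no plants -> everything inert
    quiet <- generateLibrary(librarySpec(nCompounds = 10,
        nPlantedSelective = 0, nPlantedPanToxic = 0, seed = 1))
    expect_true(all(truthLabels(quiet$truth) == "inert"))
    expect_true(all(trueViability(quiet$truth) == 1))

    # same spec + seed -> identical outputs
    again <- generateLibrary(spec)
    expect_identical(lib$annotations, again$annotations)
    expect_identical(trueViability(lib$truth), trueViability(again$truth))

    expect_error(librarySpec(nCompounds = -3), "positive")
    expect_error(librarySpec(nCompounds = 5, nPlantedSelective = 4,
        nPlantedPanToxic = 4), "exceed")
    expect_error(librarySpec(noiseSd = 0), "noiseSd")
})

test_that("selective plants respond in 2-3 cancer lines, never the control", {
    spec <- librarySpec(nCompounds = 60, nPlantedSelective = 20,
        nPlantedPanToxic = 5, seed = 3)
    truth <- generateLibrary(spec)$truth
    viab <- trueViability(truth)
    labels <- truthLabels(truth)
    eff <- 3.5 * 0.1
    sel <- names(labels)[labels == "selective_hit"]
    nResp <- rowSums(viab[sel, cancerCellLines(), drop = FALSE] < 1)
    expect_true(all(nResp %in% 2:3))
    expect_true(all(viab[sel, controlCellLine()] == 1))
    pan <- names(labels)[labels == "pan_toxic"]
    expect_true(all(abs(viab[pan, ] - (1 - eff)) < 1e-12))
})

test_that("simulatePrimaryPlates: geometry, counts and noiseless limit", {
    spec <- librarySpec(nCompounds = 30, nPlantedSelective = 3,
        nPlantedPanToxic = 1, seed = 5)
    lib <- generateLibrary(spec)
    plates <- simulatePrimaryPlates(lib$truth, spec)
    expect_equal(sum(plates$role == "sample"), 30L * 4L)
    # per plate: controls and blanks present
    expect_true(all(table(plates$plate_id[plates$role == "blank"]) >= 1))
    expect_true(all(table(plates$plate_id[plates$role ==
        "negative_control"]) >= 2))

    # full library size: 1271 x 4 = 5084 sample wells
    big <- generateLibrary(librarySpec(seed = 1))
    bigPlates <- simulatePrimaryPlates(big$truth, librarySpec(seed = 1))
    expect_equal(sum(bigPlates$role == "sample"), 5084L)

    # noiseless limit: inert compounds normalize to exactly 1 everywhere,
    # planted selective hits keep control viability 1 and < 1 in >= 2
    # cancer lines
    noiseless <- simulatePrimaryPlates(lib$truth, spec, noiseSd = 0)
    sm <- screenValues(normalizeViability(noiseless, screenCellLines()))
    labels <- truthLabels(lib$truth)
    inert <- names(labels)[labels == "inert"]
    expect_true(all(abs(sm[inert, ] - 1) < 1e-12))
    sel <- names(labels)[labels == "selective_hit"]
    expect_true(all(abs(sm[sel, controlCellLine()] - 1) < 1e-12))
    expect_true(all(rowSums(sm[sel, cancerCellLines(), drop = FALSE] < 1)
        >= 2))

    # determinism and geometry validation
    expect_identical(plates, simulatePrimaryPlates(lib$truth, spec))
    expect_error(simulatePrimaryPlates(lib$truth, spec, controlWells = 1),
        "configuration error")
    expect_error(simulatePrimaryPlates(lib$truth, spec, blankWells = 0),
        "configuration error")
})

test_that("simulateDoseResponse noiseless identities and determinism", {
    # midpoint identity: at d = IC50 the 4PL is (bottom + top) / 2
    mid <- simulateDoseResponse(ic50 = 2, bottom = 0.1, top = 0.9,
        hill = 1.7, doses = c(0.5, 1, 2, 8), replicates = 1, noiseSd = 0)
    expect_equal(mid$viability[mid$dose == 2], 0.5)
    # asymptote: viability -> top as dose -> 0
    tiny <- simulateDoseResponse(ic50 = 1, doses = c(1e-8, 1, 2, 4),
        replicates = 1, noiseSd = 0)
    expect_equal(tiny$viability[1], 1, tolerance = 1e-6)
    # seeded determinism
    expect_identical(simulateDoseResponse(ic50 = 1.16, seed = 9),
                     simulateDoseResponse(ic50 = 1.16, seed = 9))
    expect_error(simulateDoseResponse(ic50 = 1, doses = c(0, 1, 2, 4)),
        "positive")
    expect_error(simulateDoseResponse(ic50 = 1, replicates = 0), ">= 1")
})

test_that("simulateTumorGrowth null, full-suppression and determinism", {
    # full suppression, noiseless: treated volumes constant at baseline
    g <- simulateTumorGrowth(nPerArm = 3, effect = 1, noiseSd = 0,
        baselineVolume = 100, seed = 2)
    tr <- g[g$arm == "treated", ]
    expect_equal(tumorVolume(tr$length_mm, tr$width_mm),
        rep(100, nrow(tr)), tolerance = 1e-10)
    # caliper pairs are consistent with the ellipsoid volume
    veh <- g[g$arm == "vehicle", ]
    expect_equal(tumorVolume(veh$length_mm, veh$width_mm),
        100 * exp(0.18 * veh$day), tolerance = 1e-10)
    expect_identical(simulateTumorGrowth(seed = 4),
                     simulateTumorGrowth(seed = 4))
    expect_error(simulateTumorGrowth(nPerArm = 0), ">= 1")
})

test_that("simulateCtPanel encodes fold changes in cycles", {
    # fold 1, noiseless: treated Ct equals control Ct
    flat <- simulateCtPanel("GPX4", foldChanges = 1, ctNoiseSd = 0, seed = 1)
    tgt <- flat[flat$gene == "GPX4", ]
    expect_equal(tgt$ct[tgt$condition == "treated"],
                 tgt$ct[tgt$condition == "control"])
    # fold 0.5 costs exactly one extra cycle
    half <- simulateCtPanel("GPX4", foldChanges = 0.5, ctNoiseSd = 0,
        seed = 1)
    tgt <- half[half$gene == "GPX4", ]
    expect_equal(unique(tgt$ct[tgt$condition == "treated"]) -
                 unique(tgt$ct[tgt$condition == "control"]), 1)
    # reference gene is centred identically in both conditions
    ref <- half[half$gene == "GAPDH", ]
    expect_equal(unique(ref$ct), 18)
    expect_identical(simulateCtPanel("NRF2", 0.4, seed = 6),
                     simulateCtPanel("NRF2", 0.4, seed = 6))
    expect_error(simulateCtPanel("GPX4", foldChanges = 0), "> 0")
    expect_error(simulateCtPanel("GPX4", foldChanges = -1), "> 0")
})
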