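# Synthetic renderer: determinism, blank/complete renders, script
# generation, ground-truth bookkeeping, red/black separability.

test_that("a blank script renders pages with no red ink", {
    lay <- testLayout(120)
    rp <- renderProtocol(protocolScript(matrix(0, 5, 35)), lay,
                         zeroNoiseModel(dpi = 120))
    for (p in 1:5)
        expect_equal(sum(segmentRed(rp@pages[[p]])), 0L)
})

test_that("a complete design renders one straight stroke per dot pair", {
    lay <- testLayout(300)
    rc <- renderCell(lay, 1, 1023L, zeroNoiseModel())
    mask <- segmentRed(rc$raster)
    centers <- dotCenters(lay, 1, 0L, local = TRUE)
    conns <- enumerateConnections(5)
    idx <- which(mask, arr.ind = TRUE)
    px <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5)
    for (j in 1:10) {
        a <- centers[conns$dotA[j] + 1, ]
        b <- centers[conns$dotB[j] + 1, ]
        # red pixels present near the midpoint of every segment
        mid <- (a + b) / 2
        expect_gt(sum((px[, 1] - mid[1])^2 + (px[, 2] - mid[2])^2 < 3^2), 0)
    }
    expect_identical(rc$connections, 0:9)
    expect_identical(rc$expectedDesign, 1023L)
})

test_that("renders are bit-identical for identical seeds", {
    lay <- testLayout(120)
    script <- randomScript(6, 0.2, seed = 3)
    n1 <- strokeNoiseModel(dpi = 120, seed = 77L)
    r1 <- renderProtocol(script, lay, n1)
    r2 <- renderProtocol(script, lay, n1)
    for (p in 1:5) expect_identical(r1@pages[[p]], r2@pages[[p]])
    r3 <- renderProtocol(script, lay, strokeNoiseModel(dpi = 120, seed = 78L))
    expect_false(identical(r1@pages[[1]], r3@pages[[1]]))
})

test_that("randomScript ground truth counts follow from its construction", {
    # all blank
    s0 <- randomScript(0, 0, seed = 1)
    expect_equal(sum(s0@designs), 0)
    sc0 <- scoreScript(s0)
    expect_equal(uniqueDesigns(sc0), 0L)
    expect_equal(perseverativeErrors(sc0), 0L)
    # 35 cells, no perseveration: 35 first occurrences per part
    s1 <- randomScript(35, 0, seed = 2)
    sc1 <- scoreScript(s1)
    expect_equal(uniqueDesigns(sc1), 175L)
    expect_equal(perseverativeErrors(sc1), 0L)
    # independent first-occurrence oracle on a moderate-rate script
    s2 <- randomScript(20, 0.3, seed = 3)
    sc2 <- scoreScript(s2)
    uniqOracle <- sum(apply(s2@designs, 1, function(d) {
        d <- d[d > 0]; length(unique(d))
    }))
    persOracle <- sum(apply(s2@designs, 1, function(d) {
        d <- d[d > 0]; sum(duplicated(d))
    }))
    expect_equal(uniqueDesigns(sc2), uniqOracle)
    expect_equal(perseverativeErrors(sc2), persOracle)
    expect_error(randomScript(10, 1.5), "invalid argument")
    expect_error(randomScript(40, 0), "invalid argument")
})

test_that("scripted violations are echoed in the ground truth", {
    v <- matrix(FALSE, 5, 35)
    v[2, 1] <- TRUE
    script <- protocolScript(matrix(c(rep(17, 5), rep(0, 170)), 5, 35), v)
    lay <- testLayout(120)
    rp <- renderProtocol(script, lay, strokeNoiseModel(dpi = 120))
    gt <- rp@groundTruth
    expect_identical(gt$script@designs, script@designs)
    expect_equal(gt$expectedDesigns[2, 1], 0)       # violated -> excluded
    expect_equal(gt$expectedDesigns[1, 1], 17)      # untouched elsewhere
    expect_equal(length(gt$cells[[2]][[1]]$violated), 2)  # both strokes
})

test_that("red ink avoids printed black geometry except at the dots", {
    lay <- testLayout(300)
    for (part in c(1, 4)) {
        board <- renderCell(lay, part, 0L, zeroNoiseModel())$raster
        black <- board[, , 1] <= 0.5
        rc <- renderCell(lay, part, 1023L, zeroNoiseModel())
        red <- segmentRed(rc$raster)
        overlap <- which(red & black, arr.ind = TRUE)
        if (nrow(overlap)) {
            centers <- dotCenters(lay, part, 0L, local = TRUE)
            px <- cbind(overlap[, 2] - 0.5, overlap[, 1] - 0.5)
            dmin <- apply(px, 1, function(q)
                min(sqrt((centers[, 1] - q[1])^2 + (centers[, 2] - q[2])^2)))
            expect_true(all(dmin <= lay@dotRadiusPx + 1))
        } else succeed()
    }
})

test_that("noise model validity rejects bad parameters", {
    expect_error(strokeNoiseModel(jitterSdPx = -1), ">= 0")
    expect_error(strokeNoiseModel(violationProbability = 2), "\\[0, 1\\]")
    expect_error(protocolScript(matrix(2000, 5, 35)), "0..1023")
})
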