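# The five-task recognition algorithm, task by task and composed.

test_that("active dots are exactly the dots touched by ink", {
    lay <- testLayout(300)
    cfg <- recognitionConfig(lay)
    # empty mask: no active dots
    empty <- cellFromMask(matrix(FALSE, 100, 100),
                          cbind(seq(10, 90, 20), seq(10, 90, 20)))
    ads <- identifyActiveDots(empty, cfg@activationRadiusPx)
    expect_false(any(ads@active))
    # strokes touching dots 0,1,2 only (two adjacent connections)
    rc <- renderCell(lay, 1, designId(c(connIndex(0, 1), connIndex(1, 2))),
                     zeroNoiseModel())
    cell <- cellFromRender(rc, lay, 1)
    ads <- identifyActiveDots(cell, cfg@activationRadiusPx,
                              cfg@minActivationPixels)
    expect_identical(which(ads@active) - 1L, c(0L, 1L, 2L))
    expect_true(all(ads@evidence[1:3] >= cfg@minActivationPixels))
    # complete design: all five active
    rcAll <- renderCell(lay, 1, 1023L, zeroNoiseModel())
    adsAll <- identifyActiveDots(cellFromRender(rcAll, lay, 1),
                                 cfg@activationRadiusPx)
    expect_true(all(adsAll@active))
})

test_that("candidate connections are all pairs of active dots", {
    active <- c(FALSE, TRUE, TRUE, TRUE, FALSE)   # dots 1,2,3
    cands <- candidateConnections(active)
    expect_equal(nrow(cands), 3L)
    expect_setequal(cands$canonicalIndex,
                    c(connIndex(1, 2), connIndex(1, 3), connIndex(2, 3)))
    expect_equal(nrow(candidateConnections(rep(FALSE, 5))), 0L)
    expect_equal(nrow(candidateConnections(c(TRUE, rep(FALSE, 4)))), 0L)
    expect_equal(nrow(candidateConnections(rep(TRUE, 5))), 10L)
})

test_that("pixels are designated to the nearest candidate within the corridor", {
    lay <- testLayout(300)
    cfg <- recognitionConfig(lay)
    rc <- renderCell(lay, 1, designId(c(connIndex(0, 1), connIndex(1, 2))),
                     zeroNoiseModel())
    cell <- cellFromRender(rc, lay, 1)
    ads <- identifyActiveDots(cell, cfg@activationRadiusPx)
    cands <- candidateConnections(ads)
    pa <- assignPixels(cell, cands, cfg@corridorHalfwidthPx)
    drawn <- c(connIndex(0, 1), connIndex(1, 2))
    # stroke-body pixels (outside the dot disks, where the round end caps
    # of adjacent strokes can genuinely sit on another corridor) all land
    # on the drawn candidates
    centers <- cell@dotCenters
    dmin <- apply(pa@px, 1, function(q)
        min(sqrt((centers[, 1] - q[1])^2 + (centers[, 2] - q[2])^2)))
    body <- dmin > cfg@activationRadiusPx
    expect_gte(mean(pa@candidate[body] %in% drawn), 0.99)
    # and overall almost nothing is left unassigned
    expect_lte(unassignedFraction(pa), 0.01)
    # an isolated far-away pixel stays unassigned
    centers <- cell@dotCenters
    mask <- matrix(FALSE, nrow(cell@redMask), ncol(cell@redMask))
    mask[2, 2] <- TRUE   # corner, far from every candidate segment
    pa2 <- assignPixels(cellFromMask(mask, cell@dotCenters), cands,
                        cfg@corridorHalfwidthPx)
    expect_true(is.na(pa2@candidate[1]))
    expect_equal(unassignedFraction(pa2), 1)
})

test_that("line compatibility requires coverage and bounded gaps", {
    # full straight stroke
    full <- checkLineCompatibility(seq(0, 1, by = 0.005), 200)
    expect_true(full$accepted)
    # pixels covering only 30% near one dot: rejected for coverage
    part <- checkLineCompatibility(seq(0, 0.3, by = 0.005), 200)
    expect_false(part$accepted)
    expect_equal(part$reason, "coverage")
    expect_lt(abs(part$coverage - 0.3), 0.05)
    # central gap of 40%: rejected for gap (coverage 0.6 < 0.75 too, so
    # relax coverage to isolate the gap rule)
    gap <- checkLineCompatibility(c(seq(0, 0.3, by = 0.002),
                                    seq(0.7, 1, by = 0.002)), 200,
                                  coverageThreshold = 0.5)
    expect_false(gap$accepted)
    expect_equal(gap$reason, "gap")
    expect_lt(abs(gap$maxGap - 0.4), 0.05)
    # no pixels at all
    expect_false(checkLineCompatibility(numeric(), 200)$accepted)
})

test_that("coverage acceptance is monotone in added corridor pixels", {
    set.seed(11)
    for (i in 1:25) {
        len <- runif(1, 80, 300)
        t0 <- runif(sample(50:200, 1))
        base <- checkLineCompatibility(t0, len)
        extra <- checkLineCompatibility(c(t0, runif(50)), len)
        if (base$accepted) {
            # adding pixels anywhere along the corridor never rejects
            expect_true(extra$accepted)
            expect_gte(extra$coverage, base$coverage)
            expect_lte(extra$maxGap, base$maxGap)
        }
    }
})

test_that("collinear subsumption removes the spurious long candidate", {
    # constructed geometry: dots 0, 2, 4 collinear on a horizontal line
    centers <- rbind(c(20, 100), c(100, 20), c(100, 100), c(100, 180),
                     c(180, 100))
    k02 <- connIndex(0, 2); k24 <- connIndex(2, 4); k04 <- connIndex(0, 4)
    mask <- paintMaskSegment(matrix(FALSE, 200, 200), centers[1, ],
                             centers[5, ], halfWidth = 2)
    cell <- cellFromMask(mask, centers)
    active <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
    cands <- candidateConnections(active)
    pa <- assignPixels(cell, cands, 11.4)
    # tie-break toward shorter segments starves the long candidate
    expect_equal(sum(pa@candidate %in% k04, na.rm = TRUE), 0L)
    # force the long candidate into the accepted set: task 5 removes it
    fp <- rejectFalsePositives(c(k02, k24, k04), active, pa, centers,
                               activationRadiusPx = 12.4,
                               corridorHalfwidthPx = 11.4)
    expect_setequal(fp$true, c(k02, k24))
    expect_equal(fp$removed$canonicalIndex, k04)
    expect_equal(fp$removed$interiorDot, 2L)
})

test_that("a long line through an inactive interior region is retained", {
    centers <- rbind(c(20, 100), c(100, 20), c(100, 100), c(100, 180),
                     c(180, 100))
    k04 <- connIndex(0, 4)
    mask <- paintMaskSegment(matrix(FALSE, 200, 200), centers[1, ],
                             centers[5, ], halfWidth = 2)
    cell <- cellFromMask(mask, centers)
    # interior dot 2 NOT active: no subsumption triple exists
    active <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
    cands <- candidateConnections(active)
    pa <- assignPixels(cell, cands, 11.4)
    fp <- rejectFalsePositives(k04, active, pa, centers, 12.4, 11.4)
    expect_identical(fp$true, k04)
    # a single isolated stroke passes through unchanged too
    fp2 <- rejectFalsePositives(connIndex(0, 1), c(TRUE, TRUE, FALSE, FALSE,
                                                   FALSE), pa, centers,
                                12.4, 11.4)
    expect_identical(fp2$true, connIndex(0, 1))
})

test_that("violations are strokes crossing dots beyond the threshold", {
    lay <- testLayout(300)
    cfg <- recognitionConfig(lay)
    # compliant zero-noise render: no violations
    rc <- renderCell(lay, 1, 17L, zeroNoiseModel())
    out <- recognizeCell(cellFromRender(rc, lay, 1), cfg)
    expect_equal(out@violations, 0L)
    expect_equal(out@design, 17L)
    # violation mode: every stroke crosses the dots and is excluded
    for (m in c(17L, 1023L)) {
        rcv <- renderCell(lay, 1, m, strokeNoiseModel(), violate = TRUE)
        outv <- recognizeCell(cellFromRender(rcv, lay, 1), cfg)
        expect_equal(outv@violations, length(rcv$connections))
        expect_equal(outv@design, 0L)
        expect_false(outv@unscorable)   # violations, not scribble
    }
    # overshoot below the threshold is not a violation
    nm <- zeroNoiseModel()
    nm@overshootPx <- cfg@overshootThresholdPx - 4
    rcs <- renderCell(lay, 1, 17L, nm, violate = TRUE)
    outs <- recognizeCell(cellFromRender(rcs, lay, 1), cfg)
    expect_equal(outs@violations, 0L)
    expect_equal(outs@design, 17L)
})

test_that("violating strokes can be counted as designs on request", {
    lay <- testLayout(300)
    cfgLiberal <- recognitionConfig(lay, countViolationsAsDesigns = TRUE)
    rcv <- renderCell(lay, 1, 17L, strokeNoiseModel(), violate = TRUE)
    outv <- recognizeCell(cellFromRender(rcv, lay, 1), cfgLiberal)
    expect_equal(outv@design, 17L)
    expect_equal(outv@violations, 2L)   # still reported
})

test_that("recognizeCell composes the five tasks", {
    lay <- testLayout(300)
    cfg <- recognitionConfig(lay)
    # empty cell
    centers <- dotCenters(lay, 1, 0L, local = TRUE)
    empty <- cellFromMask(matrix(FALSE, 50, 50), centers)
    out0 <- recognizeCell(empty, cfg)
    expect_equal(out0@design, 0L)
    expect_equal(out0@violations, 0L)
    expect_false(out0@hasInk)
    expect_false(out0@unscorable)
    # the two-adjacent-connections configuration: only the drawn pair
    # survives (the chord between the outer dots is rejected)
    drawn <- c(connIndex(0, 1), connIndex(1, 2))
    rc <- renderCell(lay, 1, designId(drawn), zeroNoiseModel())
    out <- recognizeCell(cellFromRender(rc, lay, 1), cfg)
    expect_identical(out@trueConnections, sort(drawn))
    expect_identical(out@design, designId(drawn))
    chord <- connIndex(0, 2)
    expect_true(any(out@diagnostics$canonicalIndex == chord &
                    out@diagnostics$decision == "rejected"))
    # sampled zero-noise round trip across parts
    set.seed(5)
    for (m in sample(1:1023, 12)) for (part in c(2, 3, 5)) {
        rcM <- renderCell(lay, part, m, zeroNoiseModel())
        outM <- recognizeCell(cellFromRender(rcM, lay, part), cfg)
        expect_identical(outM@design, m)
    }
})

test_that("ink that forms no connection is unscorable, never hallucinated", {
    lay <- testLayout(300)
    centers <- dotCenters(lay, 1, 0L, local = TRUE)
    mask <- matrix(FALSE, 407, 450)
    mid <- colMeans(centers)
    # a short scribble in the middle, touching no dot
    mask <- paintMaskSegment(mask, mid - c(8, 0), mid + c(8, 0),
                             halfWidth = 2)
    cell <- cellFromMask(mask, centers)
    for (cov in c(0.5, 0.75, 0.9)) {
        cfg <- recognitionConfig(lay, coverageThreshold = cov)
        out <- recognizeCell(cell, cfg)
        expect_equal(out@design, 0L)
        expect_true(out@unscorable)
    }
    # an empty mask yields design 0 regardless of config
    out0 <- recognizeCell(cellFromMask(matrix(FALSE, 10, 10), centers),
                          recognitionConfig(lay, minActivationPixels = 1L))
    expect_equal(out0@design, 0L)
})
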