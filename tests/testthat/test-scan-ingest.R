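# Scan ingestion: red segmentation, dot detection, layout registration,
# per-cell cropping.

test_that("segmentRed isolates respondent ink from paper and print", {
    lay <- testLayout(120)
    # all-white page
    white <- array(1, dim = c(100, 80, 3))
    expect_equal(sum(segmentRed(white)), 0L)
    # board-only pages (dots + distractors, no strokes): nothing is red
    rp <- renderProtocol(protocolScript(matrix(0, 5, 35)), lay,
                         zeroNoiseModel(dpi = 120))
    for (p in c(2, 3))
        expect_equal(sum(segmentRed(rp@pages[[p]])), 0L)
    # grayscale input is refused
    expect_error(segmentRed(matrix(1, 10, 10)), "unsupported input")
    expect_error(pageImage(matrix(1, 10, 10), 1), "unsupported input")
})

test_that("segmentRed recovers the rendered stroke pixels", {
    lay <- testLayout(300)
    rc <- renderCell(lay, 1, 341L, zeroNoiseModel())
    mask <- segmentRed(rc$raster)
    # at least 99% of core ink pixels (alpha > 0.5) are captured
    expect_gte(sum(mask & rc$inkMask) / sum(rc$inkMask), 0.99)
    # and the mask adds little beyond the anti-aliased fringe
    expect_lte(sum(mask & !rc$inkMask) / sum(rc$inkMask), 0.6)
})

test_that("registration recovers an identity-like transform on own renders", {
    lay <- testLayout(150)
    rp <- renderProtocol(randomScript(10, 0.1, seed = 4), lay,
                         strokeNoiseModel(dpi = 150, seed = 4L))
    reg <- registerLayout(rp@pages[[1]], lay, part = 1)
    expect_lt(abs(reg@scale - 1), 0.005)
    expect_lt(abs(reg@rotationRad), 0.005)
    expect_lt(sqrt(sum(reg@translation^2)), 1)
    expect_lt(reg@meanResidualPx, 1)
    expect_gte(reg@matchedFraction, 0.8)
})

test_that("registration recovers a translation to half-pixel accuracy", {
    lay <- testLayout(150)
    rp <- renderProtocol(protocolScript(matrix(0, 5, 35)), lay,
                         zeroNoiseModel(dpi = 120))
    page <- rp@pages[[1]]
    dx <- 5L; dy <- -3L
    H <- dim(page)[1]; W <- dim(page)[2]
    shifted <- array(1, dim = dim(page))
    # content moves by (+dx, +dy): target rows/cols = source + shift
    srcR <- max(1, 1 - dy):min(H, H - dy)
    srcC <- max(1, 1 - dx):min(W, W - dx)
    shifted[srcR + dy, srcC + dx, ] <- page[srcR, srcC, ]
    reg <- registerLayout(shifted, lay, part = 1)
    expect_lt(abs(reg@translation[1] - dx), 0.5)
    expect_lt(abs(reg@translation[2] - dy), 0.5)
    expect_lt(abs(reg@scale - 1), 0.005)
})

test_that("registration fails cleanly on a blank page", {
    lay <- testLayout(150)
    blank <- array(1, dim = c(lay@pageHeightPx, lay@pageWidthPx, 3))
    expect_error(registerLayout(blank, lay, part = 1),
                 "registration-failure")
})

test_that("dot detection drops diamond and line distractors", {
    lay <- testLayout(150)
    rp <- renderProtocol(protocolScript(matrix(0, 5, 35)), lay,
                         zeroNoiseModel(dpi = 150))
    for (p in 1:3) {
        blobs <- detectDots(rp@pages[[p]], lay)
        # exactly the 175 printed dots survive the size/shape filter
        expect_equal(nrow(blobs), 175L)
    }
})

test_that("cropCells partitions the red pixels exactly", {
    lay <- testLayout(150)
    script <- randomScript(8, 0.2, seed = 9)
    rp <- renderProtocol(script, lay, strokeNoiseModel(dpi = 150, seed = 9L))
    page <- rp@pages[[3]]
    red <- segmentRed(page)
    reg <- registerLayout(page, lay, part = 3)
    cells <- cropCells(page, red, reg, lay)
    expect_length(cells, 35L)
    total <- sum(vapply(cells, function(ci) sum(ci@redMask), integer(1)))
    expect_equal(total + attr(cells, "droppedPixels"), sum(red))
    # non-empty masks exactly at the scripted cells
    filled <- which(script@designs[3, ] > 0) - 1L
    nonEmpty <- which(vapply(cells, function(ci) sum(ci@redMask) > 0,
                             logical(1))) - 1L
    expect_setequal(nonEmpty, filled)
})

test_that("a single drawn cell yields one non-empty mask at its index", {
    lay <- testLayout(150)
    d <- matrix(0, 5, 35); d[1, 14] <- 513
    rp <- renderProtocol(protocolScript(d), lay,
                         strokeNoiseModel(dpi = 150, seed = 2L))
    page <- rp@pages[[1]]
    red <- segmentRed(page)
    reg <- registerLayout(page, lay, part = 1)
    cells <- cropCells(page, red, reg, lay)
    counts <- vapply(cells, function(ci) sum(ci@redMask), integer(1))
    expect_equal(which(counts > 0), 14L)
})
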