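# Scan ingestion: load pages, separate respondent ink from the printed
# board, register the board layout to the image and crop per-cell red-ink
# masks.

#' Read a scanned protocol page
#'
#' @param path path to a PNG (or TIFF via \pkg{EBImage}) color scan.
#' @param part part number 1-5.
#' @param dpi scan resolution (default 300).
#' @return a [PageImage].
#' @export
readPage <- function(path, part, dpi = 300) {
    raster <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
        png::readPNG(path)
    } else {
        img <- EBImage::readImage(path)
        aperm(EBImage::imageData(img), c(2, 1, 3))
    }
    pageImage(raster, part, dpi)
}

#' @rdname readPage
#' @param raster H x W x 3 numeric array in [0, 1].
#' @export
pageImage <- function(raster, part, dpi = 300) {
    if (length(dim(raster)) == 2L)
        stop("unsupported input: grayscale page; color scan required")
    if (dim(raster)[3] > 3L) raster <- raster[, , 1:3, drop = FALSE]
    new("PageImage", raster = raster, dpi = dpi, part = as.integer(part))
}

#' Segment respondent red ink
#'
#' Designates all red pixels of the drawn design: pixels whose HSV color
#' falls in the configured red window. Printed black elements (low value)
#' and white paper (low saturation) are excluded.
#'
#' @param page a [PageImage] or H x W x 3 array.
#' @param hueToleranceDeg half-width of the hue window around 0 (red).
#' @param minSaturation,minValue lower HSV bounds.
#' @return logical H x W matrix.
#' @export
segmentRed <- function(page, hueToleranceDeg = 20, minSaturation = 0.35,
                       minValue = 0.25) {
    raster <- if (is(page, "PageImage")) page@raster else page
    if (length(dim(raster)) != 3L)
        stop("unsupported input: color page required")
    r <- raster[, , 1]
    # cheap prefilter: red-hued ink needs R >= value floor and G strictly
    # below R (white paper has G = R, black print fails the value floor);
    # the full HSV window is evaluated on the surviving pixels only.
    cand <- which(r >= minValue & raster[, , 2] < r)
    mask <- matrix(FALSE, dim(raster)[1], dim(raster)[2])
    if (length(cand)) {
        rc <- r[cand]
        gc <- raster[, , 2][cand]
        bc <- raster[, , 3][cand]
        # R is the max channel; value = R, chroma = R - min(G, B),
        # saturation = chroma / R, hue = 60 (G - B) / chroma degrees;
        # thresholds applied in multiplied-out form.
        chroma <- rc - pmin(gc, bc)
        ok <- (bc <= rc) & (chroma > 0) &
            (chroma >= minSaturation * rc) &
            (60 * abs(gc - bc) <= hueToleranceDeg * chroma)
        mask[cand[ok]] <- TRUE
    }
    mask
}

#' Detect printed dots on a page
#'
#' Finds dark blobs of approximately the printed dot size by
#' connected-component labelling of the low-value mask, filtered by area
#' and moment elongation (which drops line distractors); diamond
#' distractors are dropped by the area window.
#'
#' @param page a [PageImage] or raster array.
#' @param layout a [BoardLayout] (for the expected dot radius).
#' @param maxValue value threshold below which a pixel counts as printed
#'   black.
#' @return data.frame with columns x, y (blob centroids, page coordinates)
#'   and area.
#' @export
detectDots <- function(page, layout, maxValue = 0.5) {
    raster <- if (is(page, "PageImage")) page@raster else page
    # printed black has every channel low while red ink keeps R high, so
    # the red channel alone separates print from paper and ink
    dark <- raster[, , 1] <= maxValue
    if (!any(dark)) return(data.frame(x = numeric(), y = numeric(),
                                      area = numeric()))
    lab <- EBImage::bwlabel(dark)
    idx <- which(lab > 0L)
    labv <- lab[idx]
    h <- dim(dark)[1]
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    area <- tabulate(labv)
    cx <- rowsum(cols - 0.5, labv)[, 1] / area
    cy <- rowsum(rows - 0.5, labv)[, 1] / area
    # second moments for elongation
    dx <- (cols - 0.5) - cx[labv]
    dy <- (rows - 0.5) - cy[labv]
    sxx <- rowsum(dx * dx, labv)[, 1] / area
    syy <- rowsum(dy * dy, labv)[, 1] / area
    sxy <- rowsum(dx * dy, labv)[, 1] / area
    tr <- sxx + syy
    dt <- sqrt(pmax(0, (sxx - syy)^2 + 4 * sxy^2))
    l1 <- (tr + dt) / 2
    l2 <- pmax((tr - dt) / 2, 1e-9)
    elong <- sqrt(l1 / l2)
    expArea <- pi * layout@dotRadiusPx^2
    keep <- area >= 0.45 * expArea & area <= 1.9 * expArea & elong <= 2.2
    data.frame(x = cx[keep], y = cy[keep], area = area[keep])
}

#' Register the board layout to a scanned page
#'
#' Matches detected printed-dot centroids to the layout's expected dot
#' positions and fits a similarity transform (translation, scale, small
#' rotation) by least squares, with one robust re-fit that drops outlier
#' matches (dots partially overdrawn by respondent ink).
#'
#' @param page a [PageImage] or raster array.
#' @param layout a [BoardLayout].
#' @param part part number 1-5 (taken from the PageImage if given).
#' @param minMatchedFraction minimum fraction of the 175 expected dots that
#'   must be matched; below this a registration failure is raised.
#' @param maxResidualPx residual above which a matched dot is dropped in
#'   the robust re-fit.
#' @return a [LayoutRegistration].
#' @export
registerLayout <- function(page, layout, part = NULL,
                           minMatchedFraction = 0.8, maxResidualPx = 3) {
    if (is(page, "PageImage") && is.null(part)) part <- page@part
    if (is.null(part)) stop("part must be given when page is a raw array")
    blobs <- detectDots(page, layout)
    expected <- do.call(rbind, lapply(0:34, function(ci)
        dotCenters(layout, part, ci)))
    if (nrow(blobs) < 3L)
        stop("registration-failure: fewer than 3 printed dots detected")
    # nearest-blob match within a conservative radius (the dot squares are
    # far apart relative to plausible scan offsets)
    matchRadius <- 0.25 * layout@dotSquareSidePx
    bx <- blobs$x; by <- blobs$y
    matchOne <- function(pts) {
        nearest <- vapply(seq_len(nrow(pts)), function(i) {
            d2 <- (bx - pts[i, 1])^2 + (by - pts[i, 2])^2
            j <- which.min(d2)
            if (sqrt(d2[j]) <= matchRadius) j else NA_integer_
        }, integer(1))
        nearest
    }
    nearest <- matchOne(expected)
    ok <- !is.na(nearest)
    if (mean(ok) < minMatchedFraction)
        stop(sprintf("registration-failure: only %.0f%% of expected dots matched",
                     100 * mean(ok)))
    fit <- .fitSimilarity(expected[ok, , drop = FALSE],
                          cbind(bx, by)[nearest[ok], , drop = FALSE])
    # robust re-fit: re-match under the fitted transform, drop outliers
    proj <- .applySimilarity(fit, expected)
    nearest <- matchOne(proj)
    ok <- !is.na(nearest)
    res <- rep(NA_real_, nrow(expected))
    res[ok] <- sqrt(rowSums((proj[ok, , drop = FALSE] -
                             cbind(bx, by)[nearest[ok], , drop = FALSE])^2))
    good <- ok & res <= maxResidualPx
    if (sum(good) >= 3L)
        fit <- .fitSimilarity(expected[good, , drop = FALSE],
                              cbind(bx, by)[nearest[good], , drop = FALSE])
    proj <- .applySimilarity(fit, expected)
    res <- rep(NA_real_, nrow(expected))
    res[ok] <- sqrt(rowSums((proj[ok, , drop = FALSE] -
                             cbind(bx, by)[nearest[ok], , drop = FALSE])^2))
    resGood <- res[ok & res <= maxResidualPx]
    centers <- lapply(0:34, function(ci)
        .applySimilarity(fit, dotCenters(layout, part, ci)))
    corners <- lapply(0:34, function(ci) {
        b <- layout@cellBoxes[ci + 1L, ]
        .applySimilarity(fit, rbind(c(b[1], b[2]), c(b[3], b[2]),
                                    c(b[3], b[4]), c(b[1], b[4])))
    })
    reg <- new("LayoutRegistration",
               scale = fit$scale, rotationRad = fit$rotationRad,
               translation = fit$t,
               meanResidualPx = mean(resGood),
               maxResidualPx = max(resGood),
               matchedFraction = mean(ok),
               dotCenters = centers, cellCorners = corners)
    attr(reg, "fit") <- fit
    reg
}

#' Crop per-cell red-ink masks
#'
#' Partitions the red pixels of a page among the 35 registered cells. Each
#' red pixel is mapped through the inverse registration transform into
#' layout coordinates and assigned to the cell whose box contains it, so
#' the partition is exact; pixels outside every cell box are counted and
#' dropped.
#'
#' @param page a [PageImage] or raster array (only used for dimensions).
#' @param redMask logical matrix from [segmentRed()].
#' @param registration a [LayoutRegistration].
#' @param layout the [BoardLayout] used for registration.
#' @return list of 35 [CellInk] objects, with attribute
#'   \code{droppedPixels}.
#' @export
cropCells <- function(page, redMask, registration, layout) {
    fit <- attr(registration, "fit")
    idx <- which(redMask)
    h <- nrow(redMask)
    cells <- vector("list", 35L)
    if (length(idx)) {
        rows <- ((idx - 1L) %% h) + 1L
        cols <- ((idx - 1L) %/% h) + 1L
        pts <- cbind(cols - 0.5, rows - 0.5)
        lp <- .invertSimilarity(fit, pts)
        b1 <- layout@cellBoxes[1L, ]
        cw <- b1[3] - b1[1]
        ch <- b1[4] - b1[2]
        colIdx <- floor((lp[, 1] - b1[1]) / cw)
        rowIdx <- floor((lp[, 2] - b1[2]) / ch)
        inside <- colIdx >= 0 & colIdx < layout@nCols &
            rowIdx >= 0 & rowIdx < layout@nRows
        cellOf <- ifelse(inside, rowIdx * layout@nCols + colIdx, NA_real_)
        dropped <- sum(!inside)
    } else {
        cellOf <- numeric()
        rows <- cols <- integer()
        dropped <- 0L
    }
    for (ci in 0:34) {
        corners <- registration@cellCorners[[ci + 1L]]
        j0 <- floor(min(corners[, 1])) + 1L
        j1 <- ceiling(max(corners[, 1]))
        i0 <- floor(min(corners[, 2])) + 1L
        i1 <- ceiling(max(corners[, 2]))
        mask <- matrix(FALSE, i1 - i0 + 1L, j1 - j0 + 1L)
        sel <- which(!is.na(cellOf) & cellOf == ci)
        if (length(sel)) {
            rr <- rows[sel] - i0 + 1L
            cc <- cols[sel] - j0 + 1L
            okPix <- rr >= 1L & rr <= nrow(mask) & cc >= 1L & cc <= ncol(mask)
            mask[cbind(rr[okPix], cc[okPix])] <- TRUE
        }
        centers <- sweep(registration@dotCenters[[ci + 1L]], 2,
                         c(j0 - 1L, i0 - 1L))
        cells[[ci + 1L]] <- new("CellInk", cellIndex = ci, redMask = mask,
                                dotCenters = centers,
                                box = c(j0 - 1, i0 - 1, j1, i1))
    }
    attr(cells, "droppedPixels") <- dropped
    cells
}
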