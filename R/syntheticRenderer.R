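# Synthetic protocol renderer. Draws the printed board (black dots and
# part-specific distractors) and scripted respondent strokes (red ink with
# a hand-drawing noise model) into page rasters, and emits machine-readable
# ground truth for round-trip validation of the recognition pipeline.

.INK_RED <- c(0.80, 0.10, 0.12)

#' Construct a stroke noise model
#'
#' Defaults are the package's "moderate" hand-drawing noise at 300 dpi:
#' 1 px endpoint jitter, up to 2 px bow, 1 px endpoint shortfall. Distances
#' scale linearly with \code{dpi / 300}. Violation mode (strokes crossing
#' through the dots instead of stopping at them) extends strokes by
#' \code{overshootPx} past the dot centers; it is off by default
#' (\code{violationProbability = 0}) and can also be scripted per cell.
#'
#' @param jitterSdPx Gaussian SD of perpendicular endpoint displacement.
#' @param curvatureAmplitudePx maximum bow of the quadratic arc.
#' @param strokeWidthPx full stroke width.
#' @param endpointShortfallPx distance strokes stop short of dot centers.
#' @param overshootPx violation-mode extension past dot centers.
#' @param violationProbability per-stroke probability of violation mode.
#' @param channelNoiseSd per-pixel RGB noise SD on ink.
#' @param seed integer RNG seed for [renderProtocol()].
#' @param dpi resolution used to scale the pixel defaults.
#' @return a [StrokeNoiseModel].
#' @examples
#' strokeNoiseModel()          # moderate noise at 300 dpi
#' zeroNoiseModel()            # exact straight center-to-center strokes
#' @export
strokeNoiseModel <- function(jitterSdPx = 1 * dpi / 300,
                             curvatureAmplitudePx = 2 * dpi / 300,
                             strokeWidthPx = 5 * dpi / 300,
                             endpointShortfallPx = 1 * dpi / 300,
                             overshootPx = 30 * dpi / 300,
                             violationProbability = 0,
                             channelNoiseSd = 0.02,
                             seed = 1L,
                             dpi = 300) {
    new("StrokeNoiseModel",
        jitterSdPx = jitterSdPx,
        curvatureAmplitudePx = curvatureAmplitudePx,
        strokeWidthPx = strokeWidthPx,
        endpointShortfallPx = endpointShortfallPx,
        overshootPx = overshootPx,
        violationProbability = violationProbability,
        channelNoiseSd = channelNoiseSd,
        seed = as.integer(seed))
}

#' @rdname strokeNoiseModel
#' @export
zeroNoiseModel <- function(strokeWidthPx = 5 * dpi / 300, seed = 1L,
                           dpi = 300) {
    strokeNoiseModel(jitterSdPx = 0, curvatureAmplitudePx = 0,
                     strokeWidthPx = strokeWidthPx,
                     endpointShortfallPx = 0, overshootPx = 30 * dpi / 300,
                     violationProbability = 0, channelNoiseSd = 0,
                     seed = seed, dpi = dpi)
}

#' Construct a protocol script
#'
#' @param designs 5 x 35 matrix (or vector recycled) of design IDs in
#'   0..1023; 0 means a blank cell.
#' @param violations optional 5 x 35 logical matrix marking cells whose
#'   strokes are drawn in violation mode (crossing through the dots).
#' @return a [ProtocolScript].
#' @export
protocolScript <- function(designs, violations = NULL) {
    d <- matrix(as.numeric(designs), 5L, 35L)
    if (is.null(violations)) violations <- matrix(FALSE, 5L, 35L)
    v <- matrix(as.logical(violations), 5L, 35L)
    new("ProtocolScript", designs = d, violations = v)
}

#' Generate a random protocol script
#'
#' Fills the first \code{nFilledCellsPerPart} cells of each part with
#' designs drawn uniformly from 1..1023 without replacement within the
#' part; after the first filled cell of a part, each subsequent cell
#' instead repeats an earlier design of the same part with probability
#' \code{perseverationRate} (a scripted perseverative error), so scripted
#' repeats are the only repeats. Ground-truth unique-design and
#' perseveration counts follow directly from the script (see
#' [scoreScript()]).
#'
#' @param nFilledCellsPerPart cells to fill per part, 0..35.
#' @param perseverationRate probability in [0, 1] of repeating an earlier
#'   design within the part.
#' @param seed integer RNG seed.
#' @param violationRate probability that a filled cell is scripted in
#'   violation mode (default 0).
#' @return a [ProtocolScript].
#' @export
randomScript <- function(nFilledCellsPerPart = 18L, perseverationRate = 0.15,
                         seed = 1L, violationRate = 0) {
    if (nFilledCellsPerPart < 0 || nFilledCellsPerPart > 35)
        stop("invalid argument: nFilledCellsPerPart must be in 0..35")
    if (perseverationRate < 0 || perseverationRate > 1)
        stop("invalid argument: perseverationRate must be in [0, 1]")
    if (violationRate < 0 || violationRate > 1)
        stop("invalid argument: violationRate must be in [0, 1]")
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(seed)
    d <- matrix(0, 5L, 35L)
    v <- matrix(FALSE, 5L, 35L)
    for (p in 1:5) {
        unseen <- 1:1023
        for (i in seq_len(nFilledCellsPerPart)) {
            if (i > 1L && runif(1) < perseverationRate) {
                # deliberate perseveration: repeat an earlier design
                d[p, i] <- d[p, sample.int(i - 1L, 1L)]
            } else {
                # new designs are drawn without replacement within the
                # part, so scripted repeats are the only repeats
                pick <- sample.int(length(unseen), 1L)
                d[p, i] <- unseen[pick]
                unseen <- unseen[-pick]
            }
            v[p, i] <- runif(1) < violationRate
        }
    }
    protocolScript(d, v)
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}

# Composite color onto a canvas block with per-pixel alpha.
.compositeBlock <- function(canvas, i0, i1, j0, j1, alpha, color,
                            channelNoiseSd = 0) {
    idx <- which(alpha > 0)
    if (!length(idx)) return(canvas)
    a <- alpha[idx]
    for (ch in 1:3) {
        col <- color[ch]
        if (channelNoiseSd > 0)
            col <- .clamp01(col + rnorm(length(idx), 0, channelNoiseSd))
        sub <- canvas[i0:i1, j0:j1, ch]
        sub[idx] <- a * col + (1 - a) * sub[idx]
        canvas[i0:i1, j0:j1, ch] <- sub
    }
    canvas
}

# Paint an anti-aliased filled disk.
.paintDisk <- function(canvas, cx, cy, r, color = c(0, 0, 0)) {
    h <- dim(canvas)[1]; w <- dim(canvas)[2]
    i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r + 1))
    j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r + 1))
    if (i0 > i1 || j0 > j1) return(canvas)
    g <- .pixelGrid(i0, i1, j0, j1)
    d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    alpha <- matrix(.clamp01(r + 0.5 - d), g$nr, g$nc)
    .compositeBlock(canvas, i0, i1, j0, j1, alpha, color)
}

# Paint an anti-aliased L1-ball (diamond) distractor.
.paintDiamond <- function(canvas, cx, cy, halfDiag, color = c(0, 0, 0)) {
    h <- dim(canvas)[1]; w <- dim(canvas)[2]
    i0 <- max(1L, floor(cy - halfDiag)); i1 <- min(h, ceiling(cy + halfDiag + 1))
    j0 <- max(1L, floor(cx - halfDiag)); j1 <- min(w, ceiling(cx + halfDiag + 1))
    if (i0 > i1 || j0 > j1) return(canvas)
    g <- .pixelGrid(i0, i1, j0, j1)
    d <- abs(g$x - cx) + abs(g$y - cy)
    alpha <- matrix(.clamp01(halfDiag + 0.5 - d), g$nr, g$nc)
    .compositeBlock(canvas, i0, i1, j0, j1, alpha, color)
}

# Paint an anti-aliased thick polyline; returns the canvas and the set of
# core ink pixels (alpha > 0.5) for ground truth.
.paintPolyline <- function(canvas, pts, halfWidth, color,
                           channelNoiseSd = 0, trackInk = FALSE) {
    h <- dim(canvas)[1]; w <- dim(canvas)[2]
    pad <- halfWidth + 1.5
    i0 <- max(1L, floor(min(pts[, 2]) - pad))
    i1 <- min(h, ceiling(max(pts[, 2]) + pad))
    j0 <- max(1L, floor(min(pts[, 1]) - pad))
    j1 <- min(w, ceiling(max(pts[, 1]) + pad))
    if (i0 > i1 || j0 > j1)
        return(list(canvas = canvas, ink = NULL))
    g <- .pixelGrid(i0, i1, j0, j1)
    d <- .polylineDist(g$x, g$y, pts)
    alpha <- matrix(.clamp01(halfWidth + 0.5 - d), g$nr, g$nc)
    canvas <- .compositeBlock(canvas, i0, i1, j0, j1, alpha, color,
                              channelNoiseSd)
    ink <- NULL
    if (trackInk) {
        core <- which(alpha > 0.5, arr.ind = TRUE)
        if (nrow(core))
            ink <- cbind(row = core[, 1] + i0 - 1L, col = core[, 2] + j0 - 1L)
    }
    list(canvas = canvas, ink = ink)
}

# Sample a quadratic bezier as a polyline.
.bezierPoints <- function(p0, pc, p1, n = 13L) {
    t <- seq(0, 1, length.out = n)
    cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * pc[1] + t^2 * p1[1],
          (1 - t)^2 * p0[2] + 2 * t * (1 - t) * pc[2] + t^2 * p1[2])
}

# Draw one respondent stroke between two dot centers. Consumes a fixed
# number of RNG draws regardless of outcome so renders are reproducible.
.strokePath <- function(a, b, noise, forceViolation) {
    v <- b - a
    len <- sqrt(sum(v^2))
    u <- v / len
    nperp <- c(-u[2], u[1])
    violate <- runif(1) < noise@violationProbability || forceViolation
    if (violate) {
        e0 <- a - u * noise@overshootPx
        e1 <- b + u * noise@overshootPx
    } else {
        e0 <- a + u * noise@endpointShortfallPx
        e1 <- b - u * noise@endpointShortfallPx
    }
    j <- rnorm(2, 0, max(noise@jitterSdPx, 1e-12))
    if (noise@jitterSdPx > 0) {
        e0 <- e0 + nperp * j[1]
        e1 <- e1 + nperp * j[2]
    }
    bow <- runif(1, -1, 1) * noise@curvatureAmplitudePx
    ctrl <- (e0 + e1) / 2 + nperp * 2 * bow
    nSeg <- if (noise@curvatureAmplitudePx > 0) 9L else 2L
    list(pts = .bezierPoints(e0, ctrl, e1, nSeg), violated = violate)
}

#' Render one cell of a synthetic protocol
#'
#' Draws the printed five-dot pattern (plus part distractors) and the red
#' strokes of the given design into a cell-sized raster. One stroke is
#' drawn per connection in the design. Uses the current RNG stream; seed
#' handling is done by [renderProtocol()].
#'
#' @param layout a [BoardLayout].
#' @param part part number 1-5.
#' @param design design ID 0..1023 (0 = blank).
#' @param noise a [StrokeNoiseModel].
#' @param violate logical, force violation mode for all strokes of the cell.
#' @param cellIndex 0-based cell index (geometry is identical across cells;
#'   used for crop dimensions).
#' @return list with \code{raster} (h x w x 3 array), \code{connections}
#'   (canonical indices drawn), \code{violated} (indices of violating
#'   strokes, into \code{connections}), \code{expectedDesign} (design ID
#'   after excluding violating strokes) and \code{inkMask} (logical core
#'   ink mask, alpha > 0.5).
#' @export
renderCell <- function(layout, part, design, noise = strokeNoiseModel(),
                       violate = FALSE, cellIndex = 0L) {
    if (design < 0 || design > 1023 || design != round(design))
        stop("invalid argument: design must be an integer in 0..1023")
    box <- layout@cellBoxes[cellIndex + 1L, ]
    w <- as.integer(round(box[3]) - round(box[1]))
    h <- as.integer(round(box[4]) - round(box[2]))
    canvas <- array(1, dim = c(h, w, 3))
    centers <- dotCenters(layout, part, cellIndex, local = TRUE)
    canvas <- .paintCellBoard(canvas, layout, part, cellIndex, centers)
    conns <- designFromId(design)
    inkMask <- matrix(FALSE, h, w)
    violated <- integer()
    if (length(conns)) {
        pairs <- enumerateConnections(5L)
        halfW <- noise@strokeWidthPx / 2
        for (i in seq_along(conns)) {
            k <- conns[i]
            aIdx <- pairs$dotA[pairs$canonicalIndex == k] + 1L
            bIdx <- pairs$dotB[pairs$canonicalIndex == k] + 1L
            sp <- .strokePath(centers[aIdx, ], centers[bIdx, ], noise, violate)
            res <- .paintPolyline(canvas, sp$pts, halfW, .INK_RED,
                                  noise@channelNoiseSd, trackInk = TRUE)
            canvas <- res$canvas
            if (!is.null(res$ink)) inkMask[res$ink] <- TRUE
            if (sp$violated) violated <- c(violated, i)
        }
    }
    expected <- if (length(violated)) designId(conns[-violated])
                else design
    list(raster = canvas, connections = conns, violated = violated,
         expectedDesign = as.integer(expected), inkMask = inkMask)
}

# Printed board elements of one cell (black dots + distractors), drawn in
# cell-local coordinates.
.paintCellBoard <- function(canvas, layout, part, cellIndex, centers) {
    dg <- .distractorGeometry(layout, part, cellIndex, local = TRUE)
    if (!is.null(dg)) {
        if (dg$kind == "diamonds") {
            for (m in seq_len(nrow(dg$centers)))
                canvas <- .paintDiamond(canvas, dg$centers[m, 1],
                                        dg$centers[m, 2], dg$sizePx)
        } else if (dg$kind == "lines") {
            lw <- max(1.2, 1.5 * layout@dpi / 300)
            for (m in seq_len(nrow(dg$centers))) {
                ang <- dg$angles[m]
                dv <- c(cos(ang), sin(ang)) * dg$sizePx
                pts <- rbind(dg$centers[m, ] - dv, dg$centers[m, ] + dv)
                canvas <- .paintPolyline(canvas, pts, lw / 2, c(0, 0, 0))$canvas
            }
        }
    }
    for (d in 1:5)
        canvas <- .paintDisk(canvas, centers[d, 1], centers[d, 2],
                             layout@dotRadiusPx)
    canvas
}

#' Render a synthetic protocol
#'
#' Renders the five pages of a scripted protocol: printed black dots and
#' distractors plus red respondent strokes under the given noise model.
#' Deterministic: identical script, layout and noise (including seed) give
#' bit-identical pages.
#'
#' @param script a [ProtocolScript].
#' @param layout a [BoardLayout].
#' @param noise a [StrokeNoiseModel]; its \code{seed} slot seeds the render.
#' @param keepInkMasks if TRUE, per-page logical masks of core ink pixels
#'   are kept in the ground truth (memory-heavy at full resolution).
#' @return a [RenderedProtocol]. Ground truth holds, per scripted cell, the
#'   drawn connections, the violating strokes and the expected recognized
#'   design (violating strokes excluded).
#' @export
renderProtocol <- function(script, layout = defaultBoardLayout(),
                           noise = strokeNoiseModel(dpi = layout@dpi),
                           keepInkMasks = FALSE) {
    stopifnot(is(script, "ProtocolScript"))
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(noise@seed)
    pages <- vector("list", 5L)
    cells <- vector("list", 5L)
    expectedDesigns <- matrix(0L, 5L, 35L)
    H <- layout@pageHeightPx; W <- layout@pageWidthPx
    for (p in 1:5) {
        page <- array(1, dim = c(H, W, 3))
        inkMask <- if (keepInkMasks) matrix(FALSE, H, W) else NULL
        cellGt <- vector("list", 35L)
        for (ci in 0:34) {
            d <- script@designs[p, ci + 1L]
            rc <- renderCell(layout, p, d, noise,
                             violate = script@violations[p, ci + 1L],
                             cellIndex = ci)
            box <- layout@cellBoxes[ci + 1L, ]
            i0 <- as.integer(round(box[2])) + 1L
            j0 <- as.integer(round(box[1])) + 1L
            hc <- dim(rc$raster)[1]; wc <- dim(rc$raster)[2]
            page[i0:(i0 + hc - 1L), j0:(j0 + wc - 1L), ] <- rc$raster
            if (keepInkMasks)
                inkMask[i0:(i0 + hc - 1L), j0:(j0 + wc - 1L)] <- rc$inkMask
            expectedDesigns[p, ci + 1L] <- rc$expectedDesign
            cellGt[[ci + 1L]] <- list(cellIndex = ci, design = d,
                                      connections = rc$connections,
                                      violated = rc$violated,
                                      expectedDesign = rc$expectedDesign)
        }
        pages[[p]] <- page
        cells[[p]] <- cellGt
        if (keepInkMasks) attr(pages[[p]], "inkMask") <- inkMask
    }
    new("RenderedProtocol", pages = pages,
        groundTruth = list(script = script, cells = cells,
                           expectedDesigns = expectedDesigns,
                           seed = noise@seed),
        layout = layout, noise = noise)
}
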