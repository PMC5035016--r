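# Shared fixtures: layouts are cached per resolution (construction parses
# YAML), and rendered cells are converted to CellInk via the same red
# segmentation the pipeline uses.

.layoutCache <- new.env(parent = emptyenv())

testLayout <- function(dpi = 300) {
    key <- as.character(dpi)
    if (is.null(.layoutCache[[key]]))
        .layoutCache[[key]] <- defaultBoardLayout(dpi)
    .layoutCache[[key]]
}

# CellInk from a renderCell() result (cell-local coordinates).
cellFromRender <- function(rc, layout, part = 1) {
    mask <- segmentRed(rc$raster)
    new("CellInk", cellIndex = 0L, redMask = mask,
        dotCenters = dotCenters(layout, part, 0L, local = TRUE),
        box = c(0, 0, ncol(mask), nrow(mask)))
}

# CellInk from an explicit logical mask and dot centers (constructed
# pixel-evidence tests).
cellFromMask <- function(mask, centers) {
    new("CellInk", cellIndex = 0L, redMask = mask, dotCenters = centers,
        box = c(0, 0, ncol(mask), nrow(mask)))
}

# Set mask pixels along the straight segment a-b (optionally only the
# [from, to] portion), with the given half-width.
paintMaskSegment <- function(mask, a, b, halfWidth = 2, from = 0, to = 1) {
    p0 <- a + from * (b - a)
    p1 <- a + to * (b - a)
    i0 <- max(1L, floor(min(p0[2], p1[2]) - halfWidth - 1))
    i1 <- min(nrow(mask), ceiling(max(p0[2], p1[2]) + halfWidth + 1))
    j0 <- max(1L, floor(min(p0[1], p1[1]) - halfWidth - 1))
    j1 <- min(ncol(mask), ceiling(max(p0[1], p1[1]) + halfWidth + 1))
    for (i in i0:i1) {
        for (j in j0:j1) {
            px <- c(j - 0.5, i - 0.5)
            v <- p1 - p0
            len2 <- sum(v^2)
            t <- if (len2 > 0) sum((px - p0) * v) / len2 else 0
            t <- min(1, max(0, t))
            d <- sqrt(sum((px - (p0 + t * v))^2))
            if (d <= halfWidth) mask[i, j] <- TRUE
        }
    }
    mask
}

# Canonical index of the connection between two dots (0-based dots).
connIndex <- function(a, b) {
    conns <- enumerateConnections(5L)
    conns$canonicalIndex[conns$dotA == min(a, b) & conns$dotB == max(a, b)]
}
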