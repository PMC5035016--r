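# Board model: cells, canonical connections and the design-ID encoding.
# Pure geometry and combinatorics; no imaging.

#' Enumerate the canonical connections of an n-dot pattern
#'
#' All unordered dot pairs in lexicographic order of (dotA, dotB). For the
#' RFFT five-dot pattern this yields the 10 canonical connections whose
#' fixed ordering underlies the design-ID bitmask: no more than ten
#' different connections can be drawn between any two dots of a five-dot
#' pattern.
#'
#' @param nDots number of dots, >= 2.
#' @return data.frame with columns \code{dotA}, \code{dotB} (0-based dot
#'   indices, dotA < dotB) and \code{canonicalIndex} (0-based).
#' @examples
#' enumerateConnections(5)   # the 10 RFFT connections
#' @export
enumerateConnections <- function(nDots = 5L) {
    if (!is.numeric(nDots) || length(nDots) != 1L || nDots < 2L ||
        nDots != round(nDots))
        stop("invalid argument: nDots must be a single integer >= 2")
    pairs <- t(combn(nDots, 2L)) - 1L
    data.frame(dotA = as.integer(pairs[, 1]), dotB = as.integer(pairs[, 2]),
               canonicalIndex = seq_len(nrow(pairs)) - 1L)
}

.asCanonicalIndices <- function(connections) {
    if (is.data.frame(connections)) {
        if (!"canonicalIndex" %in% names(connections))
            stop("invalid argument: connections data.frame lacks canonicalIndex")
        idx <- connections$canonicalIndex
    } else {
        idx <- connections
    }
    if (length(idx) == 0L) return(integer())
    if (any(is.na(idx)) || any(idx != round(idx)) || any(idx < 0 | idx > 9))
        stop("invalid argument: connection outside the canonical set of 10")
    sort(unique(as.integer(idx)))
}

#' Design ID of a set of connections
#'
#' Encodes a set of canonical connections as a 10-bit integer: bit k is set
#' iff the connection with canonical index k is present. The encoding is a
#' bijection between non-empty connection subsets and 1..1023; the empty
#' set maps to 0 ("no design").
#'
#' @param connections integer vector of canonical connection indices
#'   (0-based), or a data.frame as returned by [enumerateConnections()].
#' @return integer design ID in 0..1023.
#' @examples
#' designId(c(0, 1))          # connections 0-1 and 0-2 -> 3
#' designId(0:9)              # complete design -> 1023
#' @seealso [designFromId()], [countPossibleDesigns()]
#' @export
designId <- function(connections) {
    idx <- .asCanonicalIndices(connections)
    as.integer(sum(bitwShiftL(1L, idx)))
}

#' Connections of a design ID
#'
#' Inverse of [designId()]: decodes a 10-bit design ID into the canonical
#' connection indices present.
#'
#' @param mask integer design ID in 0..1023.
#' @return integer vector of canonical connection indices (0-based).
#' @export
designFromId <- function(mask) {
    if (length(mask) != 1L || is.na(mask) || mask != round(mask) ||
        mask < 0 || mask > 1023)
        stop("invalid argument: mask must be an integer in 0..1023")
    which(bitwAnd(as.integer(mask), bitwShiftL(1L, 0:9)) != 0L) - 1L
}

#' Count the possible designs
#'
#' Number of distinct non-empty subsets of the available canonical
#' connections, computed by exhaustive subset enumeration. With the full
#' set of 10 connections this is 1023, the number of different designs a
#' respondent can draw in one cell.
#'
#' @param nConnections number of available connections (default 10).
#' @return integer count of non-empty subsets.
#' @examples
#' countPossibleDesigns()    # 1023
#' countPossibleDesigns(3)   # 7
#' @export
countPossibleDesigns <- function(nConnections = 10L) {
    if (nConnections < 1L || nConnections != round(nConnections))
        stop("invalid argument: nConnections must be a positive integer")
    n <- 0L
    for (k in seq_len(nConnections))
        n <- n + ncol(combn(seq_len(nConnections), k))
    as.integer(n)
}

#' Cell bounding box
#'
#' Rectangle of the cell at (row, col) in page coordinates, consistent with
#' the row-major 0-based cell index mapping index = row * nCols + col.
#'
#' @param layout a [BoardLayout].
#' @param row,col 0-based grid position (0 <= row < 7, 0 <= col < 5).
#' @return numeric length-4 (x0, y0, x1, y1), origin top-left.
#' @export
cellBox <- function(layout, row, col) {
    stopifnot(is(layout, "BoardLayout"))
    if (length(row) != 1L || length(col) != 1L || is.na(row) || is.na(col) ||
        row < 0 || row >= layout@nRows || col < 0 || col >= layout@nCols ||
        row != round(row) || col != round(col))
        stop("invalid argument: row/col out of range")
    idx <- as.integer(row) * layout@nCols + as.integer(col)
    stats::setNames(layout@cellBoxes[idx + 1L, ], c("x0", "y0", "x1", "y1"))
}

#' Printed-dot centers of one cell
#'
#' Maps the part's normalized dot positions into the dot square of the
#' given cell, in page coordinates (or cell-local coordinates with
#' \code{local = TRUE}).
#'
#' @param layout a [BoardLayout].
#' @param part part number 1-5.
#' @param cellIndex 0-based row-major cell index (0..34).
#' @param local if TRUE, coordinates relative to the cell box origin.
#' @return 5 x 2 numeric matrix of (x, y) dot centers.
#' @export
dotCenters <- function(layout, part, cellIndex, local = FALSE) {
    stopifnot(is(layout, "BoardLayout"))
    if (part < 1L || part > 5L) stop("invalid argument: part must be 1..5")
    if (cellIndex < 0L || cellIndex > 34L)
        stop("invalid argument: cellIndex must be 0..34")
    box <- layout@cellBoxes[cellIndex + 1L, ]
    side <- layout@dotSquareSidePx
    ox <- (box[1] + box[3]) / 2 - side / 2
    oy <- (box[2] + box[4]) / 2 - side / 2
    pos <- layout@parts[[part]]@dotPositions
    out <- cbind(ox + pos[, 1] * side, oy + pos[, 2] * side)
    if (local) out <- sweep(out, 2, c(box[1], box[2]))
    dimnames(out) <- list(NULL, c("x", "y"))
    out
}

# Distractor geometry of one cell, in the same coordinates as dotCenters().
.distractorGeometry <- function(layout, part, cellIndex, local = FALSE) {
    dl <- layout@parts[[part]]
    if (dl@distractorKind == "none" || nrow(dl@distractorPositions) == 0L)
        return(NULL)
    box <- layout@cellBoxes[cellIndex + 1L, ]
    side <- layout@dotSquareSidePx
    ox <- (box[1] + box[3]) / 2 - side / 2
    oy <- (box[2] + box[4]) / 2 - side / 2
    pos <- cbind(ox + dl@distractorPositions[, 1] * side,
                 oy + dl@distractorPositions[, 2] * side)
    if (local) pos <- sweep(pos, 2, c(box[1], box[2]))
    list(kind = dl@distractorKind, centers = pos,
         sizePx = dl@distractorSize * side, angles = dl@distractorAngles)
}
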