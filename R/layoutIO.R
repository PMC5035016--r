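# Layout configuration I/O. The board geometry is fully parametric and
# loads from a YAML file so a licensed stimulus layout can be swapped in;
# the shipped default approximates the published description (regular
# pentagon in parts 1-3 with diamond/line distractors in parts 2-3, a
# rotated-pentagon variant in parts 4-5).

#' Read a board layout configuration
#'
#' Loads page, grid and dot geometry from a YAML layout file and builds a
#' [BoardLayout] at the requested resolution. All pixel quantities scale
#' linearly with \code{dpi}.
#'
#' @param path path to a layout YAML file.
#' @param dpi resolution in dots per inch; defaults to the file's value.
#' @return a [BoardLayout].
#' @seealso [defaultBoardLayout()]
#' @export
readBoardLayout <- function(path, dpi = NULL) {
    cfg <- yaml::read_yaml(path)
    if (is.null(dpi)) dpi <- cfg$dpi
    pageW <- as.integer(round(cfg$page_width_in * dpi))
    pageH <- as.integer(round(cfg$page_height_in * dpi))
    g <- cfg$grid
    nRows <- as.integer(g$n_rows)
    nCols <- as.integer(g$n_cols)
    x0 <- g$margin_left_in * dpi
    y0 <- g$margin_top_in * dpi
    cw <- (pageW - (g$margin_left_in + g$margin_right_in) * dpi) / nCols
    ch <- (pageH - (g$margin_top_in + g$margin_bottom_in) * dpi) / nRows
    boxes <- matrix(0, nRows * nCols, 4)
    for (r in seq_len(nRows) - 1L) {
        for (c in seq_len(nCols) - 1L) {
            boxes[r * nCols + c + 1L, ] <- c(x0 + c * cw, y0 + r * ch,
                                             x0 + (c + 1) * cw, y0 + (r + 1) * ch)
        }
    }
    parts <- lapply(cfg$parts, function(p) {
        dots <- do.call(rbind, p$dots)
        dpos <- if (!is.null(p$distractors))
            do.call(rbind, p$distractors) else matrix(0, 0, 2)
        new("DotLayout",
            partNumber = as.integer(p$part),
            dotPositions = dots,
            distractorKind = if (is.null(p$distractor_kind)) "none"
                             else p$distractor_kind,
            distractorPositions = dpos,
            distractorSize = if (is.null(p$distractor_size)) 0
                             else p$distractor_size,
            distractorAngles = if (is.null(p$distractor_angles)) numeric()
                               else as.numeric(p$distractor_angles))
    })
    parts <- parts[order(vapply(parts, function(p) p@partNumber, integer(1)))]
    new("BoardLayout",
        name = if (is.null(cfg$name)) basename(path) else cfg$name,
        dpi = dpi,
        pageWidthPx = pageW, pageHeightPx = pageH,
        nRows = nRows, nCols = nCols,
        cellBoxes = boxes,
        dotSquareSidePx = cfg$dot_square_frac * min(cw, ch),
        dotRadiusPx = cfg$dot_radius_in * dpi,
        parts = parts)
}

#' Default synthetic RFFT board layout
#'
#' The layout shipped with the package: US-letter page, 7 x 5 cells, a
#' regular pentagon in parts 1-3 (diamond distractors in part 2, line
#' distractors in part 3) and the pentagon rotated 180 degrees in parts
#' 4-5. This is a documented approximation, not the licensed RFFT
#' stimulus artwork.
#'
#' @param dpi resolution in dots per inch (default 300, the scan
#'   resolution of the original protocols).
#' @return a [BoardLayout].
#' @examples
#' defaultBoardLayout(150)
#' @export
defaultBoardLayout <- function(dpi = 300) {
    readBoardLayout(system.file("extdata", "layouts", "default_rfft.yaml",
                                package = "rfftscan", mustWork = TRUE),
                    dpi = dpi)
}
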