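# End-to-end pipeline: page -> recognized cells -> protocol scores, plus
# batch entry points (score a directory of scans, simulate a synthetic
# dataset, agreement report from score files). Protocols on disk follow
# the filename convention <protocol_id>_part<1-5>.png.

#' Recognize all cells of one page
#'
#' Segments red ink, registers the layout, crops the 35 cells and runs the
#' five-task recognition in each.
#'
#' @param page a [PageImage] or H x W x 3 raster array.
#' @param part part number 1-5 (taken from the PageImage if given).
#' @param layout a [BoardLayout].
#' @param config a [RecognitionConfig].
#' @return list of 35 [RecognizedCell]; attributes \code{registration} and
#'   \code{droppedPixels}.
#' @export
recognizePage <- function(page, part = NULL, layout = defaultBoardLayout(),
                          config = recognitionConfig(layout)) {
    if (is(page, "PageImage") && is.null(part)) part <- page@part
    red <- segmentRed(page, config@hueToleranceDeg, config@minSaturation,
                      config@minValue)
    reg <- registerLayout(page, layout, part,
                          minMatchedFraction = config@minMatchedFraction,
                          maxResidualPx = config@maxResidualPx)
    cells <- cropCells(page, red, reg, layout)
    out <- lapply(cells, recognizeCell, config = config)
    attr(out, "registration") <- reg
    attr(out, "droppedPixels") <- attr(cells, "droppedPixels")
    out
}

#' Score a protocol from its five page images
#'
#' @param pages list of five [PageImage] objects or raster arrays
#'   (parts 1-5 in order).
#' @param layout a [BoardLayout].
#' @param config a [RecognitionConfig].
#' @param perseverationScope see [scoreProtocol()].
#' @return a [ProtocolScore]; attribute \code{cells} holds the per-part
#'   recognized cells.
#' @export
scorePages <- function(pages, layout = defaultBoardLayout(),
                       config = recognitionConfig(layout),
                       perseverationScope = "part") {
    stopifnot(length(pages) == 5L)
    parts <- vector("list", 5L)
    for (p in 1:5)
        parts[[p]] <- recognizePage(pages[[p]], part = p, layout = layout,
                                    config = config)
    score <- scoreProtocol(parts, perseverationScope = perseverationScope)
    attr(score, "cells") <- parts
    score
}

#' Score a rendered synthetic protocol in memory
#'
#' @param rendered a [RenderedProtocol].
#' @param config a [RecognitionConfig] (defaults to the rendered layout's).
#' @return a [ProtocolScore] (see [scorePages()]).
#' @export
scoreRendered <- function(rendered,
                          config = recognitionConfig(rendered@layout)) {
    scorePages(rendered@pages, layout = rendered@layout, config = config)
}

#' Score a directory of scanned protocols
#'
#' Scans \code{dir} for files named \code{<protocol_id>_part<1-5>.png},
#' groups them per protocol and scores each. Protocols with missing parts
#' or failed registration produce an error row (and, without
#' \code{skipFailures}, an error at the end).
#'
#' @param dir directory of PNG pages.
#' @param layout a [BoardLayout].
#' @param config a [RecognitionConfig].
#' @param outCsv optional path; when given the score table is written as
#'   CSV.
#' @param skipFailures if TRUE, per-protocol failures become warnings.
#' @param dpi scan resolution.
#' @return data.frame with one row per protocol (see [scoreRow()]); failed
#'   protocols have NA scores and an \code{error} message.
#' @export
scoreProtocolDir <- function(dir, layout = defaultBoardLayout(),
                             config = recognitionConfig(layout),
                             outCsv = NULL, skipFailures = FALSE,
                             dpi = layout@dpi) {
    files <- list.files(dir, pattern = "_part[1-5]\\.png$", ignore.case = TRUE)
    ids <- unique(sub("_part[1-5]\\.png$", "", files, ignore.case = TRUE))
    rows <- list()
    failures <- character()
    for (id in sort(ids)) {
        res <- tryCatch({
            paths <- file.path(dir, sprintf("%s_part%d.png", id, 1:5))
            missing <- !file.exists(paths)
            if (any(missing))
                stop(sprintf("missing parts: %s",
                             paste(which(missing), collapse = ",")))
            pages <- lapply(1:5, function(p) readPage(paths[p], p, dpi))
            score <- scorePages(pages, layout, config)
            row <- scoreRow(score, id)
            row$error <- ""
            row
        }, error = function(e) {
            failures <<- c(failures, id)
            row <- scoreRow(.emptyScore(), id)
            row[, !(names(row) %in% c("protocol", "complete"))] <- NA
            row$complete <- FALSE
            row$error <- conditionMessage(e)
            row
        })
        rows[[id]] <- res
    }
    out <- if (length(rows)) do.call(rbind, rows) else {
        template <- scoreRow(.emptyScore(), "none")
        template$error <- ""
        template[0, , drop = FALSE]
    }
    rownames(out) <- NULL
    if (!is.null(outCsv)) write.csv(out, outCsv, row.names = FALSE)
    if (length(failures)) {
        msg <- sprintf("%d protocol(s) failed: %s", length(failures),
                       paste(failures, collapse = ", "))
        if (skipFailures) warning(msg) else stop(msg)
    }
    out
}

.emptyScore <- function() {
    rows <- lapply(1:5, function(p)
        data.frame(part = p, attempted = 0L, uniqueDesigns = 0L,
                   perseverativeErrors = 0L, violations = 0L,
                   unscorable = 0L))
    .protocolScoreFromParts(rows)
}

#' Simulate a synthetic protocol dataset on disk
#'
#' Renders \code{n} random protocols as PNG pages (named
#' \code{<id>_part<1-5>.png}), writes a ground-truth JSON per protocol
#' (script, per-cell connections, violation flags, seed, noise) and a
#' ground-truth score CSV for the whole set. Deterministic given
#' \code{seed}.
#'
#' @param n number of protocols (>= 1).
#' @param dir output directory (created if needed).
#' @param layout a [BoardLayout].
#' @param noise a [StrokeNoiseModel]; its seed is combined with the
#'   protocol index.
#' @param nFilledCellsPerPart,perseverationRate,violationRate script
#'   generation parameters (see [randomScript()]).
#' @param seed master RNG seed.
#' @return invisibly, the ground-truth score data.frame.
#' @export
simulateProtocolSet <- function(n, dir, layout = defaultBoardLayout(),
                                noise = strokeNoiseModel(dpi = layout@dpi),
                                nFilledCellsPerPart = 18L,
                                perseverationRate = 0.15,
                                violationRate = 0, seed = 1L) {
    if (n < 1L) stop("invalid argument: n must be >= 1")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        id <- sprintf("sim%03d", i)
        protoSeed <- (seed + 7919L * i) %% .Machine$integer.max
        script <- randomScript(nFilledCellsPerPart, perseverationRate,
                               seed = protoSeed,
                               violationRate = violationRate)
        noiseI <- noise
        noiseI@seed <- as.integer(protoSeed)
        rendered <- renderProtocol(script, layout, noiseI)
        for (p in 1:5)
            png::writePNG(rendered@pages[[p]],
                          file.path(dir, sprintf("%s_part%d.png", id, p)))
        gt <- rendered@groundTruth
        jsonlite::write_json(
            list(protocol = id, seed = protoSeed,
                 noise = list(jitterSdPx = noiseI@jitterSdPx,
                              curvatureAmplitudePx = noiseI@curvatureAmplitudePx,
                              strokeWidthPx = noiseI@strokeWidthPx,
                              endpointShortfallPx = noiseI@endpointShortfallPx,
                              overshootPx = noiseI@overshootPx,
                              violationProbability = noiseI@violationProbability),
                 designs = script@designs,
                 violations = script@violations,
                 expectedDesigns = gt$expectedDesigns),
            file.path(dir, paste0(id, "_truth.json")),
            auto_unbox = TRUE, digits = NA)
        rows[[i]] <- scoreRow(scoreScript(script), id)
    }
    truth <- do.call(rbind, rows)
    write.csv(truth, file.path(dir, "ground_truth_scores.csv"),
              row.names = FALSE)
    invisible(truth)
}

#' Agreement report for two score files
#'
#' Reads two CSV score tables (one row per protocol; a \code{protocol} or
#' \code{subject_id} column plus the measure column), matches protocols by
#' id (unmatched ids are listed and excluded with a warning) and computes
#' ICC(A,1), Lin's CCC and Bland-Altman limits for the chosen measure.
#'
#' @param fileX,fileY CSV paths; x is reported as the first assessment in
#'   the difference convention x - y.
#' @param measure column name to compare (default "unique_total").
#' @param outCsv optional path for a one-row CSV report.
#' @return list with the three [AgreementResult] objects, the matched n
#'   and the excluded ids.
#' @export
agreementFromFiles <- function(fileX, fileY, measure = "unique_total",
                               outCsv = NULL) {
    readScores <- function(f) {
        d <- read.csv(f)
        idCol <- intersect(c("protocol", "subject_id", "id"), names(d))[1]
        if (is.na(idCol)) stop("no protocol/subject_id column in ", f)
        if (!measure %in% names(d))
            stop(sprintf("measure '%s' not found in %s", measure, f))
        data.frame(id = as.character(d[[idCol]]), value = d[[measure]])
    }
    x <- readScores(fileX)
    y <- readScores(fileY)
    common <- intersect(x$id, y$id)
    excluded <- setdiff(union(x$id, y$id), common)
    if (length(excluded))
        warning("unmatched ids excluded: ", paste(excluded, collapse = ", "))
    if (length(common) < 3L)
        stop("invalid argument: fewer than 3 matched protocols")
    xv <- x$value[match(common, x$id)]
    yv <- y$value[match(common, y$id)]
    icc <- iccAbsoluteSingle(cbind(xv, yv))
    ccc <- tryCatch(linCcc(xv, yv), error = function(e) NULL)
    ba <- blandAltman(xv, yv)
    if (!is.null(outCsv)) {
        write.csv(data.frame(measure = measure, n = length(common),
                             icc = icc@estimate, icc_lower = icc@ciLower,
                             icc_upper = icc@ciUpper, icc_p = icc@pValue,
                             ccc = if (is.null(ccc)) NA else ccc@estimate,
                             mean_difference = ba@details$meanDifference,
                             sd_difference = ba@details$sdDifference,
                             loa_lower = ba@details$loaLower,
                             loa_upper = ba@details$loaUpper),
                  outCsv, row.names = FALSE)
    }
    list(icc = icc, ccc = ccc, blandAltman = ba, n = length(common),
         excluded = excluded)
}
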