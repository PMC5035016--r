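#' @import methods
#' @importFrom stats rnorm runif sd var cor pf qf qnorm quantile
#' @importFrom utils combn read.csv write.csv head
NULL

# ---- geometry -------------------------------------------------------------

#' DotLayout: the five-dot pattern of one RFFT part
#'
#' Normalized geometry of the printed stimulus in one part of the Ruff
#' Figural Fluency Test: five dot positions in the unit square (origin
#' top-left, x rightward, y downward) plus the part's distractor elements
#' (diamonds in part 2, short lines in part 3, none elsewhere).
#'
#' @slot partNumber integer, 1-5.
#' @slot dotPositions 5 x 2 numeric matrix of normalized (x, y) positions.
#' @slot distractorKind "none", "diamonds" or "lines".
#' @slot distractorPositions m x 2 numeric matrix (may have zero rows).
#' @slot distractorSize numeric, normalized half-size of a distractor
#'   (half-diagonal of a diamond, half-length of a line).
#' @slot distractorAngles numeric vector of line orientations in radians
#'   (length m for kind "lines", else length 0).
#' @exportClass DotLayout
setClass("DotLayout", representation(
    partNumber = "integer",
    dotPositions = "matrix",
    distractorKind = "character",
    distractorPositions = "matrix",
    distractorSize = "numeric",
    distractorAngles = "numeric"
))

setValidity("DotLayout", function(object) {
    msg <- character()
    p <- object@partNumber
    if (length(p) != 1L || is.na(p) || p < 1L || p > 5L)
        msg <- c(msg, "partNumber must be a single integer in 1..5")
    dp <- object@dotPositions
    if (!is.numeric(dp) || nrow(dp) != 5L || ncol(dp) != 2L)
        msg <- c(msg, "dotPositions must be a 5 x 2 numeric matrix")
    else {
        if (any(dp < 0 | dp > 1))
            msg <- c(msg, "dot positions must lie in the unit square")
        if (anyDuplicated(round(dp, 12)) > 0L)
            msg <- c(msg, "dot positions must be pairwise distinct")
    }
    expected <- c("none", "diamonds", "lines", "none", "none")
    if (length(p) == 1L && !is.na(p) && p >= 1L && p <= 5L &&
        !identical(object@distractorKind, expected[p]))
        msg <- c(msg, sprintf("part %d must have distractor kind '%s'",
                              p, expected[p]))
    if (length(msg)) msg else TRUE
})

#' BoardLayout: page and grid geometry of an RFFT protocol
#'
#' Pixel geometry of one scanned protocol page at a given resolution: the
#' 7 x 5 arrangement of 35 cells, the dot square inside each cell onto which
#' the normalized five-dot pattern is mapped, the printed dot radius, and
#' the per-part [DotLayout] patterns. Cell indices are 0-based and
#' row-major: cell index = row * 5 + col.
#'
#' @slot name character layout name.
#' @slot dpi numeric scan resolution in dots per inch.
#' @slot pageWidthPx,pageHeightPx integer page size in pixels.
#' @slot nRows,nCols integer grid shape (7 and 5).
#' @slot cellBoxes 35 x 4 numeric matrix (x0, y0, x1, y1) of cell rectangles
#'   in page coordinates (0-based, origin top-left), row-major order.
#' @slot dotSquareSidePx numeric side of the centered square inside a cell
#'   onto which normalized dot coordinates are mapped.
#' @slot dotRadiusPx numeric printed dot radius in pixels.
#' @slot parts list of five [DotLayout] objects.
#' @exportClass BoardLayout
setClass("BoardLayout", representation(
    name = "character",
    dpi = "numeric",
    pageWidthPx = "integer",
    pageHeightPx = "integer",
    nRows = "integer",
    nCols = "integer",
    cellBoxes = "matrix",
    dotSquareSidePx = "numeric",
    dotRadiusPx = "numeric",
    parts = "list"
))

setValidity("BoardLayout", function(object) {
    msg <- character()
    if (object@nRows != 7L || object@nCols != 5L)
        msg <- c(msg, "grid must be 7 rows x 5 columns")
    b <- object@cellBoxes
    if (nrow(b) != 35L || ncol(b) != 4L)
        msg <- c(msg, "cellBoxes must be a 35 x 4 matrix")
    else {
        if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
            msg <- c(msg, "cell boxes must have positive extent")
        # non-overlap: row-major tiling implies x0 of col c+1 >= x1 of col c
        for (r in 0:6) {
            idx <- r * 5L + 1:5
            if (any(diff(b[idx, 1]) < b[idx[-5], 3] - b[idx[-5], 1] - 1e-9))
                msg <- c(msg, "cell boxes overlap within a row")
        }
    }
    if (length(object@parts) != 5L ||
        !all(vapply(object@parts, is, logical(1), "DotLayout")))
        msg <- c(msg, "parts must be a list of five DotLayout objects")
    if (object@dotRadiusPx <= 0)
        msg <- c(msg, "dotRadiusPx must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BoardLayout", function(object) {
    cat(sprintf("BoardLayout '%s': %d x %d px at %g dpi, %d x %d cells, dot radius %.1f px\n",
                object@name, object@pageWidthPx, object@pageHeightPx,
                object@dpi, object@nRows, object@nCols, object@dotRadiusPx))
    kinds <- vapply(object@parts, function(p) p@distractorKind, character(1))
    cat("  parts 1-5 distractors:", paste(kinds, collapse = ", "), "\n")
})

# ---- synthetic rendering --------------------------------------------------

#' StrokeNoiseModel: hand-drawing noise for the synthetic renderer
#'
#' Parameters of the noise applied to respondent strokes when rendering
#' synthetic protocol pages. All distances are pixels at the layout
#' resolution. Identical seeds give bit-identical renders.
#'
#' @slot jitterSdPx Gaussian SD of perpendicular endpoint displacement.
#' @slot curvatureAmplitudePx maximum bow of the quadratic arc replacing a
#'   straight stroke (uniform in +/- amplitude).
#' @slot strokeWidthPx full stroke width.
#' @slot endpointShortfallPx distance by which strokes stop short of dot
#'   centers.
#' @slot overshootPx distance strokes extend past dot centers in violation
#'   mode ("crossed the dots").
#' @slot violationProbability probability that a stroke is drawn in
#'   violation mode.
#' @slot channelNoiseSd SD of per-pixel RGB channel noise on ink.
#' @slot seed integer RNG seed used by [renderProtocol()].
#' @exportClass StrokeNoiseModel
setClass("StrokeNoiseModel", representation(
    jitterSdPx = "numeric",
    curvatureAmplitudePx = "numeric",
    strokeWidthPx = "numeric",
    endpointShortfallPx = "numeric",
    overshootPx = "numeric",
    violationProbability = "numeric",
    channelNoiseSd = "numeric",
    seed = "integer"
))

setValidity("StrokeNoiseModel", function(object) {
    msg <- character()
    for (s in c("jitterSdPx", "curvatureAmplitudePx", "strokeWidthPx",
                "endpointShortfallPx", "overshootPx", "channelNoiseSd"))
        if (slot(object, s) < 0)
            msg <- c(msg, paste(s, "must be >= 0"))
    vp <- object@violationProbability
    if (vp < 0 || vp > 1)
        msg <- c(msg, "violationProbability must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StrokeNoiseModel", function(object) {
    cat(sprintf(paste0("StrokeNoiseModel: jitter %.2g px, bow %.2g px, width %.2g px, ",
                       "shortfall %.2g px, overshoot %.2g px, P(violation) %.2g, seed %d\n"),
                object@jitterSdPx, object@curvatureAmplitudePx,
                object@strokeWidthPx, object@endpointShortfallPx,
                object@overshootPx, object@violationProbability, object@seed))
})

#' ProtocolScript: scripted designs for one synthetic protocol
#'
#' A 5 x 35 matrix of design IDs (0 = blank cell) plus a matching logical
#' matrix flagging cells whose strokes are drawn in violation mode.
#'
#' @slot designs 5 x 35 integer matrix of design IDs in 0..1023.
#' @slot violations 5 x 35 logical matrix.
#' @exportClass ProtocolScript
setClass("ProtocolScript", representation(
    designs = "matrix",
    violations = "matrix"
))

setValidity("ProtocolScript", function(object) {
    msg <- character()
    d <- object@designs
    if (!is.numeric(d) || nrow(d) != 5L || ncol(d) != 35L)
        msg <- c(msg, "designs must be a 5 x 35 numeric matrix")
    else if (any(d < 0 | d > 1023 | d != round(d)))
        msg <- c(msg, "design IDs must be integers in 0..1023")
    v <- object@violations
    if (!is.logical(v) || nrow(v) != 5L || ncol(v) != 35L)
        msg <- c(msg, "violations must be a 5 x 35 logical matrix")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ProtocolScript", function(object) {
    filled <- rowSums(object@designs > 0)
    cat("ProtocolScript: filled cells per part:",
        paste(filled, collapse = ", "),
        sprintf("(%d violation-mode cells)\n", sum(object@violations)))
})

#' RenderedProtocol: synthetic pages plus machine-readable ground truth
#'
#' @slot pages list of five H x W x 3 numeric arrays in [0, 1].
#' @slot groundTruth list with elements \code{script}, \code{cells} (per
#'   part, per scripted cell: connection indices, violated stroke indices,
#'   expected recognized design) and \code{expectedDesigns} (5 x 35 matrix
#'   of design IDs after excluding violating strokes).
#' @slot layout the [BoardLayout] used.
#' @slot noise the [StrokeNoiseModel] used.
#' @exportClass RenderedProtocol
setClass("RenderedProtocol", representation(
    pages = "list",
    groundTruth = "list",
    layout = "BoardLayout",
    noise = "StrokeNoiseModel"
))

setMethod("show", "RenderedProtocol", function(object) {
    cat(sprintf("RenderedProtocol: 5 pages %d x %d px, %d scripted cells\n",
                object@layout@pageWidthPx, object@layout@pageHeightPx,
                sum(object@groundTruth$script@designs > 0)))
})

# ---- ingestion ------------------------------------------------------------

#' PageImage: one scanned protocol page
#'
#' @slot raster H x W x 3 numeric array, channels in [0, 1].
#' @slot dpi numeric scan resolution.
#' @slot part integer part number 1-5.
#' @exportClass PageImage
setClass("PageImage", representation(
    raster = "array",
    dpi = "numeric",
    part = "integer"
))

setValidity("PageImage", function(object) {
    d <- dim(object@raster)
    if (length(d) != 3L || d[3] < 3L)
        return("raster must be an H x W x 3 color array")
    if (object@part < 1L || object@part > 5L)
        return("part must be in 1..5")
    TRUE
})

setMethod("show", "PageImage", function(object) {
    d <- dim(object@raster)
    cat(sprintf("PageImage: part %d, %d x %d px at %g dpi\n",
                object@part, d[2], d[1], object@dpi))
})

#' LayoutRegistration: fitted similarity transform layout -> image
#'
#' @slot scale,rotationRad numeric similarity parameters.
#' @slot translation numeric length-2 (tx, ty) in pixels.
#' @slot meanResidualPx,maxResidualPx numeric fit residuals over matched dots.
#' @slot matchedFraction fraction of expected printed dots matched.
#' @slot dotCenters list of 35 matrices (5 x 2), printed-dot centers per
#'   cell in image coordinates.
#' @slot cellCorners list of 35 matrices (4 x 2), transformed cell corners.
#' @exportClass LayoutRegistration
setClass("LayoutRegistration", representation(
    scale = "numeric",
    rotationRad = "numeric",
    translation = "numeric",
    meanResidualPx = "numeric",
    maxResidualPx = "numeric",
    matchedFraction = "numeric",
    dotCenters = "list",
    cellCorners = "list"
))

setMethod("show", "LayoutRegistration", function(object) {
    cat(sprintf(paste0("LayoutRegistration: scale %.4f, rotation %.3f deg, ",
                       "translation (%.2f, %.2f) px, mean residual %.2f px, ",
                       "%.0f%% dots matched\n"),
                object@scale, object@rotationRad * 180 / pi,
                object@translation[1], object@translation[2],
                object@meanResidualPx, 100 * object@matchedFraction))
})

#' CellInk: respondent ink cropped to one cell
#'
#' @slot cellIndex integer 0-based row-major cell index (0..34).
#' @slot redMask logical matrix of respondent-ink pixels, cell-local.
#' @slot dotCenters 5 x 2 numeric matrix of printed-dot centers in
#'   cell-local continuous coordinates.
#' @slot box numeric length-4 (x0, y0, x1, y1) of the cell crop in page
#'   coordinates.
#' @exportClass CellInk
setClass("CellInk", representation(
    cellIndex = "integer",
    redMask = "matrix",
    dotCenters = "matrix",
    box = "numeric"
))

setValidity("CellInk", function(object) {
    msg <- character()
    if (object@cellIndex < 0L || object@cellIndex > 34L)
        msg <- c(msg, "cellIndex must be in 0..34")
    if (!is.logical(object@redMask))
        msg <- c(msg, "redMask must be logical")
    if (nrow(object@dotCenters) != 5L || ncol(object@dotCenters) != 2L)
        msg <- c(msg, "dotCenters must be 5 x 2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CellInk", function(object) {
    cat(sprintf("CellInk: cell %d, %d red pixels in %d x %d crop\n",
                object@cellIndex, sum(object@redMask),
                ncol(object@redMask), nrow(object@redMask)))
})

# ---- recognition ----------------------------------------------------------

#' ActiveDotSet: dots touched by respondent ink in one cell
#'
#' @slot active logical length-5 flags.
#' @slot evidence integer length-5 red-pixel counts within the activation
#'   radius of each dot center.
#' @exportClass ActiveDotSet
setClass("ActiveDotSet", representation(
    active = "logical",
    evidence = "integer"
))

setMethod("show", "ActiveDotSet", function(object) {
    cat("ActiveDotSet: dots", paste(which(object@active) - 1L, collapse = ", "),
        "active (evidence", paste(object@evidence, collapse = "/"), "px)\n")
})

#' PixelAssignment: red pixels designated to candidate connections
#'
#' @slot px n x 2 numeric matrix of red-pixel centers (x, y), cell-local.
#' @slot candidate integer length-n canonical connection index (0-based)
#'   each pixel is designated to, or NA if unassigned.
#' @slot t numeric length-n projection parameter of each pixel onto its
#'   candidate segment (0 at dot A, 1 at dot B; clamped), NA if unassigned.
#' @slot candidates data.frame of the candidate connections considered.
#' @exportClass PixelAssignment
setClass("PixelAssignment", representation(
    px = "matrix",
    candidate = "integer",
    t = "numeric",
    candidates = "data.frame"
))

setMethod("show", "PixelAssignment", function(object) {
    n <- nrow(object@px)
    cat(sprintf("PixelAssignment: %d red pixels, %d candidates, %.1f%% unassigned\n",
                n, nrow(object@candidates),
                if (n) 100 * mean(is.na(object@candidate)) else 0))
})

#' RecognizedCell: recognition output for one cell
#'
#' @slot cellIndex integer 0-based cell index.
#' @slot activeDots logical length-5.
#' @slot trueConnections integer vector of canonical connection indices
#'   (0-based) accepted as true connections.
#' @slot design integer design ID in 0..1023 (0 = blank or unscorable).
#' @slot violations integer count of strokes crossing through dots.
#' @slot unassignedFraction numeric fraction of red pixels left unassigned.
#' @slot hasInk logical, any red pixels present.
#' @slot unscorable logical, red ink present but no true connections and no
#'   violations.
#' @slot diagnostics data.frame of per-candidate decisions with reasons.
#' @exportClass RecognizedCell
setClass("RecognizedCell", representation(
    cellIndex = "integer",
    activeDots = "logical",
    trueConnections = "integer",
    design = "integer",
    violations = "integer",
    unassignedFraction = "numeric",
    hasInk = "logical",
    unscorable = "logical",
    diagnostics = "data.frame"
))

setMethod("show", "RecognizedCell", function(object) {
    cat(sprintf("RecognizedCell: cell %d, design %d (connections: %s), %d violation(s)%s\n",
                object@cellIndex, object@design,
                if (length(object@trueConnections))
                    paste(object@trueConnections, collapse = ",") else "none",
                object@violations,
                if (object@unscorable) " [unscorable ink]" else ""))
})

# ---- scoring --------------------------------------------------------------

#' ProtocolScore: RFFT scores for one protocol
#'
#' Per-part and total unique designs, perseverative errors and violations.
#' Use [uniqueDesigns()], [perseverativeErrors()] and [violationCount()] for
#' totals, and [partScores()] for the per-part table.
#'
#' @slot parts data.frame with one row per part: part, attempted,
#'   uniqueDesigns, perseverativeErrors, violations, unscorable.
#' @slot complete logical, FALSE when parts were missing at scoring time.
#' @exportClass ProtocolScore
setClass("ProtocolScore", representation(
    parts = "data.frame",
    complete = "logical"
))

setValidity("ProtocolScore", function(object) {
    p <- object@parts
    need <- c("part", "attempted", "uniqueDesigns", "perseverativeErrors",
              "violations", "unscorable")
    if (!all(need %in% names(p)))
        return(paste("parts must have columns:", paste(need, collapse = ", ")))
    if (any(p$uniqueDesigns + p$perseverativeErrors != p$attempted))
        return("uniqueDesigns + perseverativeErrors must equal attempted in every part")
    TRUE
})

setMethod("show", "ProtocolScore", function(object) {
    cat("ProtocolScore", if (!object@complete) "(incomplete)" else "", "\n")
    print(object@parts, row.names = FALSE)
    cat(sprintf("  total: %d unique, %d perseverative, %d violations\n",
                uniqueDesigns(object), perseverativeErrors(object),
                violationCount(object)))
})

# ---- agreement ------------------------------------------------------------

#' AgreementResult: one agreement statistic for paired assessments
#'
#' @slot method "icc(A,1)", "lin-ccc" or "bland-altman".
#' @slot estimate point estimate (ICC or CCC; mean difference for
#'   Bland-Altman).
#' @slot ciLower,ciUpper 95 percent confidence bounds (NA where undefined).
#' @slot pValue p-value for the null of zero agreement (ICC only, else NA).
#' @slot n number of paired subjects.
#' @slot details list of method-specific values; for Bland-Altman:
#'   meanDifference, sdDifference, loaLower, loaUpper and the difference
#'   convention ("x - y").
#' @exportClass AgreementResult
setClass("AgreementResult", representation(
    method = "character",
    estimate = "numeric",
    ciLower = "numeric",
    ciUpper = "numeric",
    pValue = "numeric",
    n = "integer",
    details = "list"
))

setMethod("show", "AgreementResult", function(object) {
    if (object@method == "bland-altman") {
        d <- object@details
        cat(sprintf(paste0("Bland-Altman (%s): mean difference %.2f (SD %.2f), ",
                           "95%% limits of agreement %.2f to %.2f, n = %d\n"),
                    d$convention, d$meanDifference, d$sdDifference,
                    d$loaLower, d$loaUpper, object@n))
    } else {
        cat(sprintf("%s: %.3f (95%% CI %.3f to %.3f)%s, n = %d\n",
                    object@method, object@estimate, object@ciLower,
                    object@ciUpper,
                    if (!is.na(object@pValue))
                        sprintf(", p = %.3g", object@pValue) else "",
                    object@n))
    }
})

#' RecognitionConfig: thresholds of the recognition pipeline
#'
#' All pixel thresholds are absolute at the layout resolution; the
#' [recognitionConfig()] constructor scales its defaults linearly with
#' dpi / 300.
#'
#' @slot activationRadiusPx radius around a dot center within which red
#'   pixels count as touching the dot.
#' @slot minActivationPixels minimum red pixels to activate a dot.
#' @slot corridorHalfwidthPx half-width of the pixel-assignment corridor
#'   around a candidate segment.
#' @slot coverageThreshold minimum covered fraction of a candidate segment.
#' @slot maxGapFraction maximum projection gap as a fraction of length.
#' @slot overshootThresholdPx extension past a dot center beyond which a
#'   stroke counts as a procedure violation.
#' @slot minViolationPixels minimum pixels past the threshold to flag a
#'   violation.
#' @slot minIndependentPixels minimum pixels of independent support that
#'   save a collinear long candidate from subsumption.
#' @slot countViolationsAsDesigns if TRUE, violating strokes still count as
#'   true connections (the human raters' liberal reading).
#' @slot hueToleranceDeg,minSaturation,minValue red-ink HSV window.
#' @slot minMatchedFraction,maxResidualPx registration acceptance limits.
#' @exportClass RecognitionConfig
setClass("RecognitionConfig", representation(
    activationRadiusPx = "numeric",
    minActivationPixels = "integer",
    corridorHalfwidthPx = "numeric",
    coverageThreshold = "numeric",
    maxGapFraction = "numeric",
    overshootThresholdPx = "numeric",
    minViolationPixels = "integer",
    minIndependentPixels = "integer",
    countViolationsAsDesigns = "logical",
    hueToleranceDeg = "numeric",
    minSaturation = "numeric",
    minValue = "numeric",
    minMatchedFraction = "numeric",
    maxResidualPx = "numeric"
))

setMethod("show", "RecognitionConfig", function(object) {
    cat(sprintf(paste0("RecognitionConfig: activation r %.1f px (>= %d px), ",
                       "corridor %.1f px, coverage >= %.2f, gap <= %.2f, ",
                       "overshoot > %.1f px\n"),
                object@activationRadiusPx, object@minActivationPixels,
                object@corridorHalfwidthPx, object@coverageThreshold,
                object@maxGapFraction, object@overshootThresholdPx))
})
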