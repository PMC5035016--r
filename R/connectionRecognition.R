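# The five-task connection-recognition algorithm: from a cell's red-ink
# mask and printed-dot centers, decide which of the 10 candidate
# connections are true connections, and count procedure violations
# (strokes that cross through the dots instead of stopping at them).

#' Construct a recognition configuration
#'
#' All pixel defaults are stated at 300 dpi and scale linearly with
#' \code{dpi / 300}; radii built from the printed dot radius use the
#' layout's value.
#'
#' @param layout a [BoardLayout]; supplies dpi and dot radius.
#' @param activationRadiusPx radius around a dot center within which red
#'   pixels count as touching the dot (default dot radius + 4 px).
#' @param minActivationPixels minimum red pixels to activate a dot.
#' @param corridorHalfwidthPx assignment corridor half-width (default dot
#'   radius + 3 px).
#' @param coverageThreshold minimum covered fraction of a candidate
#'   segment for line compatibility.
#' @param maxGapFraction maximum projection gap as a fraction of segment
#'   length.
#' @param overshootThresholdPx extension past a dot center beyond which a
#'   stroke is a procedure violation (default 12 px, about 1 mm at 300
#'   dpi).
#' @param minViolationPixels minimum pixels past the threshold to flag a
#'   violation.
#' @param minIndependentPixels independent-support pixel count that saves
#'   a collinear long candidate from false-positive removal.
#' @param countViolationsAsDesigns if TRUE, violating strokes still count
#'   as true connections (emulates the human raters' liberal reading).
#' @param hueToleranceDeg,minSaturation,minValue red-ink HSV window.
#' @param minMatchedFraction,maxResidualPx registration acceptance limits.
#' @return a [RecognitionConfig].
#' @export
recognitionConfig <- function(layout = defaultBoardLayout(),
                              activationRadiusPx = layout@dotRadiusPx + 4 * k,
                              minActivationPixels = 3L,
                              corridorHalfwidthPx = layout@dotRadiusPx + 3 * k,
                              coverageThreshold = 0.75,
                              maxGapFraction = 0.20,
                              overshootThresholdPx = 12 * k,
                              minViolationPixels = 3L,
                              minIndependentPixels = 3L,
                              countViolationsAsDesigns = FALSE,
                              hueToleranceDeg = 20,
                              minSaturation = 0.35,
                              minValue = 0.25,
                              minMatchedFraction = 0.8,
                              maxResidualPx = 3 * k) {
    k <- layout@dpi / 300
    new("RecognitionConfig",
        activationRadiusPx = activationRadiusPx,
        minActivationPixels = as.integer(minActivationPixels),
        corridorHalfwidthPx = corridorHalfwidthPx,
        coverageThreshold = coverageThreshold,
        maxGapFraction = maxGapFraction,
        overshootThresholdPx = overshootThresholdPx,
        minViolationPixels = as.integer(minViolationPixels),
        minIndependentPixels = as.integer(minIndependentPixels),
        countViolationsAsDesigns = countViolationsAsDesigns,
        hueToleranceDeg = hueToleranceDeg,
        minSaturation = minSaturation,
        minValue = minValue,
        minMatchedFraction = minMatchedFraction,
        maxResidualPx = maxResidualPx)
}

.redPixelCoords <- function(cell) {
    idx <- which(cell@redMask)
    h <- nrow(cell@redMask)
    if (!length(idx)) return(matrix(numeric(), 0, 2,
                                    dimnames = list(NULL, c("x", "y"))))
    cbind(x = ((idx - 1L) %/% h) + 0.5, y = ((idx - 1L) %% h) + 0.5)
}

#' Task 1: identify the active dots of a cell
#'
#' A dot is active (part of the drawn design) iff at least
#' \code{minPixels} red pixels lie within \code{radiusPx} of its center.
#'
#' @param cell a [CellInk].
#' @param radiusPx activation radius in pixels.
#' @param minPixels minimum red-pixel evidence.
#' @return an [ActiveDotSet].
#' @export
identifyActiveDots <- function(cell, radiusPx, minPixels = 3L) {
    px <- .redPixelCoords(cell)
    ev <- integer(5)
    if (nrow(px)) {
        for (d in 1:5) {
            ev[d] <- sum((px[, 1] - cell@dotCenters[d, 1])^2 +
                         (px[, 2] - cell@dotCenters[d, 2])^2 <= radiusPx^2)
        }
    }
    new("ActiveDotSet", active = ev >= minPixels, evidence = ev)
}

#' Task 2: candidate connections between active dots
#'
#' All connections that can possibly exist between the active dots, in
#' canonical order.
#'
#' @param active an [ActiveDotSet] (or logical length-5 vector).
#' @return data.frame of candidate connections (columns as
#'   [enumerateConnections()]).
#' @export
candidateConnections <- function(active) {
    flags <- if (is(active, "ActiveDotSet")) active@active else active
    conns <- enumerateConnections(5L)
    conns[flags[conns$dotA + 1L] & flags[conns$dotB + 1L], , drop = FALSE]
}

#' Task 3: designate red pixels to candidate connections
#'
#' Each red pixel is assigned to the candidate whose segment (between the
#' dot centers) is nearest, provided the distance is at most the corridor
#' half-width; ties are broken toward the shorter segment, then the lower
#' canonical index. Pixels farther than the corridor from every candidate
#' stay unassigned.
#'
#' @param cell a [CellInk].
#' @param candidates data.frame from [candidateConnections()].
#' @param corridorHalfwidthPx corridor half-width in pixels.
#' @return a [PixelAssignment].
#' @export
assignPixels <- function(cell, candidates, corridorHalfwidthPx) {
    px <- .redPixelCoords(cell)
    n <- nrow(px)
    m <- nrow(candidates)
    assigned <- rep(NA_integer_, n)
    tval <- rep(NA_real_, n)
    if (n && m) {
        score <- matrix(Inf, n, m)
        tmat <- matrix(NA_real_, n, m)
        lens <- numeric(m)
        for (j in seq_len(m)) {
            a <- cell@dotCenters[candidates$dotA[j] + 1L, ]
            b <- cell@dotCenters[candidates$dotB[j] + 1L, ]
            sd <- .segDist(px[, 1], px[, 2], a, b)
            lens[j] <- sd$len
            elig <- sd$dist <= corridorHalfwidthPx
            # primary key: distance (rounded so exact geometric ties tie);
            # secondary: segment length; tertiary: canonical index
            score[elig, j] <- round(sd$dist[elig], 3) * 1e6 + sd$len +
                candidates$canonicalIndex[j] * 1e-4
            tmat[, j] <- sd$t
        }
        best <- max.col(-score, ties.method = "first")
        hasAny <- rowSums(is.finite(score)) > 0L
        assigned[hasAny] <- candidates$canonicalIndex[best[hasAny]]
        tval[hasAny] <- tmat[cbind(which(hasAny), best[hasAny])]
    }
    new("PixelAssignment", px = px, candidate = assigned, t = tval,
        candidates = candidates)
}

#' Unassigned fraction of a pixel assignment
#' @param assignment a [PixelAssignment].
#' @return proportion of red pixels left unassigned (0 if no red pixels).
#' @export
unassignedFraction <- function(assignment) {
    n <- nrow(assignment@px)
    if (!n) return(0)
    mean(is.na(assignment@candidate))
}

#' Task 4: check line compatibility of a candidate connection
#'
#' The red pixels designated to a candidate actually form a line
#' compatible with it iff (a) their projections onto the segment cover at
#' least \code{coverageThreshold} of its length and (b) the largest
#' projection gap (including end gaps) is at most \code{maxGapFraction} of
#' its length.
#'
#' @param t projection parameters (0..1) of the pixels assigned to the
#'   candidate, as produced by [assignPixels()].
#' @param lengthPx segment length in pixels.
#' @param coverageThreshold minimum covered fraction.
#' @param maxGapFraction maximum gap fraction.
#' @return list with \code{accepted} (logical), \code{reason},
#'   \code{coverage} and \code{maxGap}.
#' @export
checkLineCompatibility <- function(t, lengthPx, coverageThreshold = 0.75,
                                   maxGapFraction = 0.20) {
    if (!length(t))
        return(list(accepted = FALSE, reason = "no-pixels", coverage = 0,
                    maxGap = 1))
    nb <- max(4L, as.integer(round(lengthPx)))
    bins <- pmin(nb, pmax(1L, floor(t * nb) + 1L))
    occ <- tabulate(bins, nb) > 0L
    coverage <- mean(occ)
    runs <- rle(occ)
    gapRuns <- runs$lengths[!runs$values]
    maxGap <- if (length(gapRuns)) max(gapRuns) / nb else 0
    if (coverage < coverageThreshold)
        list(accepted = FALSE, reason = "coverage", coverage = coverage,
             maxGap = maxGap)
    else if (maxGap > maxGapFraction)
        list(accepted = FALSE, reason = "gap", coverage = coverage,
             maxGap = maxGap)
    else
        list(accepted = TRUE, reason = "ok", coverage = coverage,
             maxGap = maxGap)
}

#' Task 5: reject false-positive candidate connections
#'
#' Resolves collinear subsumption. An accepted long candidate i-k that
#' passes within the activation radius of an active interior dot j, while
#' the short candidates i-j and j-k are both accepted, is a false positive
#' arising from the short strokes' pixels -- unless it has independent
#' pixel support beyond the union of the short candidates' corridors.
#'
#' @param accepted integer vector of canonical indices of candidates that
#'   passed line compatibility.
#' @param active logical length-5 active-dot flags.
#' @param assignment a [PixelAssignment].
#' @param dotCentersPx 5 x 2 matrix of dot centers (cell-local pixels).
#' @param activationRadiusPx activation radius.
#' @param corridorHalfwidthPx corridor half-width.
#' @param minIndependentPixels independent-support threshold.
#' @return list with \code{true} (kept canonical indices) and
#'   \code{removed} (data.frame of removals with the interior dot).
#' @export
rejectFalsePositives <- function(accepted, active, assignment, dotCentersPx,
                                 activationRadiusPx, corridorHalfwidthPx,
                                 minIndependentPixels = 3L) {
    conns <- enumerateConnections(5L)
    removed <- data.frame(canonicalIndex = integer(), interiorDot = integer())
    if (length(accepted) < 3L)
        return(list(true = sort(accepted), removed = removed))
    pairKey <- function(a, b) conns$canonicalIndex[conns$dotA == min(a, b) &
                                                   conns$dotB == max(a, b)]
    lenOf <- function(k) {
        a <- dotCentersPx[conns$dotA[conns$canonicalIndex == k] + 1L, ]
        b <- dotCentersPx[conns$dotB[conns$canonicalIndex == k] + 1L, ]
        sqrt(sum((b - a)^2))
    }
    keep <- accepted[order(-vapply(accepted, lenOf, numeric(1)))]
    px <- assignment@px
    for (k in keep) {
        i <- conns$dotA[conns$canonicalIndex == k]
        kk <- conns$dotB[conns$canonicalIndex == k]
        a <- dotCentersPx[i + 1L, ]
        b <- dotCentersPx[kk + 1L, ]
        for (j in setdiff(which(active) - 1L, c(i, kk))) {
            c0 <- dotCentersPx[j + 1L, ]
            sd <- .segDist(c0[1], c0[2], a, b)
            if (sd$dist > activationRadiusPx) next
            kij <- pairKey(i, j)
            kjk <- pairKey(j, kk)
            if (!(kij %in% keep) || !(kjk %in% keep)) next
            # independent support: pixels assigned to the long candidate
            # farther than the corridor from both short segments
            sel <- !is.na(assignment@candidate) & assignment@candidate == k
            nInd <- 0L
            if (any(sel)) {
                pA <- dotCentersPx[conns$dotA[conns$canonicalIndex == kij] + 1L, ]
                pB <- dotCentersPx[conns$dotB[conns$canonicalIndex == kij] + 1L, ]
                d1 <- .segDist(px[sel, 1], px[sel, 2], pA, pB)$dist
                qA <- dotCentersPx[conns$dotA[conns$canonicalIndex == kjk] + 1L, ]
                qB <- dotCentersPx[conns$dotB[conns$canonicalIndex == kjk] + 1L, ]
                d2 <- .segDist(px[sel, 1], px[sel, 2], qA, qB)$dist
                nInd <- sum(d1 > corridorHalfwidthPx & d2 > corridorHalfwidthPx)
            }
            if (nInd < minIndependentPixels) {
                keep <- setdiff(keep, k)
                removed <- rbind(removed,
                                 data.frame(canonicalIndex = k,
                                            interiorDot = j))
                break
            }
        }
    }
    list(true = sort(keep), removed = removed)
}

#' Detect procedure violations in a cell
#'
#' Counts drawn strokes whose red pixels extend beyond a dot center by
#' more than the overshoot threshold along the stroke direction ("went a
#' few millimeters through and crossed the dots"). Only pixels designated
#' to the stroke itself or left unassigned are considered, so ink of other
#' strokes sharing a dot cannot masquerade as overshoot.
#'
#' @param candidates integer vector of canonical indices of drawn strokes
#'   (candidates that passed line compatibility).
#' @param assignment a [PixelAssignment].
#' @param dotCentersPx 5 x 2 matrix of dot centers.
#' @param corridorHalfwidthPx corridor half-width.
#' @param overshootThresholdPx overshoot threshold in pixels.
#' @param minViolationPixels minimum pixels past the threshold.
#' @return list with \code{count} and \code{violating} (canonical indices).
#' @export
detectViolations <- function(candidates, assignment, dotCentersPx,
                             corridorHalfwidthPx, overshootThresholdPx,
                             minViolationPixels = 3L) {
    conns <- enumerateConnections(5L)
    px <- assignment@px
    violating <- integer()
    if (nrow(px) && length(candidates)) {
        for (k in candidates) {
            a <- dotCentersPx[conns$dotA[conns$canonicalIndex == k] + 1L, ]
            b <- dotCentersPx[conns$dotB[conns$canonicalIndex == k] + 1L, ]
            sel <- is.na(assignment@candidate) | assignment@candidate == k
            if (!any(sel)) next
            sd <- .segDist(px[sel, 1], px[sel, 2], a, b)
            # evidence window: within the corridor of the infinite line and
            # at most 4 thresholds beyond either dot center
            ext <- sd$perp <= corridorHalfwidthPx &
                sd$tRaw * sd$len > -4 * overshootThresholdPx &
                sd$tRaw * sd$len < sd$len + 4 * overshootThresholdPx
            over <- pmax(-sd$tRaw * sd$len, (sd$tRaw - 1) * sd$len)
            nOver <- sum(ext & over > overshootThresholdPx)
            if (nOver >= minViolationPixels) violating <- c(violating, k)
        }
    }
    list(count = length(violating), violating = violating)
}

#' Recognize the design drawn in one cell
#'
#' Composes the five tasks (active dots, candidate connections, pixel
#' assignment, line compatibility, false-positive rejection) plus
#' violation detection, and encodes the surviving true connections as a
#' design ID. Violating strokes are excluded from the true connections
#' unless \code{config@countViolationsAsDesigns} is TRUE. A cell with red
#' ink but no true connections and no violations is marked unscorable
#' (design 0).
#'
#' @param cell a [CellInk].
#' @param config a [RecognitionConfig].
#' @return a [RecognizedCell].
#' @export
recognizeCell <- function(cell, config) {
    stopifnot(is(cell, "CellInk"), is(config, "RecognitionConfig"))
    px <- .redPixelCoords(cell)
    hasInk <- nrow(px) > 0L
    active <- identifyActiveDots(cell, config@activationRadiusPx,
                                 config@minActivationPixels)
    cands <- candidateConnections(active)
    diag <- data.frame(canonicalIndex = integer(), decision = character(),
                       reason = character(), coverage = numeric(),
                       maxGap = numeric())
    if (!hasInk || nrow(cands) == 0L) {
        return(new("RecognizedCell", cellIndex = cell@cellIndex,
                   activeDots = active@active, trueConnections = integer(),
                   design = 0L, violations = 0L,
                   unassignedFraction = if (hasInk) 1 else 0,
                   hasInk = hasInk, unscorable = hasInk,
                   diagnostics = diag))
    }
    assignment <- assignPixels(cell, cands, config@corridorHalfwidthPx)
    acceptedIdx <- integer()
    for (j in seq_len(nrow(cands))) {
        k <- cands$canonicalIndex[j]
        a <- cell@dotCenters[cands$dotA[j] + 1L, ]
        b <- cell@dotCenters[cands$dotB[j] + 1L, ]
        len <- sqrt(sum((b - a)^2))
        sel <- !is.na(assignment@candidate) & assignment@candidate == k
        chk <- checkLineCompatibility(assignment@t[sel], len,
                                      config@coverageThreshold,
                                      config@maxGapFraction)
        diag <- rbind(diag, data.frame(
            canonicalIndex = k,
            decision = if (chk$accepted) "accepted" else "rejected",
            reason = chk$reason, coverage = chk$coverage,
            maxGap = chk$maxGap))
        if (chk$accepted) acceptedIdx <- c(acceptedIdx, k)
    }
    fp <- rejectFalsePositives(acceptedIdx, active@active, assignment,
                               cell@dotCenters, config@activationRadiusPx,
                               config@corridorHalfwidthPx,
                               config@minIndependentPixels)
    if (nrow(fp$removed)) {
        diag$decision[diag$canonicalIndex %in% fp$removed$canonicalIndex] <-
            "rejected"
        diag$reason[diag$canonicalIndex %in% fp$removed$canonicalIndex] <-
            "false-positive"
    }
    viol <- detectViolations(fp$true, assignment, cell@dotCenters,
                             config@corridorHalfwidthPx,
                             config@overshootThresholdPx,
                             config@minViolationPixels)
    true <- fp$true
    if (!config@countViolationsAsDesigns && length(viol$violating)) {
        true <- setdiff(true, viol$violating)
        diag$decision[diag$canonicalIndex %in% viol$violating] <- "rejected"
        diag$reason[diag$canonicalIndex %in% viol$violating] <- "violation"
    }
    design <- designId(true)
    new("RecognizedCell", cellIndex = cell@cellIndex,
        activeDots = active@active,
        trueConnections = as.integer(sort(true)),
        design = as.integer(design),
        violations = as.integer(viol$count),
        unassignedFraction = unassignedFraction(assignment),
        hasInk = hasInk,
        unscorable = hasInk && design == 0L && viol$count == 0L,
        diagnostics = diag)
}
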