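# Scoring: unique designs, perseverative errors and violations per part
# and per protocol. Design equality is design-ID equality (identical
# connection sets); a repetition of a design within a part is a
# perseverative error. Perseveration scope is within-part by default.

#' Score one part from its ordered design IDs
#'
#' Scans the part's cells in order, ignoring blanks (design 0): a design
#' ID not seen earlier in the part counts as a unique design, a repeat as
#' a perseverative error.
#'
#' @param designs numeric vector (length <= 35) of design IDs in 0..1023.
#' @param seen optional set of design IDs already seen (used for the
#'   cross-part perseveration scope).
#' @return list with \code{attempted}, \code{uniqueDesigns},
#'   \code{perseverativeErrors}.
#' @examples
#' scorePart(c(5, 9, 5, 17))   # 3 unique, 1 perseverative error
#' @export
scorePart <- function(designs, seen = integer()) {
    if (length(designs) > 35L)
        stop("invalid argument: at most 35 cells per part")
    if (any(is.na(designs)) || any(designs < 0 | designs > 1023 |
                                   designs != round(designs)))
        stop("invalid argument: design IDs must be integers in 0..1023")
    d <- designs[designs > 0]
    uniq <- 0L
    pers <- 0L
    for (x in d) {
        if (x %in% seen) pers <- pers + 1L
        else {
            uniq <- uniq + 1L
            seen <- c(seen, x)
        }
    }
    list(attempted = length(d), uniqueDesigns = uniq,
         perseverativeErrors = pers, seen = seen)
}

.protocolScoreFromParts <- function(rows, complete = TRUE) {
    parts <- do.call(rbind, rows)
    new("ProtocolScore", parts = parts, complete = complete)
}

#' Score a full protocol from recognized cells
#'
#' @param parts list of five elements (parts 1-5), each a list of
#'   [RecognizedCell] objects in cell order. A missing (NULL) part yields
#'   a partial score flagged incomplete.
#' @param perseverationScope "part" (RFFT convention: repeats count within
#'   a part only) or "protocol" (repeats count across parts; sensitivity
#'   analysis).
#' @return a [ProtocolScore].
#' @seealso [scoreScript()] for scoring a ground-truth script directly.
#' @export
scoreProtocol <- function(parts, perseverationScope = c("part", "protocol")) {
    perseverationScope <- match.arg(perseverationScope)
    if (length(parts) != 5L)
        stop("incomplete-protocol: five parts expected")
    rows <- vector("list", 5L)
    seen <- integer()
    complete <- TRUE
    for (p in 1:5) {
        cellsP <- parts[[p]]
        if (is.null(cellsP)) {
            complete <- FALSE
            rows[[p]] <- data.frame(part = p, attempted = 0L,
                                    uniqueDesigns = 0L,
                                    perseverativeErrors = 0L,
                                    violations = 0L, unscorable = 0L)
            next
        }
        designs <- vapply(cellsP, function(cc) cc@design, integer(1))
        viol <- sum(vapply(cellsP, function(cc) cc@violations, integer(1)))
        unsc <- sum(vapply(cellsP, function(cc) cc@unscorable, logical(1)))
        sp <- scorePart(designs, seen = if (perseverationScope == "protocol")
            seen else integer())
        if (perseverationScope == "protocol") seen <- sp$seen
        rows[[p]] <- data.frame(part = p, attempted = sp$attempted,
                                uniqueDesigns = sp$uniqueDesigns,
                                perseverativeErrors = sp$perseverativeErrors,
                                violations = viol, unscorable = unsc)
    }
    if (!complete)
        warning("incomplete-protocol: one or more parts missing")
    .protocolScoreFromParts(rows, complete)
}

#' Score a protocol script (ground truth)
#'
#' Scores the script the synthetic renderer draws from, applying the same
#' rules as the recognition pipeline: cells scripted in violation mode
#' contribute their stroke count as violations and are excluded from the
#' design tallies (their expected recognized design is 0).
#'
#' @param script a [ProtocolScript].
#' @param perseverationScope see [scoreProtocol()].
#' @return a [ProtocolScore].
#' @export
scoreScript <- function(script, perseverationScope = c("part", "protocol")) {
    perseverationScope <- match.arg(perseverationScope)
    rows <- vector("list", 5L)
    seen <- integer()
    for (p in 1:5) {
        d <- script@designs[p, ]
        v <- script@violations[p, ] & d > 0
        viol <- sum(vapply(which(v), function(i)
            length(designFromId(d[i])), integer(1)))
        dEff <- ifelse(v, 0, d)
        sp <- scorePart(dEff, seen = if (perseverationScope == "protocol")
            seen else integer())
        if (perseverationScope == "protocol") seen <- sp$seen
        rows[[p]] <- data.frame(part = p, attempted = sp$attempted,
                                uniqueDesigns = sp$uniqueDesigns,
                                perseverativeErrors = sp$perseverativeErrors,
                                violations = viol, unscorable = 0L)
    }
    .protocolScoreFromParts(rows)
}

#' @rdname protocolScoreAccessors
#' @export
setGeneric("uniqueDesigns", function(x) standardGeneric("uniqueDesigns"))
#' @rdname protocolScoreAccessors
#' @export
setGeneric("perseverativeErrors",
           function(x) standardGeneric("perseverativeErrors"))
#' @rdname protocolScoreAccessors
#' @export
setGeneric("violationCount", function(x) standardGeneric("violationCount"))
#' @rdname protocolScoreAccessors
#' @export
setGeneric("partScores", function(x) standardGeneric("partScores"))

#' Accessors for ProtocolScore totals
#'
#' Totals are sums over the five parts, matching the RFFT convention of
#' reporting the total number of unique designs and perseverative errors.
#'
#' @param x a [ProtocolScore].
#' @return integer total, or the per-part data.frame for
#'   \code{partScores}.
#' @name protocolScoreAccessors
#' @aliases uniqueDesigns perseverativeErrors violationCount partScores
NULL

#' @rdname protocolScoreAccessors
setMethod("uniqueDesigns", "ProtocolScore", function(x)
    as.integer(sum(x@parts$uniqueDesigns)))
#' @rdname protocolScoreAccessors
setMethod("perseverativeErrors", "ProtocolScore", function(x)
    as.integer(sum(x@parts$perseverativeErrors)))
#' @rdname protocolScoreAccessors
setMethod("violationCount", "ProtocolScore", function(x)
    as.integer(sum(x@parts$violations)))
#' @rdname protocolScoreAccessors
setMethod("partScores", "ProtocolScore", function(x) x@parts)

#' One-row summary of a protocol score
#'
#' @param score a [ProtocolScore].
#' @param id protocol identifier for the row.
#' @return data.frame with per-part and total unique designs,
#'   perseverative errors, violations and unscorable-cell counts.
#' @export
scoreRow <- function(score, id = "protocol") {
    p <- score@parts
    row <- data.frame(protocol = id)
    for (i in 1:5) {
        row[[paste0("unique_p", i)]] <- p$uniqueDesigns[i]
        row[[paste0("persev_p", i)]] <- p$perseverativeErrors[i]
    }
    row$unique_total <- uniqueDesigns(score)
    row$persev_total <- perseverativeErrors(score)
    row$violations_total <- violationCount(score)
    row$unscorable_total <- sum(p$unscorable)
    row$complete <- score@complete
    row
}
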