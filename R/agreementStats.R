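# Rater-agreement statistics: two-way absolute-agreement single-measures
# intraclass correlation (McGraw & Wong ICC(A,1)), Lin's concordance
# correlation coefficient (Lin 1989, Fisher-z CI), Bland-Altman 95% limits
# of agreement, and the multi-rater reconciliation rule used for the human
# criterion scoring.

#' Intraclass correlation, two-way absolute agreement, single measures
#'
#' ICC(A,1) of McGraw & Wong from the two-way ANOVA decomposition:
#' \deqn{ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with subjects as rows and raters as columns. The 95\% CI and the
#' p-value (H0: ICC = 0) use the standard F-based formulas.
#'
#' @param scores n x k numeric matrix: n subjects, k raters, no missing
#'   cells.
#' @param conf confidence level (default 0.95).
#' @return an [AgreementResult] with method "icc(A,1)"; details hold the
#'   mean squares.
#' @references McGraw K.O., Wong S.P. (1996) Forming inferences about some
#'   intraclass correlation coefficients. Psychological Methods 1:30-46.
#' @export
iccAbsoluteSingle <- function(scores, conf = 0.95) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    k <- ncol(scores)
    if (n < 3L || k < 2L)
        stop("invalid argument: need at least 3 subjects and 2 raters")
    if (anyNA(scores))
        stop("invalid argument: missing cells are not supported")
    grand <- mean(scores)
    rowm <- rowMeans(scores)
    colm <- colMeans(scores)
    MSR <- k * sum((rowm - grand)^2) / (n - 1)
    MSC <- n * sum((colm - grand)^2) / (k - 1)
    SSE <- sum((scores - outer(rowm, colm, "+") + grand)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
    if (denom <= 0 || (MSR == 0 && MSC == 0 && MSE == 0))
        stop("undefined-statistic: zero total variance")
    icc <- (MSR - MSE) / denom
    alpha <- 1 - conf
    # McGraw & Wong CI for ICC(A,1)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (MSE > 0 && is.finite(a)) {
        v <- (a * MSC + b * MSE)^2 /
            ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
        FL <- qf(1 - alpha / 2, n - 1, v)
        FU <- qf(1 - alpha / 2, v, n - 1)
        lower <- n * (MSR - FL * MSE) /
            (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
        upper <- n * (FU * MSR - MSE) /
            (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
        p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    } else {
        lower <- upper <- p <- NA_real_
    }
    new("AgreementResult", method = "icc(A,1)", estimate = icc,
        ciLower = lower, ciUpper = upper, pValue = p, n = as.integer(n),
        details = list(MSR = MSR, MSC = MSC, MSE = MSE, k = k))
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with
#' biased (1/n) moment estimators; 95\% CI via the Fisher z transform with
#' Lin's (1989) standard error.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param conf confidence level.
#' @return an [AgreementResult] with method "lin-ccc".
#' @references Lin L.I. (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45:255-268.
#' @export
linCcc <- function(x, y, conf = 0.95) {
    if (length(x) != length(y))
        stop("invalid argument: x and y must have equal length")
    n <- length(x)
    if (n < 3L) stop("invalid argument: need n >= 3")
    mx <- mean(x); my <- mean(y)
    sx2 <- mean((x - mx)^2)
    sy2 <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
    if (sx2 == 0 && sy2 == 0)
        stop("undefined-statistic: zero variance in both inputs")
    ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
    lower <- upper <- NA_real_
    if (sx2 > 0 && sy2 > 0 && abs(ccc) < 1) {
        r <- sxy / sqrt(sx2 * sy2)
        if (abs(r) > 0) {
            u <- (mx - my) / (sx2 * sy2)^(1 / 4)
            z <- atanh(ccc)
            sez2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                     2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                     ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
            if (is.finite(sez2) && sez2 >= 0) {
                zq <- qnorm(1 - (1 - conf) / 2)
                lower <- tanh(z - zq * sqrt(sez2))
                upper <- tanh(z + zq * sqrt(sez2))
            }
        }
    } else if (abs(ccc) == 1) {
        lower <- upper <- ccc
    }
    new("AgreementResult", method = "lin-ccc", estimate = ccc,
        ciLower = lower, ciUpper = upper, pValue = NA_real_,
        n = as.integer(n), details = list())
}

#' Bland-Altman 95% limits of agreement
#'
#' Differences d = x - y (the convention is recorded in the result), their
#' mean and sample SD (n - 1 denominator), and limits of agreement
#' mean +/- 1.96 SD.
#'
#' @param x,y numeric vectors of equal length (n >= 2); by the package's
#'   convention x is the computerized (or first) assessment and y the
#'   human (or second) assessment.
#' @return an [AgreementResult] with method "bland-altman"; details hold
#'   meanDifference, sdDifference, loaLower, loaUpper, convention.
#' @examples
#' ba <- blandAltman(c(10, 12, 9), c(11, 12, 10))
#' limitsOfAgreement(ba)
#' @export
blandAltman <- function(x, y) {
    if (length(x) != length(y))
        stop("invalid argument: x and y must have equal length")
    n <- length(x)
    if (n < 2L) stop("undefined-statistic: need n >= 2")
    d <- x - y
    md <- mean(d)
    sdd <- sd(d)
    new("AgreementResult", method = "bland-altman", estimate = md,
        ciLower = NA_real_, ciUpper = NA_real_, pValue = NA_real_,
        n = as.integer(n),
        details = list(meanDifference = md, sdDifference = sdd,
                       loaLower = md - 1.96 * sdd,
                       loaUpper = md + 1.96 * sdd,
                       convention = "x - y"))
}

#' Limits of agreement from printed summary statistics
#'
#' Closed form of the Bland-Altman limits from a reported mean difference
#' and SD of differences: mean +/- 1.96 SD. Useful to reproduce published
#' limits from published summaries.
#'
#' @param meanDifference mean of the paired differences.
#' @param sdDifference SD of the paired differences.
#' @return named numeric length-2 (lower, upper).
#' @examples
#' limitsFromSummary(-1.42, 2.78)   # c(-6.87, 4.03) to 2 dp
#' @export
limitsFromSummary <- function(meanDifference, sdDifference) {
    c(lower = meanDifference - 1.96 * sdDifference,
      upper = meanDifference + 1.96 * sdDifference)
}

#' Limits of agreement of a Bland-Altman result
#' @param result an [AgreementResult] from [blandAltman()].
#' @return named numeric length-2 (lower, upper).
#' @export
limitsOfAgreement <- function(result) {
    stopifnot(is(result, "AgreementResult"),
              result@method == "bland-altman")
    c(lower = result@details$loaLower, upper = result@details$loaUpper)
}

#' Reconcile multi-rater scores
#'
#' Implements the human-assessment reconciliation: a third rater is
#' required iff the first two raters differ by more than two points in any
#' part or more than four points in total. With a third rater present, the
#' two most concordant raters (smallest absolute total difference; ties
#' broken by rater precedence (1,2) > (1,3) > (2,3)) are averaged
#' per part; otherwise raters 1 and 2 are averaged.
#'
#' @param rater1,rater2 numeric length-5 per-part scores.
#' @param rater3 optional numeric length-5 per-part scores.
#' @param partThreshold,totalThreshold trigger thresholds (defaults 2 and
#'   4 points).
#' @return list with \code{final} (length-5 averaged part scores),
#'   \code{finalTotal}, \code{thirdRaterRequired}, \code{chosenPair} and
#'   \code{audit} (pairwise total differences).
#' @export
reconcileRaters <- function(rater1, rater2, rater3 = NULL,
                            partThreshold = 2, totalThreshold = 4) {
    stopifnot(length(rater1) == 5L, length(rater2) == 5L)
    required <- any(abs(rater1 - rater2) > partThreshold) ||
        abs(sum(rater1) - sum(rater2)) > totalThreshold
    if (!required || is.null(rater3)) {
        if (required && is.null(rater3))
            stop("reconciliation-incomplete: third rater required but absent")
        final <- (rater1 + rater2) / 2
        return(list(final = final, finalTotal = sum(final),
                    thirdRaterRequired = required, chosenPair = c(1L, 2L),
                    audit = data.frame(pair = "1-2",
                                       totalDiff = abs(sum(rater1) -
                                                       sum(rater2)))))
    }
    stopifnot(length(rater3) == 5L)
    raters <- list(rater1, rater2, rater3)
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    diffs <- vapply(pairs, function(p)
        abs(sum(raters[[p[1]]]) - sum(raters[[p[2]]])), numeric(1))
    best <- pairs[[which.min(diffs)]]   # which.min keeps precedence on ties
    final <- (raters[[best[1]]] + raters[[best[2]]]) / 2
    list(final = final, finalTotal = sum(final), thirdRaterRequired = TRUE,
         chosenPair = best,
         audit = data.frame(pair = c("1-2", "1-3", "2-3"),
                            totalDiff = diffs))
}
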