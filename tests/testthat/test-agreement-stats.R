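# Agreement statistics: ICC(A,1), Lin's CCC, Bland-Altman, rater
# reconciliation.

# Independent ICC oracle: explicit two-way ANOVA sums of squares by
# element-wise loops, then the absolute-agreement single-measures formula.
iccOracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    SSR <- 0; SSC <- 0; SST <- 0
    for (i in 1:n) SSR <- SSR + k * (mean(m[i, ]) - grand)^2
    for (j in 1:k) SSC <- SSC + n * (mean(m[, j]) - grand)^2
    for (i in 1:n) for (j in 1:k) SST <- SST + (m[i, j] - grand)^2
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Independent CCC oracle: direct evaluation of the definition.
cccOracle <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y))) / n
    sx2 <- sum((x - mean(x))^2) / n
    sy2 <- sum((y - mean(y))^2) / n
    2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

test_that("ICC(A,1) matches the brute-force ANOVA oracle to 1e-10", {
    set.seed(31)
    for (i in 1:30) {
        n <- sample(4:12, 1); k <- sample(2:4, 1)
        subj <- rnorm(n, 0, 3)
        rater <- rnorm(k, 0, 1)
        m <- outer(subj, rater, "+") + matrix(rnorm(n * k), n, k)
        res <- iccAbsoluteSingle(m)
        expect_lt(abs(res@estimate - iccOracle(m)), 1e-10)
        expect_true(res@ciLower <= res@estimate + 1e-12)
        expect_true(res@ciUpper >= res@estimate - 1e-12)
    }
})

test_that("ICC is 1 for identical raters and ~0 for independent noise", {
    x <- c(3, 7, 1, 9, 4, 6)
    res <- iccAbsoluteSingle(cbind(x, x))
    expect_equal(res@estimate, 1)
    set.seed(32)
    noise <- cbind(rnorm(10000), rnorm(10000))
    expect_lt(abs(iccAbsoluteSingle(noise)@estimate), 0.1)
    expect_error(iccAbsoluteSingle(matrix(5, 4, 2)), "undefined-statistic")
    expect_error(iccAbsoluteSingle(matrix(1, 2, 2)), "invalid argument")
})

test_that("ICC recovers known variance components in simulation", {
    # subjects sigma_a^2 = 9, raters sigma_c^2 = 1, error sigma_e^2 = 4.
    # With few raters the realized rater spread dominates the Monte-Carlo
    # error, so the target conditions on the drawn rater effects:
    # ICC = sigma_a^2 / (sigma_a^2 + var(raters) + sigma_e^2).
    set.seed(33)
    n <- 5000; k <- 3
    raterEffects <- rnorm(k, 0, 1)
    m <- outer(rnorm(n, 0, 3), raterEffects, "+") +
        matrix(rnorm(n * k, 0, 2), n, k)
    res <- iccAbsoluteSingle(m)
    target <- 9 / (9 + var(raterEffects) + 4)
    expect_lt(abs(res@estimate - target), 0.03)
})

test_that("Lin's CCC matches its direct-formula oracle and edge cases", {
    set.seed(34)
    for (i in 1:25) {
        n <- sample(5:40, 1)
        x <- rnorm(n, 10, 3)
        y <- 0.8 * x + rnorm(n, 1, 2)
        res <- linCcc(x, y)
        expect_lt(abs(res@estimate - cccOracle(x, y)), 1e-10)
        # |CCC| <= |r| always
        expect_lte(abs(res@estimate), abs(cor(x, y)) + 1e-12)
    }
    x <- c(1, 5, 3, 8, 2)
    expect_equal(linCcc(x, x)@estimate, 1)
    xz <- x - mean(x)
    expect_equal(linCcc(xz, -xz)@estimate, -1)
    expect_error(linCcc(rep(2, 5), rep(3, 5)), "undefined-statistic")
})

test_that("affine distortions keep Pearson r = 1 but CCC < 1", {
    x <- seq(1, 20)
    for (ab in list(c(3, 1), c(0, 1.5), c(-2, 0.7))) {
        y <- ab[1] + ab[2] * x
        expect_equal(cor(x, y), 1)
        expect_lt(linCcc(x, y)@estimate, 1)
    }
})

test_that("Bland-Altman reproduces printed limits from printed summaries", {
    # unique designs, computerized vs human: mean -1.42, SD 2.78
    lim1 <- limitsFromSummary(-1.42, 2.78)
    expect_equal(round(unname(lim1), 2), c(-6.87, 4.03))
    # perseverative errors, human vs human: mean +0.56, SD 2.36
    lim2 <- limitsFromSummary(0.56, 2.36)
    expect_equal(round(unname(lim2), 2), c(-4.07, 5.19))
})

test_that("Bland-Altman limits have the exact 1.96-SD structure", {
    set.seed(36)
    for (i in 1:20) {
        n <- sample(5:50, 1)
        x <- rnorm(n, 50, 10)
        y <- x + rnorm(n, -1, 2)
        res <- blandAltman(x, y)
        d <- res@details
        expect_equal(d$meanDifference, mean(x - y))
        expect_equal(d$sdDifference, sd(x - y))
        expect_equal(d$loaUpper - d$loaLower, 2 * 1.96 * d$sdDifference)
        expect_equal(unname(limitsOfAgreement(res)),
                     c(d$loaLower, d$loaUpper))
    }
    ba0 <- blandAltman(1:5, 1:5)
    expect_equal(ba0@details$meanDifference, 0)
    expect_equal(unname(limitsOfAgreement(ba0)), c(0, 0))
    expect_error(blandAltman(1, 1), "undefined-statistic")
})

test_that("third-rater triggering matches the rule on exhaustive grids", {
    r1 <- c(10, 12, 8, 15, 9)
    for (dPart in -4:4) for (whichPart in c(1L, 4L)) {
        r2 <- r1
        r2[whichPart] <- r2[whichPart] + dPart
        required <- abs(dPart) > 2 || abs(sum(r1) - sum(r2)) > 4
        if (required) {
            expect_error(reconcileRaters(r1, r2), "reconciliation-incomplete")
            res <- reconcileRaters(r1, r2, r1)
            expect_true(res$thirdRaterRequired)
        } else {
            res <- reconcileRaters(r1, r2)
            expect_false(res$thirdRaterRequired)
            expect_equal(res$final, (r1 + r2) / 2)
        }
    }
    # spread across parts: each part within 2 but total differs by > 4
    r2 <- r1 + c(2, 2, 1, 0, 0)
    expect_error(reconcileRaters(r1, r2), "reconciliation-incomplete")
})

test_that("the most concordant pair is averaged, with deterministic ties", {
    # totals 80, 90, 81: the (rater1, rater3) pair is most concordant
    r1 <- c(16, 16, 16, 16, 16)
    r2 <- c(18, 18, 18, 18, 18)
    r3 <- c(17, 16, 16, 16, 16)
    res <- reconcileRaters(r1, r2, r3)
    expect_equal(res$chosenPair, c(1L, 3L))
    expect_equal(res$finalTotal, 80.5)
    # exhaustive check: chosen pair minimizes the absolute total difference
    set.seed(38)
    for (i in 1:20) {
        a <- sample(0:20, 5, replace = TRUE)
        b <- a + sample(c(-3, 3), 5, replace = TRUE)
        c3 <- a + sample(-1:5, 5, replace = TRUE)
        res <- tryCatch(reconcileRaters(a, b, c3), error = function(e) NULL)
        if (is.null(res) || !res$thirdRaterRequired) next
        diffs <- c(abs(sum(a) - sum(b)), abs(sum(a) - sum(c3)),
                   abs(sum(b) - sum(c3)))
        expect_equal(min(diffs),
                     res$audit$totalDiff[match(paste(res$chosenPair,
                                                     collapse = "-"),
                                               c("1-2", "1-3", "2-3"))])
    }
    # tie on concordance: precedence (1,2) > (1,3) > (2,3)
    rA <- c(20, 20, 20, 20, 20)            # total 100
    rB <- c(10, 30, 20, 23, 20)            # total 103, part diffs > 2
    rC <- c(19, 21, 20, 17, 20)            # total 97
    res <- reconcileRaters(rA, rB, rC)     # pairs 1-2 and 1-3 both diff 3
    expect_equal(res$chosenPair, c(1L, 2L))
})
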