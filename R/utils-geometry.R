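# Low-level vectorized 2-D helpers shared by the renderer and recognizer.
# All coordinates are continuous page/cell coordinates: origin top-left,
# x rightward, y downward; the pixel at matrix position [i, j] has center
# (j - 0.5, i - 0.5).

# Distance from points (px, py) to the segment p1-p2, plus the clamped and
# unclamped projection parameter t (t = 0 at p1, 1 at p2).
.segDist <- function(px, py, p1, p2) {
    vx <- p2[1] - p1[1]
    vy <- p2[2] - p1[2]
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
        d <- sqrt((px - p1[1])^2 + (py - p1[2])^2)
        return(list(dist = d, t = rep(0, length(px)), tRaw = rep(0, length(px)),
                    perp = d, len = 0))
    }
    tRaw <- ((px - p1[1]) * vx + (py - p1[2]) * vy) / len2
    t <- pmin(1, pmax(0, tRaw))
    dx <- px - (p1[1] + t * vx)
    dy <- py - (p1[2] + t * vy)
    # perpendicular distance to the infinite line
    len <- sqrt(len2)
    perp <- abs((px - p1[1]) * vy - (py - p1[2]) * vx) / len
    list(dist = sqrt(dx * dx + dy * dy), t = t, tRaw = tRaw, perp = perp,
         len = len)
}

# Minimum distance from points to a polyline given as an n x 2 matrix.
.polylineDist <- function(px, py, pts) {
    d <- rep(Inf, length(px))
    for (i in seq_len(nrow(pts) - 1L)) {
        d <- pmin(d, .segDist(px, py, pts[i, ], pts[i + 1L, ])$dist)
    }
    d
}

# Pixel-center coordinate vectors for a matrix block rows i0:i1, cols j0:j1.
.pixelGrid <- function(i0, i1, j0, j1) {
    xs <- (j0:j1) - 0.5
    ys <- (i0:i1) - 0.5
    list(x = rep(xs, each = i1 - i0 + 1L),
         y = rep(ys, times = j1 - j0 + 1L),
         nr = i1 - i0 + 1L, nc = j1 - j0 + 1L)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

# Umeyama least-squares similarity fit (no reflection): maps src (n x 2)
# onto dst (n x 2) as dst ~ s * R %*% src + t.
.fitSimilarity <- function(src, dst) {
    mu_s <- colMeans(src)
    mu_d <- colMeans(dst)
    sc <- sweep(src, 2, mu_s)
    dc <- sweep(dst, 2, mu_d)
    S <- crossprod(dc, sc) / nrow(src)   # 2x2 covariance
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, d))
    R <- sv$u %*% D %*% t(sv$v)
    varS <- sum(sc^2) / nrow(src)
    s <- sum(diag(D) * sv$d) / varS
    t <- mu_d - s * as.vector(R %*% mu_s)
    list(scale = s, R = R, t = t,
         rotationRad = atan2(R[2, 1], R[1, 1]))
}

.applySimilarity <- function(fit, pts) {
    sweep(fit$scale * (pts %*% t(fit$R)), 2, fit$t, "+")
}

.invertSimilarity <- function(fit, pts) {
    (sweep(pts, 2, fit$t) %*% fit$R) / fit$scale
}
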