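# Internal 2D geometry helpers shared by the simulator, the membrane
# classifier and the evaluation code. Polygons are n x 2 matrices of
# vertices (closed implicitly: last joins first).

# even-odd (ray casting) point-in-polygon test; vectorized over points
.pointInPolygon <- function(px, py, poly) {
    n <- nrow(poly)
    xs <- poly[, 1]; ys <- poly[, 2]
    xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
    inside <- rep(FALSE, length(px))
    for (k in seq_len(n)) {
        crosses <- ((ys[k] > py) != (ye[k] > py))
        if (any(crosses)) {
            xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
            inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
        }
    }
    inside
}

# minimum Euclidean distance from each point to the closed polygon boundary
.distToPolygon <- function(px, py, poly) {
    n <- nrow(poly)
    ax <- poly[, 1]; ay <- poly[, 2]
    bx <- ax[c(2:n, 1)]; by <- ay[c(2:n, 1)]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    len2[len2 == 0] <- .Machine$double.eps
    best <- rep(Inf, length(px))
    for (k in seq_len(n)) {
        t <- ((px - ax[k]) * dx[k] + (py - ay[k]) * dy[k]) / len2[k]
        t <- pmin(1, pmax(0, t))
        qx <- ax[k] + t * dx[k]; qy <- ay[k] + t * dy[k]
        d2 <- (px - qx)^2 + (py - qy)^2
        best <- pmin(best, d2)
    }
    sqrt(best)
}

# signed distance: negative inside the polygon (even-odd rule)
.signedDistToPolygon <- function(px, py, poly) {
    d <- .distToPolygon(px, py, poly)
    ifelse(.pointInPolygon(px, py, poly), -d, d)
}

# proper segment-segment intersection test (shared endpoints excluded)
.segIntersect <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# TRUE if the closed polygon self-intersects (non-adjacent edge pairs only)
.polygonSelfIntersects <- function(poly) {
    n <- nrow(poly)
    if (n < 4L) return(FALSE)
    idx <- c(seq_len(n), 1L)
    for (i in seq_len(n - 2L)) {
        jmax <- if (i == 1L) n - 1L else n
        for (j in (i + 2L):jmax) {
            if (.segIntersect(poly[idx[i], ], poly[idx[i + 1L], ],
                              poly[idx[j], ], poly[idx[j + 1L], ]))
                return(TRUE)
        }
    }
    FALSE
}

# cumulative arc length along an open polyline (n x 2), first entry 0
.cumArcLength <- function(pts) {
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    c(0, cumsum(seg))
}

# resample a polyline at given arc-length positions (linear interpolation)
.interpAlongPath <- function(pts, s) {
    cs <- .cumArcLength(pts)
    s <- pmin(pmax(s, 0), cs[length(cs)])
    x <- approx(cs, pts[, 1], xout = s, ties = "ordered")$y
    y <- approx(cs, pts[, 2], xout = s, ties = "ordered")$y
    cbind(x = x, y = y)
}

# outward unit normals at polygon vertices (average of adjacent edge normals);
# assumes counter-clockwise orientation gives outward = rotate edge by -90deg,
# so orientation is detected from the signed area
.polygonNormals <- function(poly) {
    n <- nrow(poly)
    nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
    ex <- poly[nxt, 1] - poly[prv, 1]
    ey <- poly[nxt, 2] - poly[prv, 2]
    len <- sqrt(ex^2 + ey^2); len[len == 0] <- 1
    area2 <- sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2])
    sgn <- if (area2 > 0) 1 else -1
    cbind(sgn * ey / len, -sgn * ex / len)
}
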