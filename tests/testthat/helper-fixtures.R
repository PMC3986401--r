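# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored data.

# expected photons of a unit-mass integrated Gaussian over a pixel window
expectedSpot <- function(rows, cols, x_px, y_px, sigma = 1.2, photons = 800,
                         background = 10) {
    fx <- pnorm(cols + 1, x_px, sigma) - pnorm(cols, x_px, sigma)
    fy <- pnorm(rows + 1, y_px, sigma) - pnorm(rows, y_px, sigma)
    background + photons * outer(fy, fx)
}

# one noisy spot ROI (photon counts) with the truth position in px
noisySpotROI <- function(x_px, y_px, n = 11L, sigma = 1.2, photons = 800,
                         background = 10) {
    E <- expectedSpot(0:(n - 1L), 0:(n - 1L), x_px, y_px, sigma, photons,
                      background)
    matrix(rpois(n * n, E), n, n)
}

# brute-force O(N^2) MSD oracle (all frame pairs, gaps excluded)
bruteMSD <- function(x, y, maxLag, gap = rep(FALSE, length(x))) {
    vapply(seq_len(maxLag), function(k) {
        i <- seq_len(length(x) - k)
        use <- !gap[i] & !gap[i + k]
        mean((x[i + k][use] - x[i][use])^2 + (y[i + k][use] - y[i][use])^2)
    }, numeric(1))
}

# exhaustive minimum-cost assignment over all permutations (n <= 6)
bruteAssignment <- function(cost) {
    n <- nrow(cost)
    perm <- function(v) {
        if (length(v) == 1L) return(matrix(v))
        out <- NULL
        for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perm(v[-i])))
        out
    }
    P <- perm(seq_len(n))
    costs <- apply(P, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
    list(cost = min(costs), perm = P[which.min(costs), ])
}

# noisy observation of a truth trajectory as a linked-trajectory data.frame
asObserved <- function(truth, locSigma = 0.03) {
    data.frame(frame = truth$frame, t = truth$t,
               x_um = truth$x + rnorm(nrow(truth), 0, locSigma),
               y_um = truth$y + rnorm(nrow(truth), 0, locSigma),
               gap = FALSE)
}

# synthetic bright-ring plane (membrane-like) in photon counts
ringImage <- function(n = 100, cx = 50, cy = 50, radius = 40, amp = 30,
                      background = 5, sigma = 1.2, noisy = TRUE) {
    img <- matrix(background, n, n)
    th <- seq(0, 2 * pi, length.out = 20 * n)
    for (i in seq_along(th)) {
        x0 <- cx + radius * cos(th[i]); y0 <- cy + radius * sin(th[i])
        c0 <- max(0L, floor(x0) - 8L); c1 <- min(n - 1L, floor(x0) + 8L)
        r0 <- max(0L, floor(y0) - 8L); r1 <- min(n - 1L, floor(y0) + 8L)
        rows <- r0:r1; cols <- c0:c1
        fx <- pnorm(cols + 1, x0, sigma) - pnorm(cols, x0, sigma)
        fy <- pnorm(rows + 1, y0, sigma) - pnorm(rows, y0, sigma)
        img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
            amp * outer(fy, fx)
    }
    if (noisy) img <- matrix(rpois(n * n, img), n, n)
    img
}
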