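# Small shared numerics.

# Otsu threshold on a numeric vector (256-bin histogram); used for
# phase-congruency maps, intensity masks and blinking traces.
.otsu <- function(x, nbins = 256L) {
    x <- x[is.finite(x)]
    r <- range(x)
    if (diff(r) == 0) return(r[1])
    h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
    mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
    w <- cumsum(h); m <- cumsum(h * mids)
    tot <- w[nbins]; mtot <- m[nbins]
    between <- (mtot * w - m * tot)^2 / (w * (tot - w))
    between[!is.finite(between)] <- -Inf
    mids[which.max(between)]
}

# expected fraction of a unit-mass 2D Gaussian (sd sigma, px units) falling
# in each pixel of a [rows x cols] window; pixel (r, c) 0-based covers
# [c, c+1] x [r, r+1] in px units, emitter at (x0, y0) px
.integratedGaussian <- function(rows, cols, x0, y0, sigma) {
    fx <- pnorm(cols + 1, x0, sigma) - pnorm(cols, x0, sigma)
    fy <- pnorm(rows + 1, y0, sigma) - pnorm(rows, y0, sigma)
    outer(fy, fx)
}

# derive a child seed (< 2^31) from a base seed and a stream label
.childSeed <- function(seed, stream) {
    if (is.null(seed)) return(NULL)
    as.integer((as.numeric(seed) * 69069 + 101 * stream) %% 2147483647)
}

.setSeed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))
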