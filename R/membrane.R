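# Membrane segmentation: phase-congruency edge strength (log-Gabor filter
# bank), Otsu binarization, morphological cleanup (EBImage) and sub-pixel
# ridge refinement of the closed cell contour.

#' Phase congruency edge-strength map
#'
#' Computes a noise-compensated phase-congruency map from a log-Gabor filter
#' bank (Kovesi-style, \code{nScale} scales x \code{nOrient} orientations).
#' Phase congruency marks locations where Fourier components are maximally
#' in phase (edges, ridges) and, being a normalized quantity, is invariant
#' to affine rescaling of image intensity -- the property that makes it a
#' robust membrane detector across staining intensities.
#'
#' @param img numeric matrix.
#' @param nScale number of filter scales (>= 3).
#' @param nOrient number of filter orientations (>= 4).
#' @param minWavelength wavelength of the smallest-scale filter, px.
#' @param mult scaling factor between successive filter wavelengths.
#' @param sigmaOnf bandwidth parameter of the log-Gabor radial component.
#' @param k noise compensation: threshold = mean + k * sd of the estimated
#'   noise energy distribution.
#' @return matrix of phase congruency values in [0, 1].
#' @export
phaseCongruency <- function(img, nScale = 3L, nOrient = 6L,
                            minWavelength = 4, mult = 2.1, sigmaOnf = 0.55,
                            k = 2) {
    eps <- 1e-4
    ny <- nrow(img); nx <- ncol(img)
    IM <- fft(img)
    # frequency grids in cycles/px, natural (unshifted) FFT order
    fx <- (seq_len(nx) - 1); fx[fx > nx / 2] <- fx[fx > nx / 2] - nx; fx <- fx / nx
    fy <- (seq_len(ny) - 1); fy[fy > ny / 2] <- fy[fy > ny / 2] - ny; fy <- fy / ny
    FX <- matrix(fx, ny, nx, byrow = TRUE)
    FY <- matrix(fy, ny, nx)
    radius <- sqrt(FX^2 + FY^2); radius[1, 1] <- 1
    theta <- atan2(-FY, FX)
    sintheta <- sin(theta); costheta <- cos(theta)
    lp <- 1 / (1 + (radius / 0.45)^30)  # low-pass to tame the corners
    logGabor <- vector("list", nScale)
    for (s in seq_len(nScale)) {
        wl <- minWavelength * mult^(s - 1)
        f0 <- 1 / wl
        lg <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2)) * lp
        lg[1, 1] <- 0
        logGabor[[s]] <- lg
    }
    thetaSigma <- pi / nOrient / 1.2
    totalEnergy <- matrix(0, ny, nx)
    totalSumAn <- matrix(0, ny, nx)
    for (o in seq_len(nOrient)) {
        angl <- (o - 1) * pi / nOrient
        ds <- sintheta * cos(angl) - costheta * sin(angl)
        dc <- costheta * cos(angl) + sintheta * sin(angl)
        dtheta <- abs(atan2(ds, dc))
        spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
        sumE <- sumO <- sumAn <- maxAn <- matrix(0, ny, nx)
        EOr <- EOi <- vector("list", nScale)
        tau <- NULL
        for (s in seq_len(nScale)) {
            EO <- fft(IM * logGabor[[s]] * spread, inverse = TRUE) / (ny * nx)
            re <- Re(EO); im <- Im(EO)
            An <- sqrt(re^2 + im^2)
            EOr[[s]] <- re; EOi[[s]] <- im
            sumE <- sumE + re; sumO <- sumO + im; sumAn <- sumAn + An
            maxAn <- pmax(maxAn, An)
            if (s == 1L) tau <- median(An) / sqrt(log(4))
        }
        XEnergy <- sqrt(sumE^2 + sumO^2) + eps
        MeanE <- sumE / XEnergy; MeanO <- sumO / XEnergy
        Energy <- matrix(0, ny, nx)
        for (s in seq_len(nScale)) {
            Energy <- Energy + EOr[[s]] * MeanE + EOi[[s]] * MeanO -
                abs(EOr[[s]] * MeanO - EOi[[s]] * MeanE)
        }
        # Rayleigh-based noise energy estimate from the smallest scale
        totalTau <- tau * (1 - (1 / mult)^nScale) / (1 - 1 / mult)
        noiseMean <- totalTau * sqrt(pi / 2)
        noiseSigma <- totalTau * sqrt((4 - pi) / 2)
        Tn <- noiseMean + k * noiseSigma
        Energy <- pmax(Energy - Tn, 0)
        # weight down pixels with a narrow filter-response spread
        width <- (sumAn / (maxAn + eps) - 1) / (nScale - 1)
        weight <- 1 / (1 + exp(10 * (0.5 - width)))
        totalEnergy <- totalEnergy + weight * Energy
        totalSumAn <- totalSumAn + sumAn
    }
    pc <- totalEnergy / (totalSumAn + eps)
    pmin(pmax(pc, 0), 1)
}

# gradient-magnitude fallback edge map (contrast-normalized)
.gradientRidge <- function(img) {
    sm <- .gaussianBlur(img, 1)
    gx <- sm; gy <- sm
    gx[, ] <- 0; gy[, ] <- 0
    gx[, 2:(ncol(sm) - 1)] <- (sm[, 3:ncol(sm)] - sm[, 1:(ncol(sm) - 2)]) / 2
    gy[2:(nrow(sm) - 1), ] <- (sm[3:nrow(sm), ] - sm[1:(nrow(sm) - 2), ]) / 2
    g <- sqrt(gx^2 + gy^2)
    if (max(g) > 0) g / max(g) else g
}

# refine 0-based boundary pixel chain to the sub-pixel crest of `strength`
# by a weighted centroid along the local outward normal (+- reach px);
# two passes, the second recentering the sampling window on the first result
.refineRidge <- function(chain_rc, strength, reach = 3, passes = 2L) {
    # chain in (x, y) px coordinates (pixel centers at index + 0.5)
    poly <- cbind(chain_rc[, 2] + 0.5, chain_rc[, 1] + 0.5)
    for (pass in seq_len(passes)) poly <- .refineRidgeOnce(poly, strength, reach)
    poly
}

.refineRidgeOnce <- function(poly, strength, reach = 3) {
    ny <- nrow(strength); nx <- ncol(strength)
    nrm <- .polygonNormals(poly)
    ts <- seq(-reach, reach, by = 0.25)
    bilinear <- function(x, y) {
        x <- pmin(pmax(x, 0.5), nx - 0.5) - 0.5
        y <- pmin(pmax(y, 0.5), ny - 0.5) - 0.5
        c0 <- floor(x); r0 <- floor(y)
        c0 <- pmin(c0, nx - 2L); r0 <- pmin(r0, ny - 2L)
        fx <- x - c0; fy <- y - r0
        i <- cbind(r0 + 1, c0 + 1)
        strength[i] * (1 - fx) * (1 - fy) +
            strength[cbind(r0 + 1, c0 + 2)] * fx * (1 - fy) +
            strength[cbind(r0 + 2, c0 + 1)] * (1 - fx) * fy +
            strength[cbind(r0 + 2, c0 + 2)] * fx * fy
    }
    out <- poly
    for (i in seq_len(nrow(poly))) {
        xs <- poly[i, 1] + ts * nrm[i, 1]
        ys <- poly[i, 2] + ts * nrm[i, 2]
        w <- bilinear(xs, ys)
        w <- pmax(w - min(w), 0)  # local background removal: affine-invariant
        if (sum(w) > 0) {
            t0 <- sum(ts * w) / sum(w)
            out[i, ] <- poly[i, ] + t0 * nrm[i, ]
        }
    }
    # light smoothing along the chain tames pixel-level jitter
    n <- nrow(out)
    if (n >= 5L) {
        sm <- function(v) (v[c(n - 1, n, 1:(n - 2))] + v[c(n, 1:(n - 1))] + v +
                           v[c(2:n, 1)] + v[c(3:n, 1, 2)]) / 5
        out <- cbind(sm(out[, 1]), sm(out[, 2]))
    }
    out
}

#' Segment the cell membrane from a membrane-label z-stack
#'
#' Per plane: compute the phase-congruency edge map, binarize it by Otsu's
#' threshold intersected with an intensity mask, keep the largest connected
#' component, close it (hole filling), trace its boundary and refine each
#' boundary vertex to the sub-pixel crest of the ridge along the local
#' normal. Planes where no sufficiently large closed contour is found are
#' marked empty (NULL), not fatal.
#'
#' @param stack a [RawZStack-class] (membrane channel) or 3D array of
#'   calibrated counts.
#' @param cam a [CameraModel-class] when \code{stack} is a bare array.
#' @param method \code{"phase_congruency"} (default) or
#'   \code{"gradient_ridge"} fallback; the choice is recorded in the result.
#' @param minArea smallest component area (px) considered a cell section.
#' @param ... passed to [phaseCongruency()].
#' @return A [MembraneMap-class].
#' @export
segmentMembrane <- function(stack, cam = NULL,
                            method = c("phase_congruency", "gradient_ridge"),
                            minArea = 50, ...) {
    method <- match.arg(method)
    if (is(stack, "RawZStack")) {
        cam <- stack@camera
        arr <- calibrateFrame(stack)
        zStep <- stack@zStep
    } else {
        arr <- if (length(dim(stack)) == 2L)
            array(stack, dim = c(dim(stack), 1L)) else stack
        if (is.null(cam)) cam <- cameraModel(offset = 0, gain = 1)
        else arr <- calibrateFrame(arr, cam)
        zStep <- 0.3
    }
    p <- cam@pixelSize
    nP <- dim(arr)[3]
    contours <- vector("list", nP)
    pcMaps <- vector("list", nP)
    for (kPlane in seq_len(nP)) {
        img <- arr[, , kPlane]
        if (diff(range(img)) <= 0) { pcMaps[[kPlane]] <- img * 0; next }
        pc <- if (method == "phase_congruency") phaseCongruency(img, ...)
              else .gradientRidge(img)
        pcMaps[[kPlane]] <- pc
        mask <- pc > .otsu(pc) & img > .otsu(img)
        if (!any(mask)) next
        lab <- EBImage::bwlabel(mask * 1)
        sizes <- tabulate(lab[lab > 0])
        if (length(sizes) == 0L || max(sizes) < minArea) next
        big <- (lab == which.max(sizes)) * 1
        filled <- EBImage::fillHull(big)
        if (sum(filled) <= sum(big)) next  # ridge did not close a region
        oc <- EBImage::ocontour(filled)
        if (length(oc) == 0L) next
        chain <- oc[[which.max(vapply(oc, nrow, 1L))]]
        if (nrow(chain) < 8L) next
        # refine to the crest of the (smoothed) intensity ridge: the PC map
        # localizes the membrane, the intensity profile centers it
        refined <- .refineRidge(chain, .gaussianBlur(img, 0.8))
        ctr <- cbind(x = refined[, 1] * p, y = refined[, 2] * p)
        if (.polygonSelfIntersects(ctr)) {
            # fall back to the unrefined (pixel-level) boundary
            ctr <- cbind(x = (chain[, 2] + 0.5) * p, y = (chain[, 1] + 0.5) * p)
        }
        contours[[kPlane]] <- ctr
    }
    new("MembraneMap", contours = contours, pcMaps = pcMaps, pixelSize = p,
        zStep = zStep, method = method)
}
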