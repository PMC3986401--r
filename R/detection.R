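# Detection: camera calibration, difference-of-Gaussian candidate finding,
# Poisson maximum-likelihood Gaussian PSF fitting with CRLB uncertainties,
# and a log-likelihood-ratio goodness-of-fit filter.

#' Convert raw camera data to Poisson-scale photon counts
#'
#' Inverts the camera model elementwise: \code{counts = (raw - offset) /
#' gain}, so that downstream maximum-likelihood fitting can treat pixel
#' values as (approximately) Poisson distributed.
#'
#' @param raw a numeric matrix (one frame), a 3D array, a [RawMovie-class]
#'   or a [RawZStack-class].
#' @param cam a [CameraModel-class]; taken from the object when \code{raw}
#'   is a RawMovie/RawZStack.
#' @return An object of the same shape as the input, in photon counts.
#' @examples
#' calibrateFrame(matrix(600, 2, 2), cameraModel(offset = 100, gain = 5))
#' @export
calibrateFrame <- function(raw, cam = NULL) {
    if (is(raw, "RawMovie")) { if (is.null(cam)) cam <- raw@camera; raw <- raw@frames }
    else if (is(raw, "RawZStack")) { if (is.null(cam)) cam <- raw@camera; raw <- raw@planes }
    if (is.null(cam)) stop("a CameraModel is required")
    (raw - cam@offset) / cam@gain
}

# separable Gaussian blur with replicated edges
.gaussianBlur <- function(img, sigma) {
    hw <- max(1L, ceiling(3 * sigma))
    k <- dnorm(-hw:hw, 0, sigma); k <- k / sum(k)
    pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
    convRows <- function(m) t(apply(m, 1, function(v)
        stats::filter(pad(v, hw), k, sides = 2)[(hw + 1):(hw + length(v))]))
    m <- convRows(img)
    t(convRows(t(m)))
}

#' Find candidate spot pixels by difference-of-Gaussian filtering
#'
#' Band-pass filters the frame with a difference of Gaussians and returns
#' local maxima above threshold, excluding a border of half the fitting ROI.
#' Candidate pairs closer than one ROI width keep only the brighter member
#' (ties broken by lower row, then column).
#'
#' @param frame calibrated photon-count matrix.
#' @param sigmaSmall,sigmaLarge DoG standard deviations in pixels
#'   (\code{sigmaSmall < sigmaLarge}).
#' @param threshold DoG response threshold in counts; default 4 times the
#'   robust MAD of the filtered frame.
#' @param roiSize fitting ROI width in pixels (odd).
#' @return integer matrix with columns \code{row}, \code{col} (0-based pixel
#'   indices) and \code{response}; zero rows when nothing is found.
#' @export
findCandidates <- function(frame, sigmaSmall = 1.0, sigmaLarge = 2.0,
                           threshold = NULL, roiSize = 7L) {
    stopifnot(sigmaSmall < sigmaLarge)
    half <- roiSize %/% 2L
    ny <- nrow(frame); nx <- ncol(frame)
    if (ny < roiSize || nx < roiSize) stop("frame smaller than filter support")
    dog <- .gaussianBlur(frame, sigmaSmall) - .gaussianBlur(frame, sigmaLarge)
    if (is.null(threshold))
        threshold <- 4 * mad(as.vector(dog), center = median(dog))
    if (threshold <= 0) threshold <- .Machine$double.eps
    empty <- cbind(row = integer(0), col = integer(0), response = numeric(0))
    # strict local maxima over the 8-neighborhood
    inner_r <- (half + 1L):(ny - half); inner_c <- (half + 1L):(nx - half)
    if (length(inner_r) < 1L || length(inner_c) < 1L) return(empty)
    cand <- NULL
    D <- dog
    for (r in inner_r) for (c in inner_c) {
        v <- D[r, c]
        if (v <= threshold) next
        nb <- D[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
        if (v >= max(nb) && sum(nb == v) == 1L)
            cand <- rbind(cand, c(r - 1L, c - 1L, v))
    }
    if (is.null(cand)) return(empty)
    colnames(cand) <- c("row", "col", "response")
    # proximity suppression: within one ROI width keep the brighter
    ord <- order(-cand[, "response"], cand[, "row"], cand[, "col"])
    cand <- cand[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (!keep[i]) next
        if (i < nrow(cand)) {
            j <- (i + 1L):nrow(cand)
            tooClose <- keep[j] &
                abs(cand[j, "row"] - cand[i, "row"]) < roiSize &
                abs(cand[j, "col"] - cand[i, "col"]) < roiSize
            keep[j][tooClose] <- FALSE
        }
    }
    out <- cand[keep, , drop = FALSE]
    out[order(out[, "row"], out[, "col"]), , drop = FALSE]
}

# model pieces for the integrated-Gaussian Poisson likelihood on an ROI
.roiModel <- function(nR, nC, x, y, sigma) {
    rows <- 0:(nR - 1L); cols <- 0:(nC - 1L)
    Ex <- pnorm(cols + 1, x, sigma) - pnorm(cols, x, sigma)
    Ey <- pnorm(rows + 1, y, sigma) - pnorm(rows, y, sigma)
    dEx <- dnorm(cols, x, sigma) - dnorm(cols + 1, x, sigma)
    dEy <- dnorm(rows, y, sigma) - dnorm(rows + 1, y, sigma)
    d2Ex <- dnorm(cols, x, sigma) * (cols - x) / sigma^2 -
            dnorm(cols + 1, x, sigma) * (cols + 1 - x) / sigma^2
    d2Ey <- dnorm(rows, y, sigma) * (rows - y) / sigma^2 -
            dnorm(rows + 1, y, sigma) * (rows + 1 - y) / sigma^2
    list(Ex = Ex, Ey = Ey, dEx = dEx, dEy = dEy, d2Ex = d2Ex, d2Ey = d2Ey)
}

#' Fit a single spot by Poisson maximum likelihood
#'
#' Maximizes the Poisson log-likelihood \code{sum(d * log(mu) - mu)} with
#' \code{mu = bg + N * (integrated 2D Gaussian)} over position, signal
#' photons and background by coordinate-wise Newton ascent (capped at
#' \code{maxIter} iterations; converged when the position update falls below
#' 1e-4 px). The theoretical localization precision (CRLB) is computed from
#' the Fisher information of the same model.
#'
#' @param roi odd-sized square matrix of photon counts around the candidate.
#' @param psfSigma PSF standard deviation in pixels (held fixed unless
#'   \code{fitSigma}).
#' @param pixelSize pixel size in um (for the um-scale outputs).
#' @param origin 0-based (row, col) frame pixel of \code{roi[1,1]}, so
#'   positions can be reported in frame coordinates.
#' @param fitSigma also optimize the PSF width (free-sigma variant).
#' @param maxIter iteration cap.
#' @return A \code{SpotFit} list: \code{x, y} (um, frame coordinates),
#'   \code{x_px, y_px} (0-based frame pixel units), \code{photons},
#'   \code{background} (photons/px), \code{sigma_fit} (px), \code{loglik},
#'   \code{llr} (2 * (saturated - fitted) log-likelihood), \code{pvalue}
#'   (chi-square upper tail, dof = npixels - 4), \code{crlb_xy} (um),
#'   \code{converged} and \code{accepted} (set by [llrFilter()]).
#' @export
fitSpotMLE <- function(roi, psfSigma = 1.2, pixelSize = 0.127,
                       origin = c(0L, 0L), fitSigma = FALSE, maxIter = 30L) {
    nR <- nrow(roi); nC <- ncol(roi)
    if (nR %% 2L == 0L || nC %% 2L == 0L) stop("ROI must be odd-sized")
    d <- pmax(roi, 0)
    if (all(d == 0)) stop("all-zero ROI")
    # moment initialisation
    bg <- max(min(d), .Machine$double.eps)
    N <- max(sum(d) - bg * nR * nC, 10)
    x <- nC / 2; y <- nR / 2
    sig <- psfSigma
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        mdl <- .roiModel(nR, nC, x, y, sig)
        mu <- bg + N * outer(mdl$Ey, mdl$Ex)
        mu <- pmax(mu, 1e-12)
        rat <- d / mu - 1
        dmu_dx <- N * outer(mdl$Ey, mdl$dEx)
        dmu_dy <- N * outer(mdl$dEy, mdl$Ex)
        d2mu_dx <- N * outer(mdl$Ey, mdl$d2Ex)
        d2mu_dy <- N * outer(mdl$d2Ey, mdl$Ex)
        dmu_dN <- outer(mdl$Ey, mdl$Ex)
        newton <- function(d1, d2) {
            num <- sum(d1 * rat)
            den <- sum(d2 * rat - d1^2 * d / mu^2)
            if (!is.finite(den) || den == 0) 0 else num / den
        }
        dx <- -newton(dmu_dx, d2mu_dx)
        dy <- -newton(dmu_dy, d2mu_dy)
        dx <- max(-1, min(1, dx)); dy <- max(-1, min(1, dy))
        x <- x + dx; y <- y + dy
        dN <- -newton(dmu_dN, 0 * dmu_dN)
        N <- max(N + dN, 1e-3)
        dbg <- -newton(matrix(1, nR, nC), matrix(0, nR, nC))
        bg <- max(bg + dbg, 1e-6)
        if (fitSigma) {
            # Newton step on sigma with numerical second derivative
            ll <- function(s) {
                m <- .roiModel(nR, nC, x, y, s)
                muS <- pmax(bg + N * outer(m$Ey, m$Ex), 1e-12)
                sum(d * log(muS) - muS)
            }
            h <- 1e-3
            g1 <- (ll(sig + h) - ll(sig - h)) / (2 * h)
            g2 <- (ll(sig + h) - 2 * ll(sig) + ll(sig - h)) / h^2
            if (is.finite(g2) && g2 < 0)
                sig <- max(0.3, min(5, sig - g1 / g2))
        }
        if (max(abs(dx), abs(dy)) < 1e-4) { converged <- TRUE; break }
    }
    mdl <- .roiModel(nR, nC, x, y, sig)
    mu <- pmax(bg + N * outer(mdl$Ey, mdl$Ex), 1e-12)
    loglik <- sum(d * log(mu) - mu)
    llSat <- sum(ifelse(d > 0, d * log(d) - d, 0))
    llr <- max(0, 2 * (llSat - loglik))
    dof <- nR * nC - 4L
    pvalue <- pchisq(llr, df = dof, lower.tail = FALSE)
    # Fisher information for (x, y, N, bg)
    derivs <- list(
        x = N * outer(mdl$Ey, mdl$dEx),
        y = N * outer(mdl$dEy, mdl$Ex),
        N = outer(mdl$Ey, mdl$Ex),
        bg = matrix(1, nR, nC))
    FI <- matrix(0, 4, 4)
    for (i in 1:4) for (j in i:4) {
        FI[i, j] <- FI[j, i] <- sum(derivs[[i]] * derivs[[j]] / mu)
    }
    crlb_px <- tryCatch(sqrt(pmax(diag(solve(FI))[1:2], 0)),
                        error = function(e) c(NA_real_, NA_real_))
    structure(list(
        x = (origin[2] + x) * pixelSize, y = (origin[1] + y) * pixelSize,
        x_px = origin[2] + x, y_px = origin[1] + y,
        photons = N, background = bg, sigma_fit = sig,
        loglik = loglik, llr = llr, pvalue = pvalue,
        crlb_xy = mean(crlb_px) * pixelSize,
        converged = converged, accepted = NA), class = "SpotFit")
}

#' @export
print.SpotFit <- function(x, ...) {
    cat(sprintf("SpotFit: (%.4f, %.4f) um, %.0f photons, bg %.2f, crlb %.1f nm, LLR p=%.3g%s\n",
                x$x, x$y, x$photons, x$background, 1000 * x$crlb_xy, x$pvalue,
                if (isTRUE(x$accepted)) " [accepted]" else ""))
    invisible(x)
}

#' Filter spot fits by intensity and PSF-shape likelihood ratio
#'
#' A fit is accepted iff its fitted photon count reaches
#' \code{intensityMin} and the log-likelihood-ratio statistic
#' \code{2 * (LL_saturated - LL_fit)} is compatible with the PSF model,
#' i.e. its chi-square upper-tail p-value (dof = npixels - 4) is at least
#' \code{llrPvalueMax}. Misfits (e.g. two overlapping spots fit as one)
#' produce large LLR values and small p-values, and are rejected.
#'
#' @param fits list of \code{SpotFit} objects.
#' @param intensityMin minimum fitted photons.
#' @param llrPvalueMax p-value floor (default 1e-3).
#' @return The same list with \code{accepted} set on every fit.
#' @export
llrFilter <- function(fits, intensityMin = 100, llrPvalueMax = 1e-3) {
    lapply(fits, function(f) {
        f$accepted <- is.finite(f$photons) && f$photons >= intensityMin &&
            is.finite(f$pvalue) && f$pvalue >= llrPvalueMax
        f
    })
}

#' Detect and fit all spots in a movie or single frame
#'
#' Frame-level convenience wrapper: calibrate, find DoG candidates, fit each
#' candidate ROI by Poisson maximum likelihood, and apply the LLR filter.
#'
#' @param x a [RawMovie-class], [RawZStack-class], or calibrated matrix.
#' @param cam a [CameraModel-class] (taken from \code{x} when available).
#' @param psfSigma PSF sigma in px used by the fitter.
#' @param roiSize fitting ROI width (odd).
#' @param sigmaSmall,sigmaLarge,threshold DoG parameters, see
#'   [findCandidates()].
#' @param intensityMin,llrPvalueMax acceptance filter, see [llrFilter()].
#' @param fitSigma free-sigma fitting.
#' @param keepRejected keep rejected fits in the output (flagged).
#' @return data.frame with one row per fit: \code{frame, x_um, y_um, x_px,
#'   y_px, photons, bg, sigma_fit, crlb_um, llr, pvalue, converged,
#'   accepted}.
#' @export
detectSpots <- function(x, cam = NULL, psfSigma = 1.2, roiSize = 7L,
                        sigmaSmall = 1.0, sigmaLarge = 2.0, threshold = NULL,
                        intensityMin = 100, llrPvalueMax = 1e-3,
                        fitSigma = FALSE, keepRejected = FALSE) {
    if (is(x, "RawMovie")) { cam <- x@camera; arr <- x@frames }
    else if (is(x, "RawZStack")) { cam <- x@camera; arr <- x@planes }
    else if (is.matrix(x)) arr <- array(x, dim = c(nrow(x), ncol(x), 1L))
    else arr <- x
    if (is.null(cam)) stop("a CameraModel is required")
    half <- roiSize %/% 2L
    rows <- list()
    for (f in seq_len(dim(arr)[3])) {
        frame <- calibrateFrame(arr[, , f], cam)
        cand <- findCandidates(frame, sigmaSmall, sigmaLarge, threshold, roiSize)
        if (nrow(cand) == 0L) next
        fits <- lapply(seq_len(nrow(cand)), function(i) {
            r <- cand[i, "row"]; c <- cand[i, "col"]
            roi <- frame[(r - half + 1L):(r + half + 1L),
                         (c - half + 1L):(c + half + 1L)]
            fitSpotMLE(roi, psfSigma, cam@pixelSize,
                       origin = c(r - half, c - half), fitSigma = fitSigma)
        })
        fits <- llrFilter(fits, intensityMin, llrPvalueMax)
        for (ft in fits) {
            if (!ft$accepted && !keepRejected) next
            rows[[length(rows) + 1L]] <- data.frame(
                frame = f, x_um = ft$x, y_um = ft$y,
                x_px = ft$x_px, y_px = ft$y_px,
                photons = ft$photons, bg = ft$background,
                sigma_fit = ft$sigma_fit, crlb_um = ft$crlb_xy,
                llr = ft$llr, pvalue = ft$pvalue,
                converged = ft$converged, accepted = ft$accepted)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                          x_px = numeric(), y_px = numeric(), photons = numeric(),
                          bg = numeric(), sigma_fit = numeric(), crlb_um = numeric(),
                          llr = numeric(), pvalue = numeric(),
                          converged = logical(), accepted = logical()))
    do.call(rbind, rows)
}
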