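# Trajectory dynamics: MSD computation and free/corralled diffusion fits,
# smooth-path fitting with arc-length speeds, motion-phase segmentation.

# accept either linked-trajectory (x_um/y_um) or truth (x/y) column naming
.trajXY <- function(traj) {
    x <- if (!is.null(traj$x_um)) traj$x_um else traj$x
    y <- if (!is.null(traj$y_um)) traj$y_um else traj$y
    if (is.null(x) || is.null(y)) stop("trajectory needs x_um/y_um (or x/y) columns")
    list(x = x, y = y)
}

#' Mean square displacement of a trajectory
#'
#' \code{msd(k * dt) = mean over i of |r(i+k) - r(i)|^2} using all valid
#' frame pairs; pairs touching bridged (gap) frames are excluded since those
#' carry no localization.
#'
#' @param traj a \code{Trajectory} data.frame (columns \code{frame, t, x_um,
#'   y_um, gap}) or any data.frame with those columns (\code{gap} optional).
#' @param maxLagFraction largest lag as a fraction of trajectory length
#'   (default 1/4).
#' @return An \code{MSDCurve} list: \code{lags} (s), \code{msd} (um^2),
#'   \code{nPairs}, \code{dt}.
#' @export
computeMSD <- function(traj, maxLagFraction = 0.25) {
    if (nrow(traj) < 10L) stop("trajectory too short for MSD (need >= 10 frames)")
    gap <- if (is.null(traj$gap)) rep(FALSE, nrow(traj)) else traj$gap
    dt <- median(diff(traj$t))
    n <- nrow(traj)
    maxLag <- max(1L, floor(n * maxLagFraction))
    lags <- seq_len(maxLag)
    msd <- numeric(maxLag); np <- integer(maxLag)
    xy <- .trajXY(traj); x <- xy$x; y <- xy$y
    ok <- !gap
    for (k in lags) {
        i <- seq_len(n - k)
        use <- ok[i] & ok[i + k]
        np[k] <- sum(use)
        msd[k] <- if (np[k] > 0)
            mean((x[i + k][use] - x[i][use])^2 + (y[i + k][use] - y[i][use])^2)
            else NA_real_
    }
    structure(list(lags = lags * dt, msd = msd, nPairs = np, dt = dt),
              class = "MSDCurve")
}

#' @export
print.MSDCurve <- function(x, ...) {
    cat(sprintf("MSDCurve: %d lags (dt %.4g s), msd[1] = %.4g um^2\n",
                length(x$lags), x$dt, x$msd[1]))
    if (!is.null(x$fit))
        cat(sprintf("  fit: %s model, D = %.4g um^2/s%s, offset %.4g um^2%s\n",
                    x$fit$model, x$fit$D,
                    if (x$fit$model == "corralled")
                        sprintf(", L = %.3g um", x$fit$L) else "",
                    x$fit$offset,
                    if (isTRUE(x$fit$flagged)) " [poor fit]" else ""))
    invisible(x)
}

#' Fit free and corralled diffusion models to an MSD curve
#'
#' Free diffusion: \code{msd = 4 * D * dt + offset} (weighted least squares,
#' weights proportional to the number of averaged pairs per lag). Corralled
#' diffusion in a domain of characteristic size L:
#' \code{msd = (L^2 / 3) * (1 - exp(-12 * D * dt / L^2)) + offset}, which
#' rises with initial slope 4 D and saturates near \code{L^2 / 3}. Both are
#' fit over the first \code{min(nFitLags, length)} lags and the model with
#' the lower AIC is selected; \code{offset >= 0, D >= 0, L > 0} are
#' enforced. A ballistic alternative (\code{v^2 dt^2 + offset}) is also
#' scored as a diagnostic: when it clearly outperforms both diffusion models
#' the fit is flagged, guarding against applying diffusion models to
#' directed motion.
#'
#' @param msdc an \code{MSDCurve} from [computeMSD()].
#' @param nFitLags number of leading lags used (default 10).
#' @return The \code{MSDCurve} with a \code{fit} element: \code{model}
#'   ("free" or "corralled"), \code{D}, \code{L} (NA for free),
#'   \code{offset}, \code{aic} (named vector), \code{converged},
#'   \code{flagged}.
#' @export
fitMSD <- function(msdc, nFitLags = 10L) {
    ok <- is.finite(msdc$msd) & msdc$nPairs > 0
    lags <- msdc$lags[ok]; y <- msdc$msd[ok]; w <- msdc$nPairs[ok]
    nUse <- min(nFitLags, length(lags))
    if (nUse < 4L) stop("need at least 4 lags to fit MSD models")
    lags <- lags[seq_len(nUse)]; y <- y[seq_len(nUse)]; w <- w[seq_len(nUse)]
    w <- w / mean(w)
    aicOf <- function(res, k) nUse * log(sum(w * res^2) / nUse) + 2 * k
    # free: constrained linear fit
    lmfit <- lm(y ~ lags, weights = w)
    Dfree <- max(coef(lmfit)[2] / 4, 0)
    offFree <- max(coef(lmfit)[1], 0)
    resFree <- y - (4 * Dfree * lags + offFree)
    aicFree <- aicOf(resFree, 2)
    # corralled: bounded Levenberg-Marquardt
    corral <- tryCatch({
        Lstart <- sqrt(3 * max(y))
        Dstart <- max(Dfree, (y[1] - min(y[1], offFree)) / (4 * lags[1]), 1e-6)
        nf <- minpack.lm::nlsLM(
            y ~ off + (L^2 / 3) * (1 - exp(-12 * D * lags / L^2)),
            start = list(off = min(y[1] / 2, offFree), D = Dstart, L = Lstart),
            lower = c(0, 0, 1e-4), upper = c(Inf, Inf, Inf),
            weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- coef(nf)
        list(D = cf[["D"]], L = cf[["L"]], offset = cf[["off"]],
             res = y - predict(nf), converged = TRUE)
    }, error = function(e) NULL)
    aicCorral <- if (is.null(corral)) Inf else aicOf(corral$res, 3)
    # ballistic diagnostic
    bal <- lm(y ~ I(lags^2), weights = w)
    aicBal <- aicOf(residuals(bal), 2)
    aic <- c(free = aicFree, corralled = aicCorral, ballistic = aicBal)
    flagged <- aicBal + 2 < min(aicFree, aicCorral)
    if (aicFree <= aicCorral || is.null(corral)) {
        fit <- list(model = "free", D = unname(Dfree), L = NA_real_,
                    offset = unname(offFree), aic = aic,
                    corralConverged = !is.null(corral), flagged = flagged)
    } else {
        fit <- list(model = "corralled", D = unname(corral$D),
                    L = unname(corral$L), offset = unname(corral$offset),
                    aic = aic, corralConverged = TRUE, flagged = flagged)
    }
    msdc$fit <- fit
    msdc
}

#' Fit a smooth path through a trajectory
#'
#' Represents the particle path by least-squares fits of x(t) and y(t),
#' either a second-order polynomial or a regression spline whose number of
#' segments is, by default, increased until the residual RMS falls below
#' twice the median localization uncertainty (a smooth fit that does not
#' truncate features).
#'
#' @param traj Trajectory data.frame (\code{t, x_um, y_um}; gap rows are
#'   ignored).
#' @param method \code{"spline"} or \code{"poly2"}.
#' @param nSegments spline segment count; \code{NULL} (default) selects
#'   automatically.
#' @param locSigma localization uncertainty (um) for automatic segment
#'   selection; default the median \code{crlb_um} if present, else 0.03.
#' @return A \code{SmoothPath} list: \code{method, nSegments, arcLength}
#'   (um), \code{predict(t)} returning path points, \code{points} (dense
#'   n x 2 polyline), \code{tRange}, \code{residualRMS}.
#' @export
fitSmoothPath <- function(traj, method = c("spline", "poly2"),
                          nSegments = NULL, locSigma = NULL) {
    method <- match.arg(method)
    obs <- if (is.null(traj$gap)) traj else traj[!traj$gap, , drop = FALSE]
    t <- obs$t
    xy <- .trajXY(obs); x <- xy$x; y <- xy$y
    if (is.null(locSigma))
        locSigma <- if (!is.null(obs$crlb_um) && any(is.finite(obs$crlb_um)))
            median(obs$crlb_um, na.rm = TRUE) else 0.03
    makeFit <- function(nseg) {
        if (method == "poly2") {
            fx <- lm(x ~ poly(t, 2, raw = TRUE))
            fy <- lm(y ~ poly(t, 2, raw = TRUE))
        } else {
            df <- max(3L, nseg + 2L)  # cubic B-spline with nseg segments
            if (length(t) < 2L * df) return(NULL)
            basis <- splines::bs(t, df = df)
            fx <- lm(x ~ basis); fy <- lm(y ~ basis)
        }
        prd <- function(tt) {
            tt <- pmin(pmax(tt, min(t)), max(t))
            if (method == "poly2") {
                nd <- data.frame(t = tt)
                cbind(predict(fx, nd), predict(fy, nd))
            } else {
                nb <- predict(basis, tt)
                cbind(cbind(1, nb) %*% coef(fx), cbind(1, nb) %*% coef(fy))
            }
        }
        rms <- sqrt(mean(residuals(fx)^2 + residuals(fy)^2))
        list(predict = prd, rms = rms)
    }
    if (method == "poly2") {
        ft <- makeFit(0L); nseg <- 1L
        if (length(t) < 6L) stop("underdetermined fit")
    } else {
        target <- 2 * locSigma
        nseg <- if (!is.null(nSegments)) nSegments else 3L
        ft <- makeFit(nseg)
        if (is.null(ft)) stop("underdetermined fit")
        if (is.null(nSegments)) {
            while (ft$rms > target) {
                nxt <- makeFit(nseg + 2L)
                if (is.null(nxt) || nxt$rms >= ft$rms * 0.999) break
                nseg <- nseg + 2L; ft <- nxt
            }
        }
    }
    tt <- seq(min(t), max(t), length.out = max(20L * length(t) %/% 10L, 200L))
    pts <- ft$predict(tt)
    arc <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
    structure(list(method = method, nSegments = nseg, arcLength = arc,
                   predict = ft$predict, points = pts,
                   tRange = range(t), residualRMS = ft$rms),
              class = "SmoothPath")
}

#' @export
print.SmoothPath <- function(x, ...) {
    cat(sprintf("SmoothPath (%s%s): arc length %.3f um, residual RMS %.1f nm\n",
                x$method,
                if (x$method == "spline") sprintf(", %d segments", x$nSegments) else "",
                x$arcLength, 1000 * x$residualRMS))
    invisible(x)
}

#' Arc-length position of each observation along a smooth path
#'
#' For each observed position the nearest point of the path is found; the
#' returned value is the arc length from the path start to that point.
#' Positive motion is along the path away from the start. Back-tracking is
#' allowed (s is not forced monotone); at exact ties the smaller arc length
#' wins.
#'
#' @param traj Trajectory data.frame.
#' @param path a \code{SmoothPath} from [fitSmoothPath()].
#' @return data.frame \code{t, s} (s in um), one row per non-gap
#'   observation.
#' @export
pathPosition <- function(traj, path) {
    obs <- if (is.null(traj$gap)) traj else traj[!traj$gap, , drop = FALSE]
    oxy <- .trajXY(obs)
    pts <- path$points
    cs <- .cumArcLength(pts)
    n <- nrow(pts)
    ax <- pts[-n, 1]; ay <- pts[-n, 2]
    dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
    len2 <- dx^2 + dy^2; len2[len2 == 0] <- .Machine$double.eps
    s <- vapply(seq_len(nrow(obs)), function(i) {
        # project onto every segment; smaller arc length wins exact ties
        tt <- pmin(1, pmax(0, ((oxy$x[i] - ax) * dx + (oxy$y[i] - ay) * dy) / len2))
        d2 <- (ax + tt * dx - oxy$x[i])^2 + (ay + tt * dy - oxy$y[i])^2
        k <- which.min(d2)
        cs[k] + tt[k] * sqrt(len2[k])
    }, numeric(1))
    data.frame(t = obs$t, s = s)
}

#' Piecewise speeds from path positions
#'
#' Fits a first-order polynomial to sections of path position versus time;
#' the section slope is the speed. Positive speed is motion along the path
#' away from the start position.
#'
#' @param sOfT data.frame \code{t, s} from [pathPosition()].
#' @param window section length in seconds.
#' @param step section spacing in seconds; defaults to \code{window}
#'   (non-overlapping sections).
#' @return data.frame \code{tMid, speed, n} (one row per section).
#' @export
estimateSpeeds <- function(sOfT, window = 2, step = NULL) {
    if (is.null(step)) step <- window
    t0 <- min(sOfT$t); t1 <- max(sOfT$t)
    if (t1 - t0 < window) stop("window longer than the record")
    starts <- seq(t0, t1 - window, by = step)
    rows <- lapply(starts, function(ws) {
        sel <- sOfT$t >= ws & sOfT$t <= ws + window
        if (sum(sel) < 3L) return(NULL)
        fit <- lm(s ~ t, data = sOfT[sel, ])
        data.frame(tMid = ws + window / 2, speed = coef(fit)[2], n = sum(sel))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Segment a trajectory into motion phases
#'
#' Rolling-window classification: a window is \emph{immobile} when its net
#' displacement is below \code{3 * locSigma}; \emph{directed} when the
#' windowed speed exceeds \code{vMin} and the straightness (net displacement
#' over summed path length) is at least \code{straightMin}; otherwise
#' \emph{diffusive}. Windows vote on the frames they cover and adjacent
#' same-kind runs merge into segments covering the trajectory.
#'
#' @param traj Trajectory data.frame spanning at least 4 s.
#' @param window window length, s (default 2).
#' @param step window step, s (default 0.5).
#' @param vMin minimum directed speed, um/s (default 0.2).
#' @param straightMin minimum straightness for directed motion (default 0.8).
#' @param locSigma localization sigma, um (default median \code{crlb_um} or
#'   0.03).
#' @return data.frame of \code{PhaseSegment}s: \code{start, end} (s),
#'   \code{kind} (directed | diffusive | immobile), \code{v} (um/s, mean
#'   window speed, NA unless directed), \code{duration}.
#' @export
segmentPhases <- function(traj, window = 2, step = 0.5, vMin = 0.2,
                          straightMin = 0.8, locSigma = NULL) {
    obs <- if (is.null(traj$gap)) traj else traj[!traj$gap, , drop = FALSE]
    if (diff(range(obs$t)) < 4) stop("trajectory shorter than 4 s")
    if (is.null(locSigma))
        locSigma <- if (!is.null(obs$crlb_um) && any(is.finite(obs$crlb_um)))
            median(obs$crlb_um, na.rm = TRUE) else 0.03
    t0 <- min(obs$t); t1 <- max(obs$t)
    starts <- seq(t0, max(t0, t1 - window), by = step)
    votes <- matrix(0, nrow(obs), 3,
                    dimnames = list(NULL, c("immobile", "directed", "diffusive")))
    speeds <- rep(NA_real_, length(starts))
    sxy <- .trajXY(obs)
    # moving-average smoothing (~window/4) tames localization noise so that
    # slow directed runs keep their straightness; partial means at the edges
    dtMed <- median(diff(obs$t))
    kMA <- max(1L, round(window / 4 / dtMed))
    movAvg <- function(v) {
        cs <- cumsum(c(0, v))
        h <- kMA %/% 2L
        i <- seq_along(v)
        lo <- pmax(i - h, 1L); hi <- pmin(i + h, length(v))
        (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    xs_all <- movAvg(sxy$x); ys_all <- movAvg(sxy$y)
    for (k in seq_along(starts)) {
        sel <- which(obs$t >= starts[k] & obs$t <= starts[k] + window)
        if (length(sel) < 3L) next
        # coarse polyline (5 points) over the smoothed track
        ci <- sel[unique(round(seq(1, length(sel), length.out = 5)))]
        xs <- xs_all[ci]; ys <- ys_all[ci]
        net <- sqrt((xs[length(xs)] - xs[1])^2 + (ys[length(ys)] - ys[1])^2)
        pathLen <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
        dtw <- obs$t[sel[length(sel)]] - obs$t[sel[1]]
        v <- net / dtw
        speeds[k] <- v
        kind <- if (net < 3 * locSigma) "immobile"
                else if (v >= vMin && net / max(pathLen, 1e-12) >= straightMin)
                    "directed"
                else "diffusive"
        votes[sel, kind] <- votes[sel, kind] + 1
    }
    kinds <- colnames(votes)[max.col(votes, ties.method = "first")]
    kinds[rowSums(votes) == 0] <- "diffusive"
    # merge contiguous runs
    runs <- rle(kinds)
    ends <- cumsum(runs$lengths); begins <- c(1, head(ends, -1) + 1)
    out <- data.frame(start = obs$t[begins], end = obs$t[ends],
                      kind = runs$values, v = NA_real_)
    for (i in seq_len(nrow(out))) {
        if (out$kind[i] == "directed") {
            inwin <- starts + window / 2 >= out$start[i] &
                     starts + window / 2 <= out$end[i]
            out$v[i] <- mean(speeds[inwin], na.rm = TRUE)
        }
    }
    out$duration <- out$end - out$start
    out
}
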