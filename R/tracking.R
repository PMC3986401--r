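# Trajectory building: rigid two-channel alignment, exact linear-assignment
# frame-to-frame linking with birth/death alternatives, and gap closing
# across blinking-induced detection gaps.

# Exact solver for the square linear assignment problem (Jonker-Volgenant /
# shortest augmenting path, O(n^3)). Returns for each row the assigned
# column. Forbidden entries should carry a large finite cost.
.lapSolve <- function(cost) {
    n <- nrow(cost)
    if (n == 0L) return(integer(0))
    stopifnot(ncol(cost) == n)
    INF <- .Machine$double.xmax / 4
    u <- numeric(n)        # row potentials
    v <- numeric(n + 1L)   # column potentials, index 1 = virtual column 0
    p <- integer(n + 1L)   # p[j+1]: row assigned to column j (0 = none)
    way <- integer(n + 1L)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(INF, n + 1L)
        used <- rep(FALSE, n + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            delta <- INF; j1 <- 0L
            js <- which(!used[2:(n + 1L)])
            if (length(js)) {
                cur <- cost[i0, js] - u[i0] - v[js + 1L]
                upd <- cur < minv[js + 1L]
                if (any(upd)) {
                    minv[js[upd] + 1L] <- cur[upd]
                    way[js[upd] + 1L] <- j0
                }
                k <- which.min(minv[js + 1L])
                delta <- minv[js[k] + 1L]
                j1 <- js[k]
            }
            usedIdx <- which(used)
            rowsUsed <- p[usedIdx]
            u[rowsUsed[rowsUsed > 0]] <- u[rowsUsed[rowsUsed > 0]] + delta
            v[usedIdx] <- v[usedIdx] - delta
            notUsed <- which(!used)
            minv[notUsed] <- minv[notUsed] - delta
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    rowsol <- integer(n)
    for (j in seq_len(n)) if (p[j + 1L] > 0L) rowsol[p[j + 1L]] <- j
    rowsol
}

# assignment with birth/death alternatives: m sources, k targets,
# linkCost m x k (NA = forbidden), scalar alternative cost per miss.
# Returns integer vector length m: target index or 0 (death); plus births.
.lapLink <- function(linkCost, altCost) {
    m <- nrow(linkCost); k <- ncol(linkCost)
    n <- m + k
    BIG <- max(altCost, linkCost[is.finite(linkCost)], 0) * 1e6 + 1e6
    C <- matrix(BIG, n, n)
    feas <- is.finite(linkCost)
    C[1:m, 1:k][feas] <- linkCost[feas]
    if (m > 0) C[cbind(1:m, k + 1:m)] <- altCost   # deaths
    if (k > 0) C[cbind(m + 1:k, 1:k)] <- altCost   # births
    # lower-right: transposed feasibility at negligible cost (standard trick
    # to keep the augmented problem consistent)
    C[m + 1:k, k + 1:m][t(feas)] <- 0
    sol <- .lapSolve(C)
    assign <- integer(m)
    if (m > 0) {
        a <- sol[1:m]
        assign <- ifelse(a >= 1 & a <= k, a, 0L)
    }
    assign
}

#' Estimate the rigid shift between two channels
#'
#' Maximizes the normalized cross-correlation of the sum projections of two
#' image stacks, with sub-pixel refinement by quadratic interpolation around
#' the correlation peak. Used to register the QD channel onto the membrane
#' channel of a dual-view acquisition.
#'
#' @param stackA,stackB [RawZStack-class]/[RawMovie-class] objects, 3D
#'   arrays, or matrices (treated as their own sum projection), equal size.
#' @param maxShift maximum shift considered, px (default a quarter of the
#'   smaller image dimension).
#' @return A \code{ChannelShift} list: \code{dx, dy} in px (the shift to
#'   apply to B to land on A) and \code{peakCorrelation}.
#' @export
alignChannels <- function(stackA, stackB, maxShift = NULL) {
    proj <- function(x) {
        if (is(x, "RawZStack")) x <- x@planes
        if (is(x, "RawMovie")) x <- x@frames
        if (length(dim(x)) == 3L) apply(x, c(1, 2), sum) else x
    }
    A <- proj(stackA); B <- proj(stackB)
    stopifnot(all(dim(A) == dim(B)))
    ny <- nrow(A); nx <- ncol(A)
    if (is.null(maxShift)) maxShift <- floor(min(ny, nx) / 4)
    A0 <- A - mean(A); B0 <- B - mean(B)
    # circular cross-correlation via FFT
    cc <- Re(fft(fft(A0) * Conj(fft(B0)), inverse = TRUE)) / (ny * nx)
    shift_y <- c(0:(ny - 1)); shift_y[shift_y > ny / 2] <- shift_y[shift_y > ny / 2] - ny
    shift_x <- c(0:(nx - 1)); shift_x[shift_x > nx / 2] <- shift_x[shift_x > nx / 2] - nx
    ok <- outer(abs(shift_y) <= maxShift, abs(shift_x) <= maxShift)
    cc[!ok] <- -Inf
    pk <- arrayInd(which.max(cc), dim(cc))
    r <- pk[1]; c <- pk[2]
    if (abs(shift_y[r]) >= maxShift || abs(shift_x[c]) >= maxShift)
        stop("correlation peak at the search border; channels too misaligned")
    # quadratic (parabolic) sub-pixel interpolation around the peak
    sub <- function(m1, m0, p1) {
        den <- m1 - 2 * m0 + p1
        if (den >= 0) 0 else 0.5 * (m1 - p1) / den
    }
    wr <- function(i, n) ((i - 1) %% n) + 1
    ddy <- sub(cc[wr(r - 1, ny), c], cc[r, c], cc[wr(r + 1, ny), c])
    ddx <- sub(cc[r, wr(c - 1, nx)], cc[r, c], cc[r, wr(c + 1, nx)])
    denom <- sqrt(sum(A0^2) * sum(B0^2))
    structure(list(dx = shift_x[c] + ddx, dy = shift_y[r] + ddy,
                   peakCorrelation = cc[r, c] / denom),
              class = "ChannelShift")
}

#' @export
print.ChannelShift <- function(x, ...) {
    cat(sprintf("ChannelShift: dx = %.3f px, dy = %.3f px (peak NCC %.3f)\n",
                x$dx, x$dy, x$peakCorrelation))
    invisible(x)
}

#' Link per-frame localizations into trajectories
#'
#' Two-stage cost-matrix linking. Stage 1 solves, for each consecutive frame
#' pair, the rectangular assignment with link cost equal to squared
#' displacement (links beyond \code{maxDisp} forbidden) and birth/death
#' alternative cost \code{(1.05 * maxDisp)^2}, producing track segments.
#' Stage 2 (gap closing) joins segment ends to later segment starts across
#' gaps of at most \code{maxGap} frames with the same squared-displacement
#' cost, solved as a second exact assignment. Both stages minimize total
#' cost; the solver is exact, not greedy.
#'
#' @param fits data.frame of accepted localizations with columns
#'   \code{frame, x_um, y_um} (and optionally \code{photons}).
#' @param dt frame interval, s.
#' @param maxDisp maximum displacement per frame, um (default 0.64, i.e.
#'   5 px at 127 nm covering 2.5 um/s fastest transport at 9 frames/s with
#'   margin; scale to your frame rate).
#' @param maxGap maximum number of bridged (unobserved) frames (default 5).
#' @return list of \code{Trajectory} data.frames, each with columns
#'   \code{particle_id, frame, t, x_um, y_um, photons, gap}; bridged frames
#'   carry linearly interpolated positions and \code{gap = TRUE}. Ordered by
#'   particle id (first frame, then spatial order).
#' @export
linkTrajectories <- function(fits, dt = 1 / 9, maxDisp = 0.64, maxGap = 5L) {
    stopifnot(maxDisp > 0, maxGap >= 0)
    if (is.null(fits$photons)) fits$photons <- NA_real_
    if (nrow(fits) == 0L) return(list())
    fits <- fits[order(fits$frame, fits$y_um, fits$x_um), , drop = FALSE]
    frames <- sort(unique(fits$frame))
    idx <- split(seq_len(nrow(fits)), fits$frame)
    # stage 1: frame-to-frame segments
    segOf <- integer(nrow(fits))           # segment id per localization
    segs <- list()                         # each: vector of fit row indices
    newSeg <- function(i) { segs[[length(segs) + 1L]] <<- i; length(segs) }
    for (i in idx[[as.character(frames[1])]]) segOf[i] <- newSeg(i)
    altCost <- (1.05 * maxDisp)^2
    for (fi in seq_along(frames)[-1]) {
        prevRows <- idx[[as.character(frames[fi - 1L])]]
        curRows <- idx[[as.character(frames[fi])]]
        contiguous <- (frames[fi] - frames[fi - 1L]) == 1L
        if (length(prevRows) && length(curRows) && contiguous) {
            D2 <- outer(seq_along(prevRows), seq_along(curRows), function(a, b) {
                (fits$x_um[prevRows[a]] - fits$x_um[curRows[b]])^2 +
                (fits$y_um[prevRows[a]] - fits$y_um[curRows[b]])^2
            })
            D2[D2 > maxDisp^2] <- NA
            assign <- .lapLink(D2, altCost)
        } else assign <- integer(length(prevRows)) # all deaths
        linkedCur <- rep(FALSE, length(curRows))
        for (a in seq_along(prevRows)) {
            if (assign[a] > 0L) {
                srcSeg <- segOf[prevRows[a]]
                tgt <- curRows[assign[a]]
                segs[[srcSeg]] <- c(segs[[srcSeg]], tgt)
                segOf[tgt] <- srcSeg
                linkedCur[assign[a]] <- TRUE
            }
        }
        for (b in which(!linkedCur)) segOf[curRows[b]] <- newSeg(curRows[b])
    }
    # stage 2: gap closing (segment end -> later segment start, gap <= maxGap)
    segStart <- vapply(segs, function(s) fits$frame[s[1]], 1)
    segEnd <- vapply(segs, function(s) fits$frame[s[length(s)]], 1)
    nS <- length(segs)
    if (nS > 1L && maxGap > 0L) {
        G <- matrix(NA_real_, nS, nS)
        for (a in seq_len(nS)) for (b in seq_len(nS)) {
            if (a == b) next
            gap <- segStart[b] - segEnd[a] - 1L
            if (gap < 1L || gap > maxGap) next
            ea <- segs[[a]][length(segs[[a]])]; sb <- segs[[b]][1]
            d2 <- (fits$x_um[ea] - fits$x_um[sb])^2 +
                  (fits$y_um[ea] - fits$y_um[sb])^2
            # displacement allowance grows with the bridged interval
            if (d2 <= (maxDisp * (gap + 1L))^2) G[a, b] <- d2
        }
        if (any(is.finite(G))) {
            joinTo <- .lapLink(G, altCost)
            # merge chains: follow join pointers from chain heads
            isTail <- rep(FALSE, nS)
            for (a in seq_len(nS)) if (joinTo[a] > 0L) isTail[joinTo[a]] <- TRUE
            merged <- list()
            for (a in seq_len(nS)) {
                if (isTail[a]) next
                chain <- segs[[a]]; cur <- a
                while (joinTo[cur] > 0L) {
                    cur <- joinTo[cur]
                    chain <- c(chain, segs[[cur]])
                }
                merged[[length(merged) + 1L]] <- chain
            }
            segs <- merged
        }
    }
    # order trajectories by first frame then position (stable ids)
    firsts <- vapply(segs, function(s) fits$frame[s[1]], 1)
    ord <- order(firsts, vapply(segs, function(s) fits$y_um[s[1]], 1),
                 vapply(segs, function(s) fits$x_um[s[1]], 1))
    segs <- segs[ord]
    out <- vector("list", length(segs))
    for (j in seq_along(segs)) {
        s <- segs[[j]]
        df <- data.frame(particle_id = j, frame = fits$frame[s],
                         t = (fits$frame[s] - 1) * dt,
                         x_um = fits$x_um[s], y_um = fits$y_um[s],
                         photons = fits$photons[s], gap = FALSE)
        # bridge gaps with interpolated, gap-flagged rows
        full <- df$frame[1]:df$frame[nrow(df)]
        if (length(full) > nrow(df)) {
            miss <- setdiff(full, df$frame)
            gi <- data.frame(particle_id = j, frame = miss, t = (miss - 1) * dt,
                             x_um = approx(df$frame, df$x_um, miss)$y,
                             y_um = approx(df$frame, df$y_um, miss)$y,
                             photons = NA_real_, gap = TRUE)
            df <- rbind(df, gi)
            df <- df[order(df$frame), , drop = FALSE]
            rownames(df) <- NULL
        }
        class(df) <- c("Trajectory", "data.frame")
        out[[j]] <- df
    }
    out
}
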