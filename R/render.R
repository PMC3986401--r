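# Forward imaging model: truth positions -> expected photons -> camera ADU.

# add photons * integratedGaussian at (x_px, y_px) into expectation image E
.stampGaussian <- function(E, x_px, y_px, sigma, photons, halfwidth = NULL) {
    ny <- nrow(E); nx <- ncol(E)
    if (is.null(halfwidth)) halfwidth <- ceiling(6 * sigma)
    c0 <- max(0L, floor(x_px) - halfwidth)
    c1 <- min(nx - 1L, floor(x_px) + halfwidth)
    r0 <- max(0L, floor(y_px) - halfwidth)
    r1 <- min(ny - 1L, floor(y_px) + halfwidth)
    if (c0 > c1 || r0 > r1) return(E)
    rows <- r0:r1; cols <- c0:c1
    E[rows + 1L, cols + 1L] <- E[rows + 1L, cols + 1L] +
        photons * .integratedGaussian(rows, cols, x_px, y_px, sigma)
    E
}

# simulate a two-state Markov blinking chain over n frames
.simulateBlink <- function(blink, n) {
    state <- logical(n)
    s <- identical(blink@initialState, "on")
    for (i in seq_len(n)) {
        state[i] <- s
        s <- if (s) runif(1) >= blink@pOff else runif(1) < blink@pOn
    }
    state
}

#' Render a synthetic fluorescence movie from ground-truth trajectories
#'
#' Implements the camera forward model: each frame is
#' \code{gain * Poisson(background + sum over on emitters of photonsOn *
#' integrated 2D Gaussian) + offset}, with optional Gaussian read noise.
#' Emitters blink according to a two-state Markov model; off-state emitters
#' contribute nothing.
#'
#' @param truths a \code{TruthTrajectory} or list of them (positions in um).
#' @param camera a [CameraModel-class].
#' @param psf a [PSFModel-class].
#' @param blink a [BlinkModel-class], or \code{NULL} for always-on emitters.
#' @param nFrames number of frames; default the shortest truth length.
#' @param imageShape integer length-2 \code{c(ny, nx)} in pixels.
#' @param seed optional integer seed.
#' @param shotNoise logical; \code{FALSE} renders the noise-free expected
#'   image \code{gain * E[photons] + offset} (useful for model checks).
#' @return A list with elements \code{movie} (a [RawMovie-class]) and
#'   \code{truth}, a data.frame with one row per particle and frame:
#'   \code{particle_id, frame, t, x_um, y_um, z_um, on, phase}.
#' @examples
#' tr <- simulateTrajectory(motionPhase("stationary", 2), dt = 1/9,
#'                          origin = c(1.5, 1.5, 0))
#' sim <- renderMovie(tr, cameraModel(), psfModel(), blinkModel(),
#'                    imageShape = c(24, 24), seed = 7)
#' sim$movie
#' @export
renderMovie <- function(truths, camera, psf, blink = NULL, nFrames = NULL,
                        imageShape = c(64, 64), seed = NULL, shotNoise = TRUE) {
    if (inherits(truths, "TruthTrajectory") || is.data.frame(truths))
        truths <- list(truths)
    .setSeed(seed)
    p <- camera@pixelSize
    ny <- as.integer(imageShape[1]); nx <- as.integer(imageShape[2])
    if (is.null(nFrames)) {
        nFrames <- if (length(truths)) min(vapply(truths, nrow, 1L)) else
            stop("nFrames required when no emitters are given")
    }
    dt <- if (length(truths)) attr(truths[[1]], "dt") else 1
    if (is.null(dt)) dt <- 1
    # per-particle blink state sequences
    states <- lapply(seq_along(truths), function(i) {
        if (is.null(blink)) rep(TRUE, nFrames) else .simulateBlink(blink, nFrames)
    })
    for (tr in truths) {
        if (nrow(tr) < nFrames) stop("a truth trajectory is shorter than nFrames")
        xs <- tr$x[seq_len(nFrames)] / p; ys <- tr$y[seq_len(nFrames)] / p
        if (any(xs < 0 | xs > nx | ys < 0 | ys > ny))
            stop("emitter outside the field of view")
    }
    frames <- array(0, dim = c(ny, nx, nFrames))
    truthRows <- vector("list", length(truths))
    for (f in seq_len(nFrames)) {
        E <- matrix(psf@background, ny, nx)
        for (i in seq_along(truths)) {
            if (!states[[i]][f]) next
            tr <- truths[[i]]
            E <- .stampGaussian(E, tr$x[f] / p, tr$y[f] / p, psf@sigma,
                                psf@photonsOn)
        }
        raw <- if (shotNoise) {
            matrix(rpois(ny * nx, E), ny, nx)
        } else E
        raw <- camera@gain * raw + camera@offset
        if (camera@readNoiseSD > 0 && shotNoise)
            raw <- raw + matrix(rnorm(ny * nx, 0, camera@readNoiseSD), ny, nx)
        frames[, , f] <- raw
    }
    for (i in seq_along(truths)) {
        tr <- truths[[i]]
        pid <- attr(tr, "particle_id")
        if (is.null(pid)) pid <- i
        truthRows[[i]] <- data.frame(
            particle_id = pid, frame = seq_len(nFrames),
            t = tr$t[seq_len(nFrames)],
            x_um = tr$x[seq_len(nFrames)], y_um = tr$y[seq_len(nFrames)],
            z_um = tr$z[seq_len(nFrames)], on = states[[i]],
            phase = tr$phase[seq_len(nFrames)], stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truthRows)
    if (is.null(truth))
        truth <- data.frame(particle_id = integer(), frame = integer(),
                            t = numeric(), x_um = numeric(), y_um = numeric(),
                            z_um = numeric(), on = logical(), phase = character())
    movie <- new("RawMovie", frames = frames, camera = camera, dt = dt,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    list(movie = movie, truth = truth)
}

#' Simulate a two-channel cell z-stack with ground truth
#'
#' Builds the fixed-cell imaging experiment synthetically: quantum dots are
#' placed either well inside the cell (internal) or on the membrane contour,
#' rendered across several consecutive z-planes with a triangular axial
#' intensity falloff, while a second channel images the membrane label as a
#' bright ridge along the contour.
#'
#' @param geometry a [CellGeometry-class]; contours in um.
#' @param nQD number of quantum dots.
#' @param fracInternal fraction (0..1) of QDs placed internally;
#'   \code{round(fracInternal * nQD)} QDs are placed at least
#'   \code{internalMargin} inside the contour, the rest within 0.1 um of it.
#' @param membraneLabelPhotons ridge brightness: expected photons per pixel
#'   at the ridge crest.
#' @param camera a [CameraModel-class].
#' @param psf a [PSFModel-class] (QD channel).
#' @param seed optional integer seed.
#' @param imageShape \code{c(ny, nx)} pixels; default covers the geometry
#'   bounding box plus a 1 um margin.
#' @param internalMargin minimum distance of internal QDs from the membrane,
#'   um (default 0.5).
#' @param minSeparation minimum lateral distance between QDs, um; single-QD
#'   analysis presumes optically resolvable puncta (default 0.8).
#' @param axialPlanes odd number of planes a QD spans (default 5) with a
#'   triangular intensity profile peaking at its central plane.
#' @return list with \code{qd} and \code{membrane} ([RawZStack-class]) and
#'   \code{truth}: data.frame \code{particle_id, x_um, y_um, z_um, plane,
#'   label} (label is \code{"internal"} or \code{"membrane"}).
#' @export
simulateCellZStack <- function(geometry, nQD, fracInternal,
                               membraneLabelPhotons = 400,
                               camera = cameraModel(), psf = psfModel(),
                               seed = NULL, imageShape = NULL,
                               internalMargin = 0.5, minSeparation = 0.8,
                               axialPlanes = 5L) {
    stopifnot(fracInternal >= 0, fracInternal <= 1, nQD >= 0)
    .setSeed(seed)
    p <- camera@pixelSize
    nP <- nPlanes(geometry)
    half <- (axialPlanes - 1L) %/% 2L
    if (nP < 2L * half + 1L) stop("geometry needs at least axialPlanes planes")
    allv <- do.call(rbind, geometry@contours)
    if (is.null(imageShape)) {
        nx <- ceiling((max(allv[, 1]) + 1) / p)
        ny <- ceiling((max(allv[, 2]) + 1) / p)
        imageShape <- c(ny, nx)
    }
    ny <- imageShape[1]; nx <- imageShape[2]
    nInt <- round(fracInternal * nQD)
    nMem <- nQD - nInt
    # central planes eligible as a QD's peak plane (so >= 3 planes rendered)
    okPlanes <- (1L + half):(nP - half)
    placed <- matrix(numeric(0), 0, 2)
    placeOne <- function(sampler) {
        for (attempt in 1:5000) {
            q <- sampler()
            if (nrow(placed) == 0 ||
                min(sqrt((placed[, 1] - q[1])^2 + (placed[, 2] - q[2])^2)) >=
                    minSeparation) {
                placed <<- rbind(placed, q)
                return(q)
            }
        }
        stop("could not place QDs at the requested separation; contour too small")
    }
    truth <- NULL
    addTruth <- function(q, plane, label) {
        truth <<- rbind(truth, data.frame(
            particle_id = nrow(placed), x_um = q[1], y_um = q[2],
            z_um = (plane - 1) * geometry@zStep, plane = plane, label = label,
            stringsAsFactors = FALSE))
    }
    bb <- apply(allv, 2, range)
    for (i in seq_len(nInt)) {
        plane <- if (length(okPlanes) == 1L) okPlanes else sample(okPlanes, 1L)
        poly <- geometry@contours[[plane]]
        q <- placeOne(function() {
            for (a in 1:5000) {
                cand <- c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2]))
                if (.pointInPolygon(cand[1], cand[2], poly) &&
                    .distToPolygon(cand[1], cand[2], poly) >= internalMargin)
                    return(cand)
            }
            stop("contour too small to place interior points at the stated margin")
        })
        addTruth(q, plane, "internal")
    }
    for (i in seq_len(nMem)) {
        plane <- if (length(okPlanes) == 1L) okPlanes else sample(okPlanes, 1L)
        poly <- geometry@contours[[plane]]
        cs <- .cumArcLength(rbind(poly, poly[1, ]))
        normals <- .polygonNormals(poly)
        q <- placeOne(function() {
            s <- runif(1, 0, cs[length(cs)])
            pt <- .interpAlongPath(rbind(poly, poly[1, ]), s)
            k <- which.min((poly[, 1] - pt[1])^2 + (poly[, 2] - pt[2])^2)
            off <- runif(1, -0.1, 0.1)
            c(pt[1] + off * normals[k, 1], pt[2] + off * normals[k, 2])
        })
        addTruth(q, plane, "membrane")
    }
    # render QD channel: triangular axial profile over axialPlanes planes
    wts <- 1 - abs(seq(-half, half)) / (half + 1)
    qdPlanes <- array(0, dim = c(ny, nx, nP))
    memPlanes <- array(0, dim = c(ny, nx, nP))
    memBackground <- 5  # photons/px in the membrane channel
    for (k in seq_len(nP)) {
        E <- matrix(psf@background, ny, nx)
        if (!is.null(truth)) {
            for (j in seq_len(nrow(truth))) {
                dk <- k - truth$plane[j]
                if (abs(dk) > half) next
                E <- .stampGaussian(E, truth$x_um[j] / p, truth$y_um[j] / p,
                                    psf@sigma, psf@photonsOn * wts[dk + half + 1])
            }
        }
        qdPlanes[, , k] <- camera@gain * matrix(rpois(ny * nx, E), ny, nx) +
            camera@offset
        # membrane ridge: Gaussian line profile stamped along the contour
        Em <- matrix(memBackground, ny, nx)
        poly <- geometry@contours[[k]]
        closed <- rbind(poly, poly[1, ])
        cs <- .cumArcLength(closed)
        step <- 0.4 * p  # sample spacing along the ridge, um
        sGrid <- seq(0, cs[length(cs)], by = step)
        pts <- .interpAlongPath(closed, sGrid)
        # unit stamps at spacing d px give crest density m/(d*sqrt(2*pi)*sigma);
        # choose stamp mass m so the ridge crest is membraneLabelPhotons/px
        stampMass <- membraneLabelPhotons * 0.4 * sqrt(2 * pi) * psf@sigma
        for (j in seq_len(nrow(pts)))
            Em <- .stampGaussian(Em, pts[j, 1] / p, pts[j, 2] / p, psf@sigma,
                                 stampMass)
        memPlanes[, , k] <- camera@gain * matrix(rpois(ny * nx, Em), ny, nx) +
            camera@offset
    }
    sd <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    list(
        qd = new("RawZStack", planes = qdPlanes, camera = camera,
                 zStep = geometry@zStep, channel = "QD", seed = sd),
        membrane = new("RawZStack", planes = memPlanes, camera = camera,
                       zStep = geometry@zStep, channel = "membrane", seed = sd),
        truth = truth %||% data.frame(particle_id = integer(), x_um = numeric(),
                                      y_um = numeric(), z_um = numeric(),
                                      plane = integer(), label = character())
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
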