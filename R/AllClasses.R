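#' @import methods
NULL

#' Camera acquisition model
#'
#' Describes the EMCCD camera mapping from photoelectrons to analog-digital
#' units (ADU): \code{raw = gain * photons + offset (+ read noise)}.
#' Calibration inverts this mapping so that downstream fitting can assume
#' Poisson-distributed counts.
#'
#' @slot offset camera baseline (ADU); subtracted during calibration.
#' @slot gain ADU per photoelectron; must be positive.
#' @slot pixelSize lateral pixel size in micrometres (default 0.127).
#' @slot readNoiseSD Gaussian read noise standard deviation in ADU
#'   (default 0; the maximum-likelihood fitter assumes pure Poisson noise).
#'
#' @seealso [cameraModel()], [calibrateFrame()]
#' @export
setClass("CameraModel", representation(
    offset = "numeric", gain = "numeric",
    pixelSize = "numeric", readNoiseSD = "numeric"
))

setValidity("CameraModel", function(object) {
    msg <- NULL
    if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
        msg <- c(msg, "gain must be a positive scalar")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a positive scalar")
    if (length(object@offset) != 1L || !is.finite(object@offset) || object@offset < 0)
        msg <- c(msg, "offset must be a non-negative scalar")
    if (length(object@readNoiseSD) != 1L || !is.finite(object@readNoiseSD) ||
        object@readNoiseSD < 0)
        msg <- c(msg, "readNoiseSD must be a non-negative scalar")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CameraModel
#'
#' @param offset camera baseline in ADU.
#' @param gain ADU per photoelectron.
#' @param pixelSize pixel size in micrometres.
#' @param readNoiseSD Gaussian read noise SD in ADU.
#' @return A [CameraModel-class] object.
#' @examples
#' cam <- cameraModel(offset = 100, gain = 5)
#' @export
cameraModel <- function(offset = 100, gain = 5, pixelSize = 0.127,
                        readNoiseSD = 0) {
    new("CameraModel", offset = offset, gain = gain, pixelSize = pixelSize,
        readNoiseSD = readNoiseSD)
}

#' Gaussian point-spread-function model of a single emitter
#'
#' @slot sigma PSF standard deviation in pixels.
#' @slot photonsOn expected signal photons per frame while the emitter is on.
#' @slot background expected background photons per pixel per frame.
#' @export
setClass("PSFModel", representation(
    sigma = "numeric", photonsOn = "numeric", background = "numeric"
))

setValidity("PSFModel", function(object) {
    msg <- NULL
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@photonsOn <= 0) msg <- c(msg, "photonsOn must be > 0")
    if (object@background < 0) msg <- c(msg, "background must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PSFModel
#'
#' Defaults (sigma 1.2 px ~ 152 nm, 800 signal photons, 10 background
#' photons/px) describe a bright single quantum dot imaged near the
#' diffraction limit on a 127 nm pixel grid.
#'
#' @param sigma PSF standard deviation, pixels.
#' @param photonsOn expected signal photons per frame in the on state.
#' @param background expected background photons per pixel per frame.
#' @return A [PSFModel-class] object.
#' @export
psfModel <- function(sigma = 1.2, photonsOn = 800, background = 10) {
    new("PSFModel", sigma = sigma, photonsOn = photonsOn, background = background)
}

#' Two-state Markov blinking model
#'
#' Quantum dots switch stochastically between a fluorescent on state and a
#' dark off state; the signature square-pulse intensity trace of a single QD
#' is modelled as a discrete-time two-state Markov chain over frames.
#'
#' @slot pOff per-frame transition probability on -> off.
#' @slot pOn per-frame transition probability off -> on.
#' @slot initialState \code{"on"} or \code{"off"}.
#' @export
setClass("BlinkModel", representation(
    pOff = "numeric", pOn = "numeric", initialState = "character"
))

setValidity("BlinkModel", function(object) {
    msg <- NULL
    if (object@pOff < 0 || object@pOff > 1) msg <- c(msg, "pOff must be in [0,1]")
    if (object@pOn < 0 || object@pOn > 1) msg <- c(msg, "pOn must be in [0,1]")
    if (!object@initialState %in% c("on", "off"))
        msg <- c(msg, "initialState must be 'on' or 'off'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BlinkModel
#'
#' @param pOff per-frame on -> off probability.
#' @param pOn per-frame off -> on probability.
#' @param initialState starting state, \code{"on"} or \code{"off"}.
#' @return A [BlinkModel-class] object. The stationary on-fraction is
#'   \code{pOn / (pOn + pOff)}.
#' @export
blinkModel <- function(pOff = 0.1, pOn = 0.5, initialState = "on") {
    new("BlinkModel", pOff = pOff, pOn = pOn, initialState = initialState)
}

#' Per-plane cell membrane geometry
#'
#' Stores one closed membrane contour per z-plane (ordered vertices in
#' micrometres) with the axial step between planes.
#'
#' @slot contours list of n x 2 matrices (columns x, y in micrometres), one
#'   per z-plane, each a simple closed polygon (last vertex implicitly joined
#'   to the first).
#' @slot zStep axial step between planes in micrometres (default 0.300).
#' @export
setClass("CellGeometry", representation(contours = "list", zStep = "numeric"))

setValidity("CellGeometry", function(object) {
    msg <- NULL
    if (length(object@contours) < 1L) msg <- c(msg, "need at least one plane")
    if (object@zStep <= 0) msg <- c(msg, "zStep must be > 0")
    for (ct in object@contours) {
        if (!is.matrix(ct) || ncol(ct) != 2L || nrow(ct) < 3L) {
            msg <- c(msg, "each contour must be an n x 2 matrix with n >= 3")
            break
        }
        if (.polygonSelfIntersects(ct)) {
            msg <- c(msg, "contour must be simple (non-self-intersecting)")
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a circular-cylinder cell geometry
#'
#' Convenience constructor for a cell whose cross-section is the same circle
#' in every plane, a reasonable stand-in for the mid-height planes of a
#' roughly spherical soma.
#'
#' @param radius cell radius in micrometres.
#' @param center numeric length-2, circle center (x, y) in micrometres.
#' @param nPlanes number of z-planes.
#' @param zStep axial step, micrometres.
#' @param nVertices number of polygon vertices approximating the circle.
#' @return A [CellGeometry-class] object.
#' @export
cellGeometry <- function(radius = 8, center = c(10, 10), nPlanes = 11,
                         zStep = 0.3, nVertices = 180) {
    th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
    circ <- cbind(x = center[1] + radius * cos(th),
                  y = center[2] + radius * sin(th))
    new("CellGeometry", contours = rep(list(circ), nPlanes), zStep = zStep)
}

#' Raw fluorescence movie in camera units
#'
#' A time series of 2D frames straight off the (possibly simulated) camera,
#' in ADU, together with the acquisition metadata needed to calibrate and
#' analyse it.
#'
#' @slot frames numeric array \code{[ny, nx, nFrames]} in ADU. Pixel
#'   \code{[r, c]} (1-based array index) is 0-based pixel (r-1, c-1), whose
#'   center is at \code{((c-0.5) * pixelSize, (r-0.5) * pixelSize)} um.
#' @slot camera the [CameraModel-class] used for acquisition.
#' @slot dt frame interval in seconds.
#' @slot seed integer seed recorded at simulation time (NA for real data).
#' @export
setClass("RawMovie", representation(
    frames = "array", camera = "CameraModel", dt = "numeric", seed = "integer"
))

setValidity("RawMovie", function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3L)
        msg <- c(msg, "frames must be a 3D array [ny, nx, nFrames]")
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Raw fluorescence z-stack in camera units
#'
#' @slot planes numeric array \code{[ny, nx, nPlanes]} in ADU, planes ordered
#'   by increasing z; plane k (1-based) is at z = (k - 1) * zStep um.
#' @slot camera the [CameraModel-class] used for acquisition.
#' @slot zStep axial step in micrometres.
#' @slot channel free-text channel label (e.g. "QD", "membrane").
#' @slot seed integer seed recorded at simulation time (NA for real data).
#' @export
setClass("RawZStack", representation(
    planes = "array", camera = "CameraModel", zStep = "numeric",
    channel = "character", seed = "integer"
))

setValidity("RawZStack", function(object) {
    msg <- NULL
    if (length(dim(object@planes)) != 3L)
        msg <- c(msg, "planes must be a 3D array [ny, nx, nPlanes]")
    if (object@zStep <= 0) msg <- c(msg, "zStep must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Super-resolved membrane map
#'
#' Result of membrane segmentation: per z-plane, a closed sub-pixel contour
#' (ordered vertices, micrometres) plus the phase-congruency edge-strength
#' map it was derived from. Planes in which no closed contour was found hold
#' \code{NULL}.
#'
#' @slot contours list (one per plane) of n x 2 matrices in micrometres, or
#'   NULL for empty planes.
#' @slot pcMaps list of per-plane phase-congruency maps (matrices in [0,1]).
#' @slot pixelSize pixel size in micrometres.
#' @slot zStep axial step in micrometres.
#' @slot method \code{"phase_congruency"} or \code{"gradient_ridge"}
#'   (fallback), recorded so downstream output can flag it.
#' @export
setClass("MembraneMap", representation(
    contours = "list", pcMaps = "list", pixelSize = "numeric",
    zStep = "numeric", method = "character"
))

# ---- basic accessors ----

#' @describeIn RawMovie-class number of frames
#' @param x object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "RawMovie", function(x) dim(x@frames)[3])

#' Number of z planes
#' @param x a RawZStack, CellGeometry or MembraneMap
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @export
setMethod("nPlanes", "RawZStack", function(x) dim(x@planes)[3])
#' @export
setMethod("nPlanes", "CellGeometry", function(x) length(x@contours))
#' @export
setMethod("nPlanes", "MembraneMap", function(x) length(x@contours))

#' Pixel size in micrometres
#' @param x an object carrying acquisition geometry
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "CameraModel", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "RawMovie", function(x) x@camera@pixelSize)
#' @export
setMethod("pixelSize", "RawZStack", function(x) x@camera@pixelSize)
#' @export
setMethod("pixelSize", "MembraneMap", function(x) x@pixelSize)

#' Frame interval in seconds
#' @param x a RawMovie
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @export
setMethod("frameInterval", "RawMovie", function(x) x@dt)

#' Camera model of an acquisition
#' @param x a RawMovie or RawZStack
#' @export
setGeneric("camera", function(x) standardGeneric("camera"))
#' @export
setMethod("camera", "RawMovie", function(x) x@camera)
#' @export
setMethod("camera", "RawZStack", function(x) x@camera)

#' Extract one frame or plane as a matrix
#' @param x a RawMovie or RawZStack
#' @param i frame/plane index (1-based)
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @export
setMethod("getFrame", "RawMovie", function(x, i) x@frames[, , i])
#' @export
setMethod("getFrame", "RawZStack", function(x, i) x@planes[, , i])

#' Membrane contour for one plane
#' @param x a MembraneMap or CellGeometry
#' @param i plane index (1-based)
#' @return n x 2 matrix of vertices in micrometres, or NULL if the plane is
#'   empty.
#' @export
setGeneric("membraneContour", function(x, i) standardGeneric("membraneContour"))
#' @export
setMethod("membraneContour", "MembraneMap", function(x, i) x@contours[[i]])
#' @export
setMethod("membraneContour", "CellGeometry", function(x, i) x@contours[[i]])

# ---- show methods ----

setMethod("show", "CameraModel", function(object) {
    cat(sprintf("CameraModel: offset %g ADU, gain %g ADU/e-, pixel %g um, read noise %g ADU\n",
                object@offset, object@gain, object@pixelSize, object@readNoiseSD))
})

setMethod("show", "PSFModel", function(object) {
    cat(sprintf("PSFModel: sigma %g px, %g photons/frame on, %g bg photons/px\n",
                object@sigma, object@photonsOn, object@background))
})

setMethod("show", "BlinkModel", function(object) {
    cat(sprintf("BlinkModel: pOff %g, pOn %g, start %s (stationary on-fraction %.3f)\n",
                object@pOff, object@pOn, object@initialState,
                object@pOn / (object@pOn + object@pOff)))
})

setMethod("show", "CellGeometry", function(object) {
    cat(sprintf("CellGeometry: %d planes, z-step %g um\n",
                length(object@contours), object@zStep))
})

setMethod("show", "RawMovie", function(object) {
    d <- dim(object@frames)
    cat(sprintf("RawMovie: %d x %d px, %d frames at %.3g s/frame (%.3g um/px)\n",
                d[1], d[2], d[3], object@dt, pixelSize(object)))
})

setMethod("show", "RawZStack", function(object) {
    d <- dim(object@planes)
    cat(sprintf("RawZStack [%s]: %d x %d px, %d planes, z-step %g um\n",
                object@channel, d[1], d[2], d[3], object@zStep))
})

setMethod("show", "MembraneMap", function(object) {
    nOK <- sum(!vapply(object@contours, is.null, logical(1)))
    cat(sprintf("MembraneMap (%s): %d/%d planes with closed contours, z-step %g um\n",
                object@method, nOK, length(object@contours), object@zStep))
})
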