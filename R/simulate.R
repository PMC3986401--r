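#' Describe one motion phase of a simulated particle
#'
#' A trajectory is simulated as an ordered sequence of motion phases, the
#' regimes observed for intracellular cargo: free (Brownian) diffusion,
#' directed motor transport along a path, confined diffusion inside a corral,
#' and immobility.
#'
#' @param kind one of \code{"brownian"}, \code{"directed"}, \code{"confined"},
#'   \code{"stationary"}.
#' @param duration phase duration in seconds.
#' @param D diffusion coefficient, um^2/s (brownian; micro-diffusion inside a
#'   confined corral).
#' @param v speed along the path, um/s (directed).
#' @param L side of the square confinement corral, um (confined).
#' @param path optional n x 2 matrix of path control points in um (directed);
#'   when absent the particle moves along a straight line from its entry
#'   point in the +x direction.
#' @return A \code{MotionPhase} object (list).
#' @examples
#' motionPhase("directed", duration = 10, v = 1.5)
#' @export
motionPhase <- function(kind = c("brownian", "directed", "confined", "stationary"),
                        duration, D = 0, v = 0, L = NA_real_, path = NULL) {
    kind <- match.arg(kind)
    if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
    if (D < 0) stop("D must be >= 0")
    if (v < 0) stop("v must be >= 0")
    if (kind == "confined" && (!is.finite(L) || L <= 0))
        stop("confined phase requires corral side L > 0")
    if (!is.null(path) && (!is.matrix(path) || ncol(path) != 2L))
        stop("path must be an n x 2 matrix")
    structure(list(kind = kind, duration = duration, D = D, v = v, L = L,
                   path = path), class = "MotionPhase")
}

#' @export
print.MotionPhase <- function(x, ...) {
    extra <- switch(x$kind,
        brownian = sprintf("D = %g um^2/s", x$D),
        directed = sprintf("v = %g um/s%s", x$v,
                           if (is.null(x$path)) " (straight line)" else " (custom path)"),
        confined = sprintf("D = %g um^2/s, corral L = %g um", x$D, x$L),
        stationary = "")
    cat(sprintf("MotionPhase %s, %g s %s\n", x$kind, x$duration, extra))
    invisible(x)
}

# reflect a coordinate into [lo, hi] (folding; handles multiple reflections)
.reflectInto <- function(x, lo, hi) {
    w <- hi - lo
    y <- (x - lo) %% (2 * w)
    lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate a ground-truth particle trajectory
#'
#' Generates the per-frame true positions of one particle following an
#' ordered list of motion phases. Each phase contributes
#' \code{round(duration / dt)} steps; the trajectory starts at \code{origin}
#' at t = 0, so a single phase of duration T yields \code{round(T/dt) + 1}
#' positions. Motion is lateral (x, y); z is held at the origin value,
#' matching acquisition at a fixed focal plane.
#'
#' Phase models: \emph{brownian} draws independent Gaussian steps per axis
#' with variance \code{2 * D * dt}; \emph{directed} advances \code{v * dt} in
#' arc length along the phase path (straight +x line from the entry point if
#' no path is given); \emph{confined} draws Brownian proposals reflected at a
#' square corral of side L centred at the phase entry point;
#' \emph{stationary} holds the position constant.
#'
#' @param phases list of [motionPhase()] objects (a single phase may be
#'   passed bare).
#' @param dt frame interval, seconds.
#' @param origin numeric length-3, start position (x, y, z) in um.
#' @param particleId identifier stored with the trajectory.
#' @param seed optional integer seed.
#' @return A \code{TruthTrajectory}: a data.frame with columns \code{frame}
#'   (1-based), \code{t} (s), \code{x}, \code{y}, \code{z} (um) and
#'   \code{phase} (the phase kind at each frame), plus attributes
#'   \code{particle_id} and \code{dt}.
#' @examples
#' tr <- simulateTrajectory(motionPhase("brownian", 10, D = 0.29), dt = 1/9,
#'                          seed = 1)
#' head(tr)
#' @export
simulateTrajectory <- function(phases, dt, origin = c(0, 0, 0),
                               particleId = 1L, seed = NULL) {
    if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
    if (inherits(phases, "MotionPhase")) phases <- list(phases)
    if (length(phases) == 0L) stop("phases must be nonempty")
    for (ph in phases) if (!inherits(ph, "MotionPhase"))
        stop("phases must be MotionPhase objects")
    .setSeed(seed)
    pos <- matrix(origin[1:2], nrow = 1)
    labels <- phases[[1]]$kind
    for (ph in phases) {
        n <- max(1L, round(ph$duration / dt))
        cur <- pos[nrow(pos), ]
        block <- switch(ph$kind,
            stationary = matrix(rep(cur, each = n), ncol = 2),
            brownian = {
                sd <- sqrt(2 * ph$D * dt)
                steps <- matrix(rnorm(2 * n, 0, sd), ncol = 2)
                cbind(cur[1] + cumsum(steps[, 1]), cur[2] + cumsum(steps[, 2]))
            },
            directed = {
                path <- ph$path
                if (is.null(path))
                    path <- rbind(cur, cur + c(ph$v * ph$duration + 1, 0))
                s0 <- 0
                # enter the path at its start; positions advance v*dt per frame
                s <- s0 + ph$v * dt * seq_len(n)
                p <- .interpAlongPath(path, s)
                # translate so the path start coincides with the entry point
                p0 <- .interpAlongPath(path, 0)
                cbind(p[, 1] - p0[1] + cur[1], p[, 2] - p0[2] + cur[2])
            },
            confined = {
                sd <- sqrt(2 * ph$D * dt)
                half <- ph$L / 2
                out <- matrix(0, n, 2)
                p <- cur
                for (i in seq_len(n)) {
                    p <- p + rnorm(2, 0, sd)
                    p[1] <- .reflectInto(p[1], cur[1] - half, cur[1] + half)
                    p[2] <- .reflectInto(p[2], cur[2] - half, cur[2] + half)
                    out[i, ] <- p
                }
                # corral centred at entry point: reflections use entry as center
                out
            },
            stop("unknown phase kind: ", ph$kind))
        pos <- rbind(pos, block)
        labels <- c(labels, rep(ph$kind, n))
    }
    nTot <- nrow(pos)
    out <- data.frame(frame = seq_len(nTot), t = (seq_len(nTot) - 1) * dt,
                      x = pos[, 1], y = pos[, 2], z = origin[3],
                      phase = labels, stringsAsFactors = FALSE)
    attr(out, "particle_id") <- particleId
    attr(out, "dt") <- dt
    class(out) <- c("TruthTrajectory", "data.frame")
    out
}
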