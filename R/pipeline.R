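# End-to-end orchestration: configuration, staged execution
# (simulate -> detect -> track -> analyze -> evaluate) and ground-truth
# evaluation.

.defaultConfig <- function() list(
    seed = 1L,
    out_dir = ".",
    mode = "movie",   # "movie": fixed-z live imaging; "zstack": fixed cell
    stages = c("simulate", "detect", "track", "analyze", "evaluate"),
    camera = list(offset = 100, gain = 5, pixel_size_um = 0.127,
                  read_noise_sd = 0),
    psf = list(sigma_px = 1.2, photons_on = 800, background = 10),
    blink = list(p_off = 0.1, p_on = 0.5),
    movie = list(
        dt_s = 1 / 9, image_px = 96,
        # default scene: two well-separated particles, one diffusing at the
        # membrane rate within a corral (so it stays in the field), one
        # mixing stop-and-go transport with immobility
        particles = list(
            list(origin_um = c(3.5, 8.5), phases = list(
                list(kind = "confined", duration_s = 30, D = 0.29, L = 2.5))),
            list(origin_um = c(2.5, 3.5), phases = list(
                list(kind = "directed", duration_s = 10, v = 0.25),
                list(kind = "stationary", duration_s = 10),
                list(kind = "directed", duration_s = 10, v = 0.25))))),
    zstack = list(radius_um = 7, center_um = c(9, 9), n_planes = 9,
                  z_step_um = 0.3, n_qd = 50, frac_internal = 0.9,
                  membrane_label_photons = 400),
    detection = list(psf_sigma_px = 1.2, roi_px = 7, dog_small_px = 1.0,
                     dog_large_px = 2.0, intensity_min = 100,
                     llr_pvalue_max = 1e-3),
    tracking = list(max_disp_um = 0.64, max_gap = 5),
    dynamics = list(msd_fit_lags = 10, speed_window_s = 2,
                    phase_window_s = 2, phase_step_s = 0.5,
                    v_min_um_s = 0.2, min_traj_frames = 20),
    classify = list(d_mem_um = 0.25, min_planes = 3)
)

# recursive merge: values in `over` override `base`
.mergeConfig <- function(base, over) {
    for (nm in names(over)) {
        if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
            !is.null(names(over[[nm]])))
            base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
        else base[[nm]] <- over[[nm]]
    }
    base
}

#' Build a pipeline run configuration
#'
#' Starts from the package defaults (which encode the reference acquisition:
#' 127 nm pixels, 9 frames/s movies, 300 nm z-steps, 800-photon QDs over 10
#' background photons/px) and overlays first a YAML file, then named
#' arguments.
#'
#' @param file optional YAML configuration file.
#' @param ... named overrides (nested lists merge recursively).
#' @return A \code{RunConfig} list.
#' @examples
#' cfg <- runConfig(seed = 7, movie = list(image_px = 48))
#' @export
runConfig <- function(file = NULL, ...) {
    cfg <- .defaultConfig()
    if (!is.null(file)) cfg <- .mergeConfig(cfg, yaml::read_yaml(file))
    dots <- list(...)
    if (length(dots)) cfg <- .mergeConfig(cfg, dots)
    if (!cfg$mode %in% c("movie", "zstack")) stop("mode must be movie or zstack")
    bad <- setdiff(cfg$stages,
                   c("simulate", "detect", "track", "analyze", "evaluate"))
    if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
    cfg$seed <- as.integer(cfg$seed)
    structure(cfg, class = c("RunConfig", "list"))
}

.cameraFromConfig <- function(cfg) cameraModel(
    offset = cfg$camera$offset, gain = cfg$camera$gain,
    pixelSize = cfg$camera$pixel_size_um,
    readNoiseSD = cfg$camera$read_noise_sd)

.psfFromConfig <- function(cfg) psfModel(
    sigma = cfg$psf$sigma_px, photonsOn = cfg$psf$photons_on,
    background = cfg$psf$background)

.phasesFromConfig <- function(plist) lapply(plist, function(ph) motionPhase(
    kind = ph$kind, duration = ph$duration_s, D = ph$D %||% 0,
    v = ph$v %||% 0, L = ph$L %||% NA_real_,
    path = if (is.null(ph$path_um)) NULL else
        matrix(unlist(ph$path_um), ncol = 2, byrow = TRUE)))

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes standard outputs
#' (localizations, trajectories, MSD fits, phases, intensity traces, and an
#' evaluation report when ground truth is available) under
#' \code{config$out_dir}. Identical config and seed give identical outputs.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @return invisibly, a list with the in-memory results of each stage
#'   (\code{movie/stacks, truth, localizations, trajectories, dynamics,
#'   evaluation}).
#' @export
runPipeline <- function(config) {
    cfg <- if (inherits(config, "RunConfig")) config else runConfig(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    cfgHashable <- unclass(cfg)
    cfgHashable$out_dir <- NULL  # the hash identifies the analysis, not where it lands
    info <- list(seed = cfg$seed, config_sha = .configHash(cfgHashable))
    jsonlite::write_json(c(info, list(mode = cfg$mode, stages = cfg$stages)),
                         file.path(cfg$out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
    stage <- function(name) name %in% cfg$stages
    res <- list(config = cfg)
    runStage <- function(name, fn) {
        tryCatch(fn(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
    }
    if (cfg$mode == "movie") {
        if (stage("simulate")) runStage("simulate", function() {
            cam <- .cameraFromConfig(cfg); psf <- .psfFromConfig(cfg)
            blink <- blinkModel(cfg$blink$p_off, cfg$blink$p_on)
            truths <- lapply(seq_along(cfg$movie$particles), function(i) {
                pp <- cfg$movie$particles[[i]]
                simulateTrajectory(.phasesFromConfig(pp$phases),
                                   dt = cfg$movie$dt_s,
                                   origin = c(unlist(pp$origin_um), 0),
                                   particleId = i,
                                   seed = .childSeed(cfg$seed, i))
            })
            sim <- renderMovie(truths, cam, psf, blink,
                               imageShape = rep(cfg$movie$image_px, 2),
                               seed = .childSeed(cfg$seed, 1000L))
            writeAcquisition(sim$movie, file.path(cfg$out_dir, "movie.tif"))
            .writeTable(sim$truth, file.path(cfg$out_dir, "truth.csv"), info)
            res$movie <<- sim$movie; res$truth <<- sim$truth
        })
        if (stage("detect")) runStage("detect", function() {
            if (is.null(res$movie)) res$movie <<- readAcquisition(
                file.path(cfg$out_dir, "movie.tif"))
            d <- cfg$detection
            loc <- detectSpots(res$movie, psfSigma = d$psf_sigma_px,
                               roiSize = d$roi_px, sigmaSmall = d$dog_small_px,
                               sigmaLarge = d$dog_large_px,
                               intensityMin = d$intensity_min,
                               llrPvalueMax = d$llr_pvalue_max)
            .writeTable(loc[, c("frame", "x_um", "y_um", "photons", "bg",
                                "crlb_um", "accepted")],
                        file.path(cfg$out_dir, "localizations.csv"), info)
            res$localizations <<- loc
        })
        if (stage("track")) runStage("track", function() {
            trs <- linkTrajectories(res$localizations, dt = cfg$movie$dt_s,
                                    maxDisp = cfg$tracking$max_disp_um,
                                    maxGap = cfg$tracking$max_gap)
            flat <- do.call(rbind, lapply(trs, as.data.frame))
            .writeTable(flat[, c("particle_id", "frame", "t", "x_um", "y_um",
                                 "gap")],
                        file.path(cfg$out_dir, "trajectories.csv"), info)
            res$trajectories <<- trs
        })
        if (stage("analyze")) runStage("analyze", function() {
            dyn <- cfg$dynamics
            msdFits <- list(); phasesAll <- NULL; speedsAll <- NULL
            blinkAll <- list()
            for (tr in res$trajectories) {
                pid <- tr$particle_id[1]
                if (sum(!tr$gap) < dyn$min_traj_frames) next
                mf <- tryCatch(fitMSD(computeMSD(tr), dyn$msd_fit_lags),
                               error = function(e) NULL)
                if (!is.null(mf))
                    msdFits[[as.character(pid)]] <- c(
                        list(particle_id = pid), mf$fit[c("model", "D", "L",
                                                          "offset", "flagged")])
                sp <- tryCatch(fitSmoothPath(tr), error = function(e) NULL)
                if (!is.null(sp)) {
                    pos <- pathPosition(tr, sp)
                    spd <- tryCatch(estimateSpeeds(pos, dyn$speed_window_s),
                                    error = function(e) NULL)
                    if (!is.null(spd)) {
                        spd$particle_id <- pid
                        speedsAll <- rbind(speedsAll, spd)
                    }
                }
                ph <- tryCatch(segmentPhases(tr, dyn$phase_window_s,
                                             dyn$phase_step_s, dyn$v_min_um_s),
                               error = function(e) NULL)
                if (!is.null(ph)) {
                    ph$particle_id <- pid
                    phasesAll <- rbind(phasesAll, ph)
                }
                if (!is.null(res$movie)) {
                    cls <- tryCatch(
                        classifySingleQD(intensityTrace(res$movie, tr)),
                        error = function(e) NULL)
                    if (!is.null(cls))
                        blinkAll[[as.character(pid)]] <- list(
                            particle_id = pid,
                            classification = cls$classification,
                            n_levels = cls$nLevels,
                            n_off_excursions = cls$nOffExcursions)
                }
            }
            jsonlite::write_json(unname(msdFits),
                                 file.path(cfg$out_dir, "msd_fits.json"),
                                 auto_unbox = TRUE, digits = NA)
            jsonlite::write_json(unname(blinkAll),
                                 file.path(cfg$out_dir, "blinking.json"),
                                 auto_unbox = TRUE, digits = NA)
            if (!is.null(phasesAll))
                .writeTable(phasesAll[, c("particle_id", "start", "end",
                                          "kind", "v")],
                            file.path(cfg$out_dir, "phases.csv"), info)
            if (!is.null(speedsAll))
                .writeTable(speedsAll[, c("particle_id", "tMid", "speed", "n")],
                            file.path(cfg$out_dir, "speeds.csv"), info)
            res$dynamics <<- list(msdFits = msdFits, phases = phasesAll,
                                  speeds = speedsAll, blinking = blinkAll)
        })
        if (stage("evaluate") && !is.null(res$truth))
            runStage("evaluate", function() {
                ev <- evaluateAgainstTruth(res, res$truth,
                                           pixelSize = cfg$camera$pixel_size_um)
                jsonlite::write_json(ev, file.path(cfg$out_dir, "evaluation.json"),
                                     auto_unbox = TRUE, digits = NA)
                res$evaluation <<- ev
            })
    } else {
        if (stage("simulate")) runStage("simulate", function() {
            z <- cfg$zstack
            geom <- cellGeometry(radius = z$radius_um,
                                 center = unlist(z$center_um),
                                 nPlanes = z$n_planes, zStep = z$z_step_um)
            sim <- simulateCellZStack(geom, nQD = z$n_qd,
                                      fracInternal = z$frac_internal,
                                      membraneLabelPhotons = z$membrane_label_photons,
                                      camera = .cameraFromConfig(cfg),
                                      psf = .psfFromConfig(cfg),
                                      seed = cfg$seed)
            writeAcquisition(sim$qd, file.path(cfg$out_dir, "qd_stack.tif"))
            writeAcquisition(sim$membrane,
                             file.path(cfg$out_dir, "membrane_stack.tif"))
            .writeTable(sim$truth, file.path(cfg$out_dir, "truth.csv"), info)
            res$stacks <<- sim[c("qd", "membrane")]; res$truth <<- sim$truth
        })
        if (stage("analyze")) runStage("analyze", function() {
            if (is.null(res$stacks)) res$stacks <<- list(
                qd = readAcquisition(file.path(cfg$out_dir, "qd_stack.tif")),
                membrane = readAcquisition(
                    file.path(cfg$out_dir, "membrane_stack.tif")))
            ca <- analyzeCellStack(res$stacks$qd, res$stacks$membrane,
                                   dMem = cfg$classify$d_mem_um,
                                   minPlanes = cfg$classify$min_planes)
            .writeTable(ca$qds, file.path(cfg$out_dir, "qd_locations.csv"), info)
            jsonlite::write_json(ca$internalization,
                                 file.path(cfg$out_dir, "internalization.json"),
                                 auto_unbox = TRUE, digits = NA)
            res$cell <<- ca
        })
        if (stage("evaluate") && !is.null(res$truth))
            runStage("evaluate", function() {
                ev <- evaluateAgainstTruth(res, res$truth,
                                           pixelSize = cfg$camera$pixel_size_um)
                jsonlite::write_json(ev, file.path(cfg$out_dir, "evaluation.json"),
                                     auto_unbox = TRUE, digits = NA)
                res$evaluation <<- ev
            })
    }
    invisible(res)
}

# greedy nearest matching of detections to truth within a radius;
# each truth position is used at most once
.matchPoints <- function(dx, dy, tx, ty, radius) {
    nd <- length(dx); nt <- length(tx)
    match <- rep(NA_integer_, nd)
    if (nd == 0L || nt == 0L) return(match)
    D <- outer(dx, tx, "-")^2 + outer(dy, ty, "-")^2
    D[D > radius^2] <- NA
    repeat {
        if (all(is.na(D))) break
        ij <- arrayInd(which.min(D), dim(D))
        match[ij[1]] <- ij[2]
        D[ij[1], ] <- NA
        D[, ij[2]] <- NA
    }
    match
}

#' Evaluate pipeline results against simulator ground truth
#'
#' Matches detections to true emitter positions (greedy nearest within
#' \code{matchPx} pixels, each truth used once), then reports detection
#' precision and recall, localization RMSE over matches, trajectory purity
#' (majority-truth-particle fraction per trajectory), and, for z-stack
#' runs, the membrane/internal confusion matrix.
#'
#' @param results list from [runPipeline()] (or a list with elements
#'   \code{localizations} and/or \code{trajectories} / \code{cell}).
#' @param truth truth table (movie: per frame and particle with
#'   \code{frame, x_um, y_um, on}; z-stack: per QD with \code{x_um, y_um,
#'   label}).
#' @param pixelSize pixel size in um.
#' @param matchPx matching radius in pixels (default 2).
#' @return An \code{EvaluationReport} list.
#' @export
evaluateAgainstTruth <- function(results, truth, pixelSize = 0.127,
                                 matchPx = 2) {
    if (nrow(truth) == 0L) stop("empty truth table")
    radius <- matchPx * pixelSize
    rep_ <- list()
    loc <- results$localizations
    if (!is.null(loc) && !is.null(truth$frame)) {
        tp <- 0L; fp <- 0L; fn <- 0L; sqerr <- c()
        purityNum <- 0L
        locTruthId <- rep(NA_integer_, nrow(loc))
        for (f in sort(unique(c(loc$frame, truth$frame)))) {
            li <- which(loc$frame == f & (is.null(loc$accepted) | loc$accepted))
            ti <- which(truth$frame == f & (is.null(truth$on) | truth$on))
            m <- .matchPoints(loc$x_um[li], loc$y_um[li],
                              truth$x_um[ti], truth$y_um[ti], radius)
            tp <- tp + sum(!is.na(m))
            fp <- fp + sum(is.na(m))
            fn <- fn + length(ti) - sum(!is.na(m))
            ok <- !is.na(m)
            locTruthId[li[ok]] <- truth$particle_id[ti[m[ok]]]
            sqerr <- c(sqerr, (loc$x_um[li[ok]] - truth$x_um[ti[m[ok]]])^2 +
                              (loc$y_um[li[ok]] - truth$y_um[ti[m[ok]]])^2)
        }
        rep_$detection <- list(
            precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
            recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
            n_true_positive = tp, n_false_positive = fp, n_false_negative = fn)
        rep_$localization_rmse_um <- if (length(sqerr)) sqrt(mean(sqerr) / 2)
                                     else NA_real_
        if (!is.null(results$trajectories)) {
            purities <- vapply(results$trajectories, function(tr) {
                obs <- tr[!tr$gap, , drop = FALSE]
                ids <- locTruthId[match(
                    paste(obs$frame, round(obs$x_um, 9), round(obs$y_um, 9)),
                    paste(loc$frame, round(loc$x_um, 9), round(loc$y_um, 9)))]
                ids <- ids[!is.na(ids)]
                if (!length(ids)) return(NA_real_)
                max(table(ids)) / length(ids)
            }, numeric(1))
            w <- vapply(results$trajectories, function(tr) sum(!tr$gap), 1)
            ok <- !is.na(purities)
            rep_$trajectory_purity <- sum(purities[ok] * w[ok]) / sum(w[ok])
        }
    }
    if (!is.null(results$cell)) {
        qds <- results$cell$qds
        m <- .matchPoints(qds$x_um, qds$y_um, truth$x_um, truth$y_um, radius)
        conf <- table(factor(truth$label[m[!is.na(m)]],
                             levels = c("membrane", "internal")),
                      factor(qds$label[!is.na(m)],
                             levels = c("membrane", "internal", "external",
                                        "unresolved")))
        rep_$classification <- list(
            confusion = as.data.frame(conf, responseName = "n"),
            accuracy = sum(truth$label[m[!is.na(m)]] ==
                           qds$label[!is.na(m)]) / sum(!is.na(m)),
            n_matched = sum(!is.na(m)), n_unmatched_truth = nrow(truth) -
                length(unique(m[!is.na(m)])))
        rep_$internalization <- results$cell$internalization
    }
    class(rep_) <- c("EvaluationReport", "list")
    rep_
}

#' @export
print.EvaluationReport <- function(x, ...) {
    cat("EvaluationReport\n")
    if (!is.null(x$detection))
        cat(sprintf("  detection: precision %.3f, recall %.3f\n",
                    x$detection$precision, x$detection$recall))
    if (!is.null(x$localization_rmse_um))
        cat(sprintf("  localization RMSE: %.1f nm\n",
                    1000 * x$localization_rmse_um))
    if (!is.null(x$trajectory_purity))
        cat(sprintf("  trajectory purity: %.3f\n", x$trajectory_purity))
    if (!is.null(x$classification))
        cat(sprintf("  classification accuracy: %.3f\n",
                    x$classification$accuracy))
    invisible(x)
}
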