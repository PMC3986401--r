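# Standard I/O: multi-page 16-bit TIFF with a JSON metadata sidecar for
# acquisitions, CSV for tables (with a JSON run-info sidecar carrying the
# config hash and seed).

#' Write an acquisition as multi-page TIFF plus JSON sidecar
#'
#' Pixel data are stored as 16-bit grayscale TIFF pages; acquisition
#' metadata (pixel size, frame interval or z-step, camera offset/gain,
#' channel, seed) go to \code{<path>.json}.
#'
#' @param x a [RawMovie-class] or [RawZStack-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeAcquisition <- function(x, path) {
    if (is(x, "RawMovie")) {
        arr <- x@frames
        meta <- list(type = "movie", dt_s = x@dt)
    } else if (is(x, "RawZStack")) {
        arr <- x@planes
        meta <- list(type = "zstack", z_step_um = x@zStep, channel = x@channel)
    } else stop("x must be a RawMovie or RawZStack")
    cam <- x@camera
    meta <- c(meta, list(
        pixel_size_um = cam@pixelSize, offset = cam@offset, gain = cam@gain,
        read_noise_sd = cam@readNoiseSD,
        seed = if (is.na(x@seed)) NULL else x@seed,
        ny = dim(arr)[1], nx = dim(arr)[2], n_pages = dim(arr)[3]))
    pages <- lapply(seq_len(dim(arr)[3]), function(k) {
        m <- arr[, , k]
        m <- pmin(pmax(round(m), 0), 65535)
        m / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read an acquisition written by [writeAcquisition()]
#'
#' @param path TIFF path (expects \code{<path>.json} next to it).
#' @return A [RawMovie-class] or [RawZStack-class].
#' @export
readAcquisition <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
    cam <- cameraModel(offset = meta$offset, gain = meta$gain,
                       pixelSize = meta$pixel_size_um,
                       readNoiseSD = meta$read_noise_sd %||% 0)
    seed <- if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed)
    if (identical(meta$type, "movie"))
        new("RawMovie", frames = arr, camera = cam, dt = meta$dt_s, seed = seed)
    else
        new("RawZStack", planes = arr, camera = cam, zStep = meta$z_step_um,
            channel = meta$channel %||% "unknown", seed = seed)
}

# write a data.frame as CSV with a single header comment carrying
# provenance; read back with read.csv(..., comment.char = "#")
.writeTable <- function(df, path, runInfo = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(runInfo))
        writeLines(sprintf("# seed=%s config_sha=%s", runInfo$seed,
                           runInfo$config_sha), con)
    write.csv(df, con, row.names = FALSE)
    invisible(path)
}

# stable hash of a configuration list (md5 of its canonical JSON)
.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
}
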