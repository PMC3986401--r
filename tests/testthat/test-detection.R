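# Detection: calibration, DoG candidates, Poisson MLE fitting, LLR filter.

test_that("calibration inverts the camera model", {
    cam <- cameraModel(offset = 100, gain = 5)
    expect_true(all(calibrateFrame(matrix(100, 4, 4), cam) == 0))
    expect_equal(calibrateFrame(matrix(600, 1, 1), cam)[1, 1], 100)
    # round trip through a rendered empty scene: mean equals the background
    sim <- renderMovie(list(), cam, psfModel(background = 10), NULL,
                       nFrames = 50, imageShape = c(32, 32), seed = 3)
    counts <- calibrateFrame(sim$movie)
    expect_equal(mean(counts), 10, tolerance = 3 * sqrt(10 / (50 * 32^2)) / 10)
})

test_that("DoG candidate finding hits isolated spots and nothing else", {
    expect_equal(nrow(findCandidates(matrix(5, 32, 32))), 0L)
    E <- expectedSpot(0:31, 0:31, 10.3, 14.7)
    set.seed(4)
    frame <- matrix(rpois(32^2, E), 32, 32)
    cand <- findCandidates(frame)
    expect_equal(nrow(cand), 1L)
    expect_lt(abs(cand[1, "col"] + 0.5 - 10.3), 1)
    expect_lt(abs(cand[1, "row"] + 0.5 - 14.7), 1)
    # two spots 10 px apart
    E2 <- E + expectedSpot(0:31, 0:31, 20.3, 14.7, background = 0)
    frame2 <- matrix(rpois(32^2, E2), 32, 32)
    expect_equal(nrow(findCandidates(frame2)), 2L)
    expect_error(findCandidates(matrix(1, 4, 4)), "smaller")
})

test_that("MLE fit is exact on its own noise-free model", {
    E <- expectedSpot(0:6, 0:6, 3.5, 3.5)
    fit <- fitSpotMLE(E)
    expect_lt(abs(fit$x_px - 3.5), 1e-3)
    expect_lt(abs(fit$y_px - 3.5), 1e-3)
    expect_lt(fit$llr, 1)
    expect_gt(fit$pvalue, 0.99)
    expect_error(fitSpotMLE(matrix(0, 7, 7)), "all-zero")
    expect_error(fitSpotMLE(matrix(1, 6, 6)), "odd")
})

test_that("MLE localization error shrinks at high SNR", {
    Elow <- expectedSpot(0:6, 0:6, 3.72, 3.28, photons = 200, background = 10)
    Ehigh <- expectedSpot(0:6, 0:6, 3.72, 3.28, photons = 1e5,
                          background = 0.01)
    fl <- fitSpotMLE(Elow); fh <- fitSpotMLE(Ehigh)
    expect_lt(abs(fh$x_px - 3.72), 1e-3)
    expect_lt(fh$crlb_xy, fl$crlb_xy / 10)
})

test_that("empirical fit variance tracks the CRLB and bias is negligible", {
    set.seed(11)
    n <- 300
    errs <- numeric(n); crlb <- numeric(n)
    for (i in seq_len(n)) {
        x0 <- 5.5 + runif(1, -0.5, 0.5); y0 <- 5.5 + runif(1, -0.5, 0.5)
        roi <- noisySpotROI(x0, y0, n = 11L)[4:10, 4:10]
        ft <- fitSpotMLE(roi, origin = c(3, 3))
        errs[i] <- ft$x_px - x0
        crlb[i] <- ft$crlb_xy / 0.127
    }
    expect_lt(abs(sd(errs) / mean(crlb) - 1), 0.2)
    expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(n))
})

test_that("LLR filter accepts clean fits and rejects misfits", {
    # self-consistency: fit of its own forward model passes
    E <- expectedSpot(0:6, 0:6, 3.5, 3.5)
    fits <- llrFilter(list(fitSpotMLE(E)))
    expect_true(fits[[1]]$accepted)
    # below the intensity floor: rejected regardless of LLR
    Elow <- expectedSpot(0:6, 0:6, 3.5, 3.5, photons = 50)
    fits <- llrFilter(list(fitSpotMLE(Elow)), intensityMin = 100)
    expect_false(fits[[1]]$accepted)
    # two overlapping spots fit as one: rejected in > 90% of cases
    set.seed(21)
    rejected <- 0L
    nrep <- 40L
    for (i in seq_len(nrep)) {
        E2 <- expectedSpot(0:6, 0:6, 2.2, 3.5, photons = 800, background = 10) +
              expectedSpot(0:6, 0:6, 4.8, 3.5, photons = 800, background = 0)
        roi <- matrix(rpois(49, E2), 7, 7)
        ft <- llrFilter(list(fitSpotMLE(roi)))[[1]]
        if (!is.na(ft$pvalue) && ft$pvalue < 1e-3) rejected <- rejected + 1L
    }
    expect_gte(rejected / nrep, 0.9)
})

test_that("detection recall and precision reach 0.95 on isolated emitters", {
    p <- 0.127
    origins <- list(c(3, 3), c(9, 3), c(3, 9), c(9, 9))  # >= 2 um apart
    truths <- lapply(seq_along(origins), function(i)
        simulateTrajectory(motionPhase("brownian", 5, D = 0.05), dt = 1 / 9,
                           origin = c(origins[[i]], 0), particleId = i,
                           seed = 30 + i))
    sim <- renderMovie(truths, cameraModel(), psfModel(), blink = NULL,
                       imageShape = c(96, 96), seed = 31)
    loc <- detectSpots(sim$movie)
    ev <- evaluateAgainstTruth(list(localizations = loc), sim$truth)
    expect_gte(ev$detection$recall, 0.95)
    expect_gte(ev$detection$precision, 0.95)
    expect_lt(ev$localization_rmse_um, 0.05)
})
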