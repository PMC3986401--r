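# Synthetic-data generator: motion models, camera forward model, blinking,
# and the two-channel cell z-stack.

test_that("stationary and directed phases follow their closed forms", {
    tr <- simulateTrajectory(motionPhase("stationary", 10), dt = 1,
                             origin = c(2, 3, 0))
    expect_true(all(tr$x == 2) && all(tr$y == 3))

    tr <- simulateTrajectory(motionPhase("directed", 10, v = 1.0), dt = 1 / 9)
    net <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
    expect_equal(net, 10.0, tolerance = 1e-9)
    expect_equal(nrow(tr), 91L)  # origin + 90 steps
})

test_that("brownian steps have variance 2 D dt per axis", {
    tr <- simulateTrajectory(motionPhase("brownian", 10^4 / 9, D = 0.29),
                             dt = 1 / 9, seed = 2)
    v <- c(var(diff(tr$x)), var(diff(tr$y)))
    expect_equal(v, rep(2 * 0.29 / 9, 2), tolerance = 0.05)
})

test_that("confined motion stays inside its corral", {
    tr <- simulateTrajectory(motionPhase("confined", 100, D = 0.3, L = 0.8),
                             dt = 1 / 9, origin = c(5, 5, 0), seed = 3)
    expect_true(all(abs(tr$x - 5) <= 0.4 + 1e-12))
    expect_true(all(abs(tr$y - 5) <= 0.4 + 1e-12))
})

test_that("input validation rejects bad phases and dt", {
    expect_error(simulateTrajectory(motionPhase("brownian", 1, D = 0.1),
                                    dt = 0), "dt")
    expect_error(motionPhase("confined", 1, D = 0.1), "L")
    expect_error(motionPhase("brownian", -1, D = 0.1), "duration")
})

test_that("empty scene renders to the camera offset exactly", {
    sim <- renderMovie(list(), cameraModel(offset = 100, gain = 5),
                       psfModel(background = 0), NULL, nFrames = 3,
                       imageShape = c(16, 16), seed = 1)
    expect_true(all(sim$movie@frames == 100))
})

test_that("long-run frame mean matches the analytic forward model", {
    cam <- cameraModel(offset = 100, gain = 5)
    psf <- psfModel(sigma = 1.2, photonsOn = 800, background = 10)
    p <- cam@pixelSize
    tr <- simulateTrajectory(motionPhase("stationary", 10^4), dt = 1,
                             origin = c(7.5 * p, 7.5 * p, 0))
    sim <- renderMovie(tr, cam, psf, blink = NULL, imageShape = c(15, 15),
                       seed = 7)
    E <- expectedSpot(0:14, 0:14, 7.5, 7.5, 1.2, 800, 10)
    peak <- which(E == max(E), arr.ind = TRUE)[1, ]
    obs <- mean(sim$movie@frames[peak[1], peak[2], ])
    expectADU <- cam@gain * E[peak[1], peak[2]] + cam@offset
    se <- cam@gain * sqrt(E[peak[1], peak[2]] / 10^4)
    expect_lt(abs(obs - expectADU), 3 * se)
})

test_that("blinking on-fraction matches the Markov stationary law", {
    tr <- simulateTrajectory(motionPhase("stationary", 10^4), dt = 1,
                             origin = c(1, 1, 0))
    sim <- renderMovie(tr, cameraModel(), psfModel(),
                       blinkModel(pOff = 0.1, pOn = 0.5), imageShape = c(16, 16),
                       seed = 11)
    expect_equal(mean(sim$truth$on), 5 / 6, tolerance = 0.025)
})

test_that("noise-free renders conserve expected photons", {
    cam <- cameraModel(offset = 0, gain = 1)
    psf <- psfModel(sigma = 1.2, photonsOn = 500, background = 2)
    p <- cam@pixelSize
    tr <- simulateTrajectory(motionPhase("stationary", 5), dt = 1,
                             origin = c(16 * p, 16 * p, 0))
    sim <- renderMovie(tr, cam, psf, NULL, imageShape = c(32, 32),
                       shotNoise = FALSE)
    total <- sum(sim$movie@frames[, , 1])
    expect_equal(total, 2 * 32^2 + 500, tolerance = 1e-3)
})

test_that("identical seeds give bit-identical movies and truth", {
    tr <- simulateTrajectory(motionPhase("brownian", 5, D = 0.1), dt = 1 / 9,
                             origin = c(2, 2, 0), seed = 5)
    a <- renderMovie(tr, cameraModel(), psfModel(), blinkModel(),
                     imageShape = c(32, 32), seed = 9)
    b <- renderMovie(tr, cameraModel(), psfModel(), blinkModel(),
                     imageShape = c(32, 32), seed = 9)
    expect_identical(a$movie@frames, b$movie@frames)
    expect_identical(a$truth, b$truth)
})

test_that("emitters outside the field are rejected", {
    tr <- simulateTrajectory(motionPhase("stationary", 3), dt = 1,
                             origin = c(50, 50, 0))
    expect_error(renderMovie(tr, cameraModel(), psfModel(), NULL,
                             imageShape = c(16, 16)),
                 "outside the field")
})

test_that("truth MSD of simulated brownian motion matches 4 D dt", {
    tr <- simulateTrajectory(motionPhase("brownian", 500, D = 0.29),
                             dt = 1 / 9, seed = 13)
    m <- bruteMSD(tr$x, tr$y, 5)
    expect_equal(m, 4 * 0.29 * (1:5) / 9, tolerance = 0.1)
})

test_that("cell z-stack honours placement geometry and label counts", {
    geom <- cellGeometry(radius = 6, center = c(8, 8), nPlanes = 9)
    sim <- simulateCellZStack(geom, nQD = 20, fracInternal = 1, seed = 5)
    expect_equal(nrow(sim$truth), 20L)
    expect_true(all(sim$truth$label == "internal"))
    for (i in seq_len(20)) {
        poly <- membraneContour(geom, sim$truth$plane[i])
        expect_true(somaSPT:::.pointInPolygon(sim$truth$x_um[i],
                                              sim$truth$y_um[i], poly))
        expect_gte(somaSPT:::.distToPolygon(sim$truth$x_um[i],
                                            sim$truth$y_um[i], poly), 0.5)
    }

    sim2 <- simulateCellZStack(geom, nQD = 50, fracInternal = 0.9, seed = 6)
    expect_equal(sum(sim2$truth$label == "internal"), 45L)
    expect_equal(sum(sim2$truth$label == "membrane"), 5L)
    dmem <- somaSPT:::.distToPolygon(
        sim2$truth$x_um[sim2$truth$label == "membrane"],
        sim2$truth$y_um[sim2$truth$label == "membrane"],
        membraneContour(geom, 3))
    expect_true(all(dmem <= 0.1 + 1e-9))

    sim0 <- simulateCellZStack(geom, nQD = 0, fracInternal = 0.5, seed = 7)
    expect_equal(nrow(sim0$truth), 0L)
})

test_that("acquisition TIFF + sidecar round trip is exact", {
    tr <- simulateTrajectory(motionPhase("stationary", 3), dt = 1 / 9,
                             origin = c(1, 1, 0))
    sim <- renderMovie(tr, cameraModel(), psfModel(), NULL,
                       imageShape = c(16, 16), seed = 21)
    path <- file.path(withr::local_tempdir(), "m.tif")
    writeAcquisition(sim$movie, path)
    back <- readAcquisition(path)
    expect_equal(back@frames, sim$movie@frames)
    expect_equal(back@dt, sim$movie@dt)
    expect_equal(pixelSize(back), pixelSize(sim$movie))
})
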