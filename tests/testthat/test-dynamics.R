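# MSD analysis, diffusion model fitting, smooth paths, speeds, and motion
# phase segmentation.

test_that("MSD matches closed forms and the brute-force oracle", {
    # stationary: identically zero
    st <- data.frame(frame = 1:20, t = (0:19) / 9, x_um = 2, y_um = 3,
                     gap = FALSE)
    expect_true(all(computeMSD(st)$msd == 0))
    # ballistic: msd = v^2 dt^2 exactly
    v <- 0.8
    bl <- data.frame(frame = 1:40, t = (0:39) / 9, x_um = v * (0:39) / 9,
                     y_um = 0, gap = FALSE)
    m <- computeMSD(bl)
    expect_equal(m$msd, v^2 * m$lags^2, tolerance = 1e-12)
    # random trajectory: equality with the O(N^2) double loop
    tr <- simulateTrajectory(motionPhase("brownian", 20, D = 0.29), dt = 1 / 9,
                             seed = 3)
    m2 <- computeMSD(tr)
    expect_equal(m2$msd, bruteMSD(tr$x, tr$y, length(m2$lags)),
                 tolerance = 1e-12)
    expect_true(all(diff(m2$nPairs) <= 0))
    expect_error(computeMSD(st[1:5, ]), "too short")
})

test_that("gap frames are excluded from MSD pairs", {
    tr <- data.frame(frame = 1:30, t = (0:29) / 9,
                     x_um = cumsum(rnorm(30, 0, 0.1)),
                     y_um = cumsum(rnorm(30, 0, 0.1)),
                     gap = rep(c(FALSE, FALSE, TRUE), 10))
    m <- computeMSD(tr)
    oracle <- bruteMSD(tr$x_um, tr$y_um, length(m$lags), tr$gap)
    expect_equal(m$msd, oracle, tolerance = 1e-12)
})

test_that("free-model fit inverts noiseless free-diffusion MSD exactly", {
    lags <- (1:20) / 9
    mc <- structure(list(lags = lags, msd = 4 * 0.5 * lags,
                         nPairs = rep(100L, 20), dt = 1 / 9),
                    class = "MSDCurve")
    ft <- fitMSD(mc)
    expect_identical(ft$fit$model, "free")
    expect_equal(ft$fit$D, 0.5, tolerance = 1e-6)
    expect_equal(ft$fit$offset, 0, tolerance = 1e-8)
})

test_that("confined simulations select the corral model and recover L", {
    set.seed(6)
    out <- replicate(8, {
        tr <- simulateTrajectory(motionPhase("confined", 111, D = 0.05,
                                             L = 0.5), dt = 1 / 9)
        f <- fitMSD(computeMSD(asObserved(tr, 0.02)))$fit
        c(L = f$L, corral = f$model == "corralled")
    })
    expect_gte(mean(out["corral", ]), 0.75)
    sel <- out["corral", ] == 1
    expect_lt(abs(mean(out["L", sel]) - 0.5) / 0.5, 0.2)
})

test_that("fitted D is invariant under rigid rotation and translation", {
    tr <- simulateTrajectory(motionPhase("brownian", 60, D = 0.29), dt = 1 / 9,
                             seed = 7)
    obs <- asObserved(tr, 0)
    D0 <- fitMSD(computeMSD(obs))$fit$D
    th <- 0.7
    rot <- data.frame(frame = obs$frame, t = obs$t,
                      x_um = cos(th) * obs$x_um - sin(th) * obs$y_um + 5,
                      y_um = sin(th) * obs$x_um + cos(th) * obs$y_um - 2,
                      gap = FALSE)
    expect_equal(fitMSD(computeMSD(rot))$fit$D, D0, tolerance = 1e-10)
})

test_that("ballistic input raises the poor-fit flag", {
    bl <- data.frame(frame = 1:100, t = (0:99) / 9, x_um = 0.1 * (0:99),
                     y_um = 0, gap = FALSE)
    ft <- fitMSD(computeMSD(bl))
    expect_true(ft$fit$flagged)
    # an honest diffusive curve is not flagged
    tr <- simulateTrajectory(motionPhase("brownian", 60, D = 0.29), dt = 1 / 9,
                             seed = 8)
    expect_false(fitMSD(computeMSD(asObserved(tr)))$fit$flagged)
})

test_that("smooth paths reproduce line and semicircle arc lengths", {
    # collinear constant speed: arc length = straight-line distance
    tr <- data.frame(frame = 1:50, t = (0:49) / 5, x_um = 0.1 * (0:49),
                     y_um = 0, gap = FALSE)
    sp <- fitSmoothPath(tr, method = "poly2")
    expect_equal(sp$arcLength, 4.9, tolerance = 1e-6)
    # noiseless semicircle of radius 3: arc length = 3 pi within 1%
    th <- seq(0, pi, length.out = 200)
    trc <- data.frame(frame = 1:200, t = seq(0, 10, length.out = 200),
                      x_um = 3 * cos(th), y_um = 3 * sin(th), gap = FALSE)
    spc <- fitSmoothPath(trc, method = "spline")
    expect_lt(abs(spc$arcLength - 3 * pi) / (3 * pi), 0.01)
    expect_gte(spc$arcLength,
               sqrt(diff(range(trc$x_um))^2) - 1e-9)  # >= chord length
    expect_error(fitSmoothPath(tr[1:3, ], method = "poly2"), "underdetermined")
})

test_that("path positions and speeds recover noiseless constant-speed motion", {
    tr <- data.frame(frame = 1:50, t = (0:49) / 5, x_um = 0.1 * (0:49),
                     y_um = 0, gap = FALSE)
    sp <- fitSmoothPath(tr, method = "poly2")
    pos <- pathPosition(tr, sp)
    expect_equal(pos$s, 0.1 * (0:49), tolerance = 1e-6)
    spd <- estimateSpeeds(pos, window = 2)
    expect_equal(spd$speed, rep(0.5, nrow(spd)), tolerance = 1e-3)
    # reversed motion gives negative speeds
    rev <- data.frame(t = pos$t, s = max(pos$s) - pos$s)
    expect_true(all(estimateSpeeds(rev, window = 2)$speed < 0))
    expect_error(estimateSpeeds(pos, window = 100), "window")
})

test_that("noisy positions project onto the path within twice the noise", {
    set.seed(14)
    th <- seq(0, pi, length.out = 300)
    truth_s <- 3 * th
    tr <- data.frame(frame = 1:300, t = seq(0, 15, length.out = 300),
                     x_um = 3 * cos(th) + rnorm(300, 0, 0.03),
                     y_um = 3 * sin(th) + rnorm(300, 0, 0.03), gap = FALSE)
    sp <- fitSmoothPath(tr, method = "spline")
    pos <- pathPosition(tr, sp)
    expect_lt(sqrt(mean((pos$s - truth_s)^2)), 2 * 0.03)
})

test_that("phase segmentation recovers a directed-immobile-directed sequence", {
    set.seed(8)
    tr <- simulateTrajectory(list(
        motionPhase("directed", 10, v = 1.5),
        motionPhase("stationary", 60),
        motionPhase("directed", 10, v = 0.25)), dt = 1 / 18)
    ph <- segmentPhases(asObserved(tr))
    main <- ph[ph$duration > 2, ]
    expect_identical(main$kind, c("directed", "immobile", "directed"))
    expect_lt(abs(main$start[2] - 10), 2)
    expect_lt(abs(main$end[2] - 70), 2)
    # recovered phase durations cover >= 80% of the truth
    covered <- sum(pmin(main$end, c(10, 70, 80)) -
                   pmax(main$start, c(0, 10, 70)))
    expect_gte(covered / 80, 0.8)
})

test_that("an all-stationary trajectory is one immobile segment", {
    tr <- simulateTrajectory(motionPhase("stationary", 20), dt = 1 / 9,
                             origin = c(1, 1, 0))
    ph <- segmentPhases(asObserved(tr, 0.02))
    expect_equal(nrow(ph), 1L)
    expect_identical(ph$kind, "immobile")
})

test_that("pure Brownian motion is classified mostly diffusive", {
    set.seed(9)
    tr <- simulateTrajectory(motionPhase("brownian", 60, D = 0.29), dt = 1 / 9)
    ph <- segmentPhases(asObserved(tr))
    frac <- sum(ph$duration[ph$kind == "diffusive"]) / sum(ph$duration)
    expect_gte(frac, 0.7)
})
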