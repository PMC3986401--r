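# Channel alignment, the exact assignment solver, and trajectory linking.

test_that("the LAP solver matches exhaustive enumeration on random costs", {
    set.seed(9)
    for (trial in 1:30) {
        n <- sample(2:6, 1)
        C <- matrix(runif(n * n), n, n)
        sol <- somaSPT:::.lapSolve(C)
        expect_equal(sum(C[cbind(seq_len(n), sol)]),
                     bruteAssignment(C)$cost, tolerance = 1e-12)
    }
})

test_that("channel alignment recovers identity, integer and sub-pixel shifts", {
    set.seed(10)
    A <- somaSPT:::.gaussianBlur(matrix(rnorm(64^2), 64, 64), 2)
    s0 <- alignChannels(A, A)
    expect_equal(c(s0$dx, s0$dy), c(0, 0), tolerance = 1e-9)
    # circular shift: B[r, c] = A[r - 2, c + 3], so content of B sits at
    # (+2 rows, -3 cols) relative to A and the aligning shift is (+3, -2)
    B <- A[c((64 - 1):64, 1:(64 - 2)), c(4:64, 1:3)]
    s1 <- alignChannels(A, B)
    expect_equal(c(s1$dx, s1$dy), c(3, -2), tolerance = 0.05)
    # sub-pixel shift constructed in Fourier space
    shiftF <- function(img, dx, dy) {
        ny <- nrow(img); nx <- ncol(img)
        fx <- (seq_len(nx) - 1); fx[fx > nx / 2] <- fx[fx > nx / 2] - nx
        fy <- (seq_len(ny) - 1); fy[fy > ny / 2] <- fy[fy > ny / 2] - ny
        ph <- exp(-2i * pi * (outer(fy, rep(1, nx)) * dy / ny +
                              outer(rep(1, ny), fx) * dx / nx))
        Re(fft(fft(img) * ph, inverse = TRUE)) / (nx * ny)
    }
    s2 <- alignChannels(A, shiftF(A, 1.5, 0))
    expect_equal(abs(s2$dx), 1.5, tolerance = 0.1)
    expect_equal(s2$dy, 0, tolerance = 0.1)
})

test_that("a single stationary spot links into one full-length trajectory", {
    fits <- data.frame(frame = 1:50, x_um = 1, y_um = 1)
    trs <- linkTrajectories(fits, dt = 1 / 9)
    expect_length(trs, 1L)
    expect_equal(nrow(trs[[1]]), 50L)
    expect_false(any(trs[[1]]$gap))
})

test_that("two crossing particles are linked as by exhaustive assignment", {
    # shallow crossing (paths cross in x but never coincide): per frame
    # pair, compare against enumerating both matchings and taking the
    # cheaper total squared displacement
    x1 <- seq(0, 1, length.out = 5); y1 <- seq(0, 0.3, length.out = 5)
    x2 <- seq(1, 0, length.out = 5); y2 <- seq(0.5, 0.2, length.out = 5)
    fits <- data.frame(frame = rep(1:5, each = 2),
                       x_um = as.vector(rbind(x1, x2)),
                       y_um = as.vector(rbind(y1, y2)))
    trs <- linkTrajectories(fits, dt = 1, maxDisp = 0.64)
    expect_length(trs, 2L)
    expect_true(all(vapply(trs, nrow, 1L) == 5L))
    # oracle per consecutive pair: straight-through is cheaper than swapping
    for (f in 1:4) {
        a <- cbind(c(x1[f], x2[f]), c(y1[f], y2[f]))
        b <- cbind(c(x1[f + 1], x2[f + 1]), c(y1[f + 1], y2[f + 1]))
        C <- outer(1:2, 1:2, function(i, j)
            (a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
        expect_equal(bruteAssignment(C)$perm, c(1L, 2L))
    }
    # and the linker indeed keeps each particle on its own line
    ends <- vapply(trs, function(tr) tr$x_um[5], numeric(1))
    starts <- vapply(trs, function(tr) tr$x_um[1], numeric(1))
    expect_equal(sort(abs(ends - starts)), c(1, 1), tolerance = 1e-9)
})

test_that("gap closing bridges blinking gaps up to max_gap", {
    fits <- data.frame(frame = c(1:10, 13:20), x_um = 1, y_um = 1)
    t5 <- linkTrajectories(fits, dt = 1, maxGap = 5L)
    expect_length(t5, 1L)
    expect_equal(sum(t5[[1]]$gap), 2L)
    expect_equal(nrow(t5[[1]]), 20L)
    t1 <- linkTrajectories(fits, dt = 1, maxGap = 1L)
    expect_length(t1, 2L)
})

test_that("localizations are conserved through linking", {
    set.seed(12)
    fits <- data.frame(frame = rep(1:20, each = 3),
                       x_um = rep(c(1, 4, 7), 20) + rnorm(60, 0, 0.05),
                       y_um = rep(c(1, 4, 7), 20) + rnorm(60, 0, 0.05))
    trs <- linkTrajectories(fits, dt = 1 / 9)
    expect_equal(sum(vapply(trs, function(tr) sum(!tr$gap), 1L)), nrow(fits))
})

test_that("linking is invariant to input row order within frames", {
    set.seed(13)
    fits <- data.frame(frame = rep(1:15, each = 2),
                       x_um = rep(c(1, 4), 15) + rnorm(30, 0, 0.05),
                       y_um = rep(c(1, 4), 15) + rnorm(30, 0, 0.05))
    trs1 <- linkTrajectories(fits, dt = 1)
    trs2 <- linkTrajectories(fits[sample(nrow(fits)), ], dt = 1)
    key <- function(trs) lapply(trs, function(tr)
        tr[order(tr$frame), c("frame", "x_um", "y_um")])
    expect_equal(key(trs1), key(trs2), ignore_attr = TRUE)
})

test_that("trajectory purity reaches 0.98 on well-separated simulated movies", {
    p <- 0.127
    origins <- list(c(3, 3), c(9, 3), c(6, 9))
    truths <- lapply(seq_along(origins), function(i)
        simulateTrajectory(motionPhase("brownian", 10, D = 0.05), dt = 1 / 9,
                           origin = c(origins[[i]], 0), particleId = i,
                           seed = 40 + i))
    sim <- renderMovie(truths, cameraModel(), psfModel(),
                       blinkModel(pOff = 0.05, pOn = 0.6),
                       imageShape = c(96, 96), seed = 44)
    loc <- detectSpots(sim$movie)
    trs <- linkTrajectories(loc, dt = 1 / 9)
    ev <- evaluateAgainstTruth(list(localizations = loc, trajectories = trs),
                               sim$truth)
    expect_gte(ev$trajectory_purity, 0.98)
})
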