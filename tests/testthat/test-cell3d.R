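# Radial-symmetry localization, z-linking, membrane/internal classification
# and the internalization fraction.

test_that("radial symmetry is exact on symmetric noise-free spots", {
    E <- expectedSpot(0:10, 0:10, 5.5, 5.5)
    rs <- localizeRadialSymmetry(E, pixelSize = 1)
    expect_lt(abs(rs[["x_px"]] - 5.5), 1e-6)
    expect_lt(abs(rs[["y_px"]] - 5.5), 1e-6)
    expect_error(localizeRadialSymmetry(matrix(3, 9, 9)), "degenerate")
})

test_that("radial symmetry recovers sub-pixel offsets, matching a grid-search oracle", {
    E <- expectedSpot(0:10, 0:10, 5.5 + 0.30, 5.5 - 0.20)
    rs <- localizeRadialSymmetry(E, pixelSize = 1)
    expect_lt(abs(rs[["x_px"]] - 5.80), 0.02)
    expect_lt(abs(rs[["y_px"]] - 5.30), 0.02)
    # oracle: dense grid search maximizing the radial-symmetry objective
    # (gradient-weighted alignment of gradients with radial directions)
    du <- E[1:10, 2:11] - E[2:11, 1:10]
    dv <- E[1:10, 1:10] - E[2:11, 2:11]
    gx <- (du - dv) / 2; gy <- -(du + dv) / 2  # unrotated gradient components
    xm <- matrix(1:10, 10, 10, byrow = TRUE); ym <- matrix(1:10, 10, 10)
    objective <- function(cx, cy) {
        rx <- xm - cx; ry <- ym - cy
        rn <- sqrt(rx^2 + ry^2) + 1e-9
        sum(((gx * rx + gy * ry) / rn)^2) / sum(gx^2 + gy^2)
    }
    grid <- expand.grid(cx = seq(5.6, 6.0, by = 0.005),
                        cy = seq(5.1, 5.5, by = 0.005))
    best <- grid[which.max(mapply(objective, grid$cx, grid$cy)), ]
    expect_lt(abs(rs[["x_px"]] - best$cx), 0.02)
    expect_lt(abs(rs[["y_px"]] - best$cy), 0.02)
})

test_that("z-linking groups across blinking gaps and enforces 3 planes", {
    mk <- function(planes) data.frame(
        plane = planes, x_um = 1, y_um = 1, x_px = 7.9, y_px = 7.9)
    q <- linkZ(mk(c(4, 5, 6)), zStep = 0.3)
    expect_equal(nrow(q), 1L)
    expect_equal(q$z_um, 4 * 0.3)           # planes {4,5,6} -> z = 5th * step
    expect_equal(q$n_planes, 3L)

    q2 <- linkZ(mk(c(2, 3)), zStep = 0.3)
    expect_equal(nrow(q2), 0L)
    expect_equal(attr(q2, "n_discarded"), 2L)

    q3 <- linkZ(mk(c(2, 3, 5)), zStep = 0.3)  # off in plane 4: still linked
    expect_equal(nrow(q3), 1L)
    expect_equal(q3$z_um, (7 / 3) * 0.3)
})

test_that("strict pixel grouping separates jittered localizations that the neighborhood mode joins", {
    f <- data.frame(plane = 1:4, x_um = 1, y_um = 1,
                    x_px = c(7.95, 8.05, 7.95, 8.05), y_px = 8.0)
    expect_equal(nrow(linkZ(f, 0.3, tolerance = "neighborhood")), 1L)
    expect_equal(nrow(linkZ(f, 0.3, tolerance = "strict")), 0L)  # 2+2 planes
})

test_that("z-link output count never exceeds the per-plane maximum", {
    set.seed(8)
    geom <- cellGeometry(radius = 6, center = c(8, 8), nPlanes = 9)
    sim <- simulateCellZStack(geom, nQD = 20, fracInternal = 0.7, seed = 8)
    fits <- localizeStack(sim$qd)
    qds <- linkZ(fits, zStep = 0.3)
    expect_lte(nrow(qds), max(table(fits$plane)))
})

test_that("classification follows the signed distance and threshold rule", {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    circle <- cbind(5 + 5 * cos(th), 5 + 5 * sin(th))
    mm <- new("MembraneMap", contours = list(circle),
              pcMaps = list(matrix(0, 1, 1)), pixelSize = 0.127, zStep = 0.3,
              method = "phase_congruency")
    mk <- function(x, y) data.frame(id = 1L, x_um = x, y_um = y, z_um = 0,
                                    n_planes = 3L, label = NA_character_,
                                    dist_membrane = NA_real_)
    # on a vertex: membrane at zero distance
    q <- classifyLocation(mk(circle[1, 1], circle[1, 2]), mm)
    expect_identical(q$label, "membrane")
    # 2 um inside a 5 um circle: internal at -3 um
    q <- classifyLocation(mk(5 + 3, 5), mm)
    expect_identical(q$label, "internal")
    expect_equal(q$dist_membrane, -2, tolerance = 0.01)
    q <- classifyLocation(mk(5 + 2, 5), mm)
    expect_equal(q$dist_membrane, -3, tolerance = 0.01)
    # threshold semantics: d_mem = 0 puts a just-inside point internal
    q <- classifyLocation(mk(5 + 4.9, 5), mm, dMem = 0)
    expect_identical(q$label, "internal")
    # outside
    q <- classifyLocation(mk(5 + 6, 5), mm)
    expect_identical(q$label, "external")
    # empty nearest plane
    mmEmpty <- new("MembraneMap", contours = list(NULL),
                   pcMaps = list(matrix(0, 1, 1)), pixelSize = 0.127,
                   zStep = 0.3, method = "phase_congruency")
    q <- classifyLocation(mk(5, 5), mmEmpty)
    expect_identical(q$label, "unresolved")
})

test_that("internalization fraction is the internal/(internal+membrane) ratio", {
    qds <- data.frame(label = c(rep("internal", 45), rep("membrane", 5)))
    expect_equal(internalizationFraction(qds)$fraction, 0.90)
    expect_equal(internalizationFraction(
        data.frame(label = rep("membrane", 4)))$fraction, 0)
    out <- internalizationFraction(data.frame(label = rep("external", 3)))
    expect_true(is.na(out$fraction))
    expect_error(internalizationFraction(data.frame(label = character())),
                 "no labelled")
})

test_that("the full cell analysis recovers a known internal fraction", {
    geom <- cellGeometry(radius = 7, center = c(9, 9), nPlanes = 9)
    sim <- simulateCellZStack(geom, nQD = 50, fracInternal = 0.8, seed = 17)
    res <- analyzeCellStack(sim$qd, sim$membrane)
    expect_lt(abs(res$internalization$fraction - 0.8), 0.08)
    ev <- evaluateAgainstTruth(list(cell = res), sim$truth)
    expect_gte(ev$classification$accuracy, 0.9)
})
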