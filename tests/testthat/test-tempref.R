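test_that("probe interpolation is exact on and between probes", {
    probes <- data.frame(position = c(0, 36), temperatureC = c(14, 32))
    a <- gradientAssay("a", "s", probes = probes,
        flyPositions = c(18, 0, 36))
    expect_equal(assignFlyTemperatures(a), c(23, 14, 32))
})

test_that("piecewise interpolation matches the searchsorted oracle", {
    probes <- data.frame(position = c(0, 10, 22, 36),
        temperatureC = c(14, 19, 27, 32))
    set.seed(53)
    pos <- runif(100, 0, 36)
    a <- gradientAssay("a", "s", probes = probes, flyPositions = pos)
    expect_equal(assignFlyTemperatures(a), oracleInterp(probes, pos))
    # affine rescaling of the position axis leaves temperatures unchanged
    a2 <- gradientAssay("a2", "s",
        probes = transform(probes, position = 5 + 3 * position),
        flyPositions = 5 + 3 * pos)
    expect_equal(assignFlyTemperatures(a2), assignFlyTemperatures(a))
    # positions beyond the 2% tolerance are refused
    expect_error(gradientAssay("a3", "s", probes = probes,
        flyPositions = c(18, 40)), "tolerance")
})

test_that("the nine-range binning follows the boundary convention", {
    d <- binPreference(c(15.2, 16.0, 29.9, 30.5))
    expect_equal(d@percentages,
        c(25, 25, 0, 0, 0, 0, 0, 25, 25))
    expect_equal(binPreference(rep(23, 7))@percentages[5L], 100)
    # boundary values: 16.0 -> 16-18, 30.0 -> 28-30, 18.0 -> 18-20
    d2 <- binPreference(c(16, 18, 30))
    expect_equal(which(d2@percentages > 0), c(2L, 3L, 8L))
    expect_error(binPreference(numeric(0)), "usage error")
})

test_that("every valid temperature maps to exactly one range", {
    set.seed(59)
    for (i in 1:200) {
        temps <- runif(sample(5:50, 1), 14, 32)
        d <- binPreference(temps)
        expect_equal(sum(d@percentages), 100, tolerance = 1e-9)
        expect_true(all(d@percentages >= 0))
    }
})

test_that("the preferred temperature is the assay median", {
    expect_equal(preferredTemperature(c(18, 20, 22, 30)), 21)
    expect_equal(preferredTemperature(24.3), 24.3)
    expect_error(preferredTemperature(numeric(0)), "usage error")
    # invariant under fly order and axis rescaling
    probes <- data.frame(position = c(0, 36), temperatureC = c(14, 32))
    set.seed(61)
    pos <- runif(30, 0, 36)
    t1 <- assignFlyTemperatures(gradientAssay("a", "s", probes = probes,
        flyPositions = pos))
    t2 <- assignFlyTemperatures(gradientAssay("a", "s", probes = probes,
        flyPositions = sample(pos)))
    expect_equal(preferredTemperature(t1), preferredTemperature(t2))
})

test_that("simulated assays recover the configured preference", {
    p <- speciesProfile("rec", prefTemp = 24, prefSpread = 1.5,
        uniformFraction = 0)
    meds <- vapply(1:8, function(j)
        preferredTemperature(assignFlyTemperatures(
            simulateGradientAssay(p, nFlies = 40, seed = 300 + j))),
        numeric(1))
    expect_lt(mean(abs(meds - 24)), 0.5)
})

test_that("aggregation averages assays and guards its inputs", {
    d1 <- binPreference(c(17, 19, 21, 23))
    d2 <- binPreference(c(17, 19, 21, 23))
    agg <- aggregateDistributions(list(d1, d2))
    expect_equal(agg@percentages, d1@percentages)
    expect_equal(agg@sem, rep(0, 9))
    expect_equal(sum(agg@percentages), 100, tolerance = 1e-9)
    expect_error(aggregateDistributions(list(agg, d1)),
        "refusing to aggregate")
    expect_error(aggregateDistributions(list(d1)), "usage error")
})

test_that("group comparison flags small designs and detects separation", {
    same <- c(22, 23, 24, 23.5, 22.5)
    r <- comparePreference(same, same)
    expect_equal(r$pValue, 1)
    expect_equal(r$direction, "none")
    r2 <- comparePreference(c(20, 21, 22), c(25, 26, 27))
    expect_equal(r2$U, 0)
    expect_true(any(grepl("smaller than 5", r2$notes)))
})
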