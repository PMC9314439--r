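test_that("a zero-rate profile produces an all-zero table", {
    p <- speciesProfile("null", baselineRate = 0,
        morningPeak = c(510, 45, 0), eveningPeak = c(1170, 45, 0))
    ae <- simulateActivity(p, simulationConfig(nFlies = 2, nDays = 1,
        temperaturesC = 23, seed = 5))
    expect_true(all(activityCounts(ae) == 0))
})

test_that("simulation is deterministic in (profile, config)", {
    p <- speciesProfile("demo")
    cfg <- simulationConfig(nFlies = 3, nDays = 2,
        temperaturesC = c(17, 26), seed = 42)
    a <- simulateActivity(p, cfg)
    b <- simulateActivity(p, cfg)
    expect_identical(activityCounts(a), activityCounts(b))
    expect_identical(flyInfo(a), flyInfo(b))
})

test_that("thermal scaling of simulated totals matches the configured TPC", {
    # breadth chosen so scale(26)/scale(17) = 2 exactly
    breadth <- sqrt(81 / (2 * log(2)))
    p <- speciesProfile("tpc2", baselineRate = 1,
        tpcTrue = c(26, 1, breadth))
    expect_equal(tpcScaleTrue(p, 26) / tpcScaleTrue(p, 17), 2)
    ae <- simulateActivity(p, simulationConfig(nFlies = 100, nDays = 3,
        temperaturesC = c(17, 26), seed = 8))
    s <- activitySummary(ae)
    m17 <- s$totalDaily[s$temperatureC == 17]
    m26 <- s$totalDaily[s$temperatureC == 26]
    ratio <- mean(m26) / mean(m17)
    # delta-method 95% Monte-Carlo interval around the true ratio of 2
    se <- ratio * sqrt(var(m26) / (length(m26) * mean(m26)^2) +
        var(m17) / (length(m17) * mean(m17)^2))
    expect_lt(abs(ratio - 2), 1.96 * se + 0.05)
})

test_that("mean simulated totals match the closed-form expectation", {
    p <- speciesProfile("exp", baselineRate = 1.2, nightAttenuation = 0.4)
    ae <- simulateActivity(p, simulationConfig(nFlies = 120, nDays = 3,
        temperaturesC = 23, seed = 13))
    s <- activitySummary(ae)
    expected <- expectedDailyActivity(p, 23)
    se <- sd(s$totalDaily) / sqrt(nrow(s))
    expect_lt(abs(mean(s$totalDaily) - expected), 4 * se + 0.02 * expected)
})

test_that("scored sleep recovers the generator's mean bout length", {
    p <- speciesProfile("ref", baselineRate = 2, nightAttenuation = 0.8,
        sleepMeanBout = 30, wakeMeanBout = 30)
    ae <- simulateActivity(p, simulationConfig(nFlies = 100, nDays = 3,
        temperaturesC = 23, seed = 7))
    ss <- sleepSummary(ae)
    pooled <- sum(ss$totalSleep) / sum(ss$nBouts)
    expect_lt(abs(pooled - 30) / 30, 0.10)
})

test_that("gradient assays are deterministic and honor degenerate mixtures", {
    p <- speciesProfile("g", prefTemp = 24, prefSpread = 1.5,
        uniformFraction = 0)
    a <- simulateGradientAssay(p, nFlies = 30, seed = 3)
    b <- simulateGradientAssay(p, nFlies = 30, seed = 3)
    expect_identical(a@flyPositions, b@flyPositions)
    # pref_spread -> 0: all recovered temperatures collapse onto prefTemp
    p0 <- speciesProfile("g0", prefTemp = 24, prefSpread = 1e-6,
        uniformFraction = 0)
    t0 <- assignFlyTemperatures(simulateGradientAssay(p0, nFlies = 20,
        seed = 4))
    expect_true(all(abs(t0 - 24) < 1e-3))
    # non-monotone calibration is refused
    badProbes <- data.frame(position = c(0, 18, 36),
        temperatureC = c(14, 30, 20))
    expect_error(simulateGradientAssay(p, probes = badProbes, nFlies = 10,
        seed = 1), "calibration error")
})

test_that("gradient-ignoring flies are uniform on the field", {
    p <- speciesProfile("u", uniformFraction = 1)
    nonReject <- 0L
    for (s in 1:50) {
        a <- simulateGradientAssay(p, nFlies = 40, seed = 1000 + s)
        ks <- suppressWarnings(stats::ks.test(a@flyPositions, "punif",
            0, 36))
        if (ks$p.value > 0.01) nonReject <- nonReject + 1L
    }
    expect_gte(nonReject, 45L)
})

test_that("the species panel is complete, ten-fold spanned and fixed", {
    panel <- makeSpeciesPanel(seed = 1)
    expect_length(panel, 11L)
    rates <- vapply(panel, function(p) p@baselineRate, numeric(1))
    expect_lt(abs(max(rates) / min(rates) - 10), 1)
    panel2 <- makeSpeciesPanel(seed = 99)
    expect_identical(
        vapply(panel, function(p) p@baselineRate, numeric(1)),
        vapply(panel2, function(p) p@baselineRate, numeric(1)))
    # every profile passes its own validity contract
    for (p in panel) expect_true(validObject(p))
})
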