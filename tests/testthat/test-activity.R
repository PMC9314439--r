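test_that("a constant trace yields the forced totals and even splits", {
    ae <- constantTraceAe(1)
    s <- activitySummary(ae)
    expect_equal(s$totalDaily, 1440)
    expect_equal(s$firstHalf, 720)
    expect_equal(s$secondHalf, 720)
    expect_equal(s$dayTotal, 720)
    expect_equal(s$nightTotal, 720)
    expect_equal(s$dayNightRatio, 1)
})

test_that("an all-zero fly flags its ratios instead of erroring", {
    s <- activitySummary(constantTraceAe(0))
    expect_equal(s$totalDaily, 0)
    expect_true(is.nan(s$dayNightRatio))
    expect_true(is.nan(s$halfRatio))
    # zero denominator with positive numerator is flagged infinite:
    # active only while the lights are on (rows start at 08:00)
    day <- rep(c(rep(1L, 720), rep(0L, 720)), 3)
    s2 <- activitySummary(makeAe(matrix(day, ncol = 1)))
    expect_true(is.infinite(s2$dayNightRatio))
})

test_that("totals agree with a naive per-day loop oracle", {
    set.seed(23)
    cts <- matrix(rpois(3 * 1440 * 4, 1.3), ncol = 4)
    ae <- makeAe(cts)
    s <- activitySummary(ae)
    for (j in 1:4) {
        perDay <- vapply(1:3, function(d)
            sum(cts[(d - 1) * 1440 + 1:1440, j]), numeric(1))
        expect_equal(s$totalDaily[j], mean(perDay))
    }
    # exact conservation identities per fly
    expect_equal(s$totalDaily, s$firstHalf + s$secondHalf)
    expect_equal(s$totalDaily, s$dayTotal + s$nightTotal)
})

test_that("profiles bin correctly and conserve the daily total", {
    ae <- constantTraceAe(2)
    prof <- activityProfile(ae)
    expect_equal(nrow(prof), 48L)
    expect_equal(prof$meanCount, rep(60, 48))
    expect_equal(prof$sem, rep(0, 48))   # single fly: SEM 0 by convention
    set.seed(31)
    ae2 <- makeAe(matrix(rpois(3 * 1440 * 5, 1), ncol = 5))
    prof2 <- activityProfile(ae2)
    s2 <- activitySummary(ae2)
    expect_equal(sum(prof2$meanCount), mean(s2$totalDaily),
        tolerance = 1e-9)
    expect_error(activityProfile(ae, binMinutes = 7), "config error")
})

test_that("window membership forces activity into the right splits", {
    # active only 09:00-10:00: all activity in firstHalf and dayTotal
    v <- integer(1440); v[541:600] <- 3L
    ae <- makeAe(matrix(rep(v, 3), ncol = 1), startClock = 0)
    s <- activitySummary(ae)
    expect_equal(s$firstHalf, s$totalDaily)
    expect_equal(s$secondHalf, 0)
    expect_equal(s$dayTotal, s$totalDaily)
    # explicit non-complementary windows are refused
    expect_error(splitTotals(ae, c(120, 840), c(120, 900)), "spec error")
    # half-day split equals the summary's columns (two-path equality)
    st <- splitTotals(ae, c(120, 840))
    expect_equal(st$inWindow, s$firstHalf)
    expect_equal(st$outWindow, s$secondHalf)
})

test_that("a morning-peaked species loads the first half of the day", {
    p <- speciesProfile("morning", baselineRate = 0.5,
        morningPeak = c(510, 45, 3), eveningPeak = c(1170, 45, 0))
    ae <- simulateActivity(p, simulationConfig(nFlies = 60, nDays = 3,
        temperaturesC = 23, seed = 17))
    s <- activitySummary(ae)
    expect_gte(mean(s$firstHalf > s$secondHalf), 0.95)
})

test_that("results are invariant to fly order", {
    set.seed(5)
    cts <- matrix(rpois(3 * 1440 * 4, 1), ncol = 4)
    ae <- makeAe(cts)
    perm <- c(3, 1, 4, 2)
    aePerm <- makeAe(cts[, perm])
    s <- activitySummary(ae)
    sPerm <- activitySummary(aePerm)
    expect_equal(sPerm$totalDaily, s$totalDaily[perm])
})

test_that("invalid minutes are excluded and heavy days dropped", {
    v <- rep(1L, 3 * 1440)
    # day 2: 10% of minutes invalid -> whole day dropped
    valid <- rep(TRUE, 3 * 1440)
    valid[1440 + 1:144] <- FALSE
    ae <- makeAe(matrix(v, ncol = 1), valid = valid)
    s <- activitySummary(ae)
    expect_equal(s$totalDaily, 1440)   # mean over the two clean days
    # a lone invalid minute is excluded from sums but the day kept
    valid2 <- rep(TRUE, 3 * 1440); valid2[10] <- FALSE
    s2 <- activitySummary(makeAe(matrix(v, ncol = 1), valid = valid2))
    expect_equal(s2$totalDaily, (3 * 1440 - 1) / 3)
})
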