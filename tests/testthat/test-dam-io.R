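test_that("sub-minute readings are summed into minute bins", {
    f <- tempfile()
    writeMonitorFixture(f, rbind(c(1, 0, 2), c(2, 1, 0)), intervalSec = 30)
    ae <- readDamMonitor(f, testDialect(3), species = "s", temperatureC = 23)
    expect_equal(nrow(ae), 1L)
    expect_equal(as.vector(activityCounts(ae)), c(3, 1, 2))
})

test_that("count totals are conserved by minute binning", {
    set.seed(41)
    raw <- matrix(rpois(240 * 2, 2), ncol = 2)
    f <- tempfile()
    writeMonitorFixture(f, raw, intervalSec = 30)
    ae <- readDamMonitor(f, testDialect(2), species = "s", temperatureC = 20)
    expect_equal(colSums(activityCounts(ae)), colSums(raw),
        ignore_attr = TRUE)
})

test_that("malformed monitor files raise named errors", {
    f <- tempfile()
    writeLines(character(0), f)
    expect_error(readDamMonitor(f, testDialect(2), "s", 23), "empty data")

    writeLines(c("1\t01 Jan 24\t08:00:00\t1\t2\t0",
                 "2\t01 Jan 24\t08:01:00\t1\t4"), f)
    expect_error(readDamMonitor(f, testDialect(2), "s", 23),
        "ragged row at line 2")

    # a gap of one reading names the missing timestamp
    writeMonitorFixture(f, matrix(1:4, ncol = 1))
    lines <- readLines(f)
    writeLines(lines[-2], f)
    expect_error(readDamMonitor(f, testDialect(1), "s", 23),
        "missing timestamp 08:01:00")

    # non-monotone timestamps
    writeLines(c("1\t01 Jan 24\t08:01:00\t1\t1",
                 "2\t01 Jan 24\t08:01:00\t1\t1"), f)
    expect_error(readDamMonitor(f, testDialect(1), "s", 23), "non-monotone")
})

test_that("status flags mark minutes invalid without dropping them", {
    f <- tempfile()
    writeMonitorFixture(f, matrix(c(1, 2, 3), ncol = 1),
        status = c(1, 51, 1))
    ae <- readDamMonitor(f, testDialect(1), species = "s", temperatureC = 23)
    expect_equal(nrow(ae), 3L)
    expect_equal(validMinutes(ae), c(TRUE, FALSE, TRUE))
    expect_equal(as.vector(activityCounts(ae)), c(1, 2, 3))
})

test_that("acclimation dropping removes whole days and re-anchors", {
    set.seed(7)
    ae <- makeAe(matrix(rpois(5 * 1440, 1), ncol = 1))
    out <- dropAcclimation(ae, 2)
    expect_equal(nrow(out), 3 * 1440)
    expect_equal(minuteOfDay(out)[1L], minuteOfDay(ae)[1L])
    expect_equal(SummarizedExperiment::rowData(out)$minuteIndex[1L], 0L)
    # identity at zero and composition a + b
    expect_identical(activityCounts(dropAcclimation(ae, 0)),
        activityCounts(ae))
    expect_equal(
        activityCounts(dropAcclimation(dropAcclimation(ae, 1), 1)),
        activityCounts(dropAcclimation(ae, 2)))
    # an empty remainder is forbidden
    ae2 <- makeAe(matrix(0L, nrow = 2 * 1440, ncol = 1))
    expect_error(dropAcclimation(ae2, 2), "length error")
})

test_that("tidy CSV round trip is the identity and writes are stable", {
    set.seed(11)
    ae <- makeAe(matrix(rpois(1440 * 3, 2), ncol = 3),
        species = "D. simulans", temperatureC = 26)
    f <- tempfile(fileext = ".csv")
    writeActivityCsv(ae, f)
    back <- readActivityCsv(f)
    expect_identical(activityCounts(back), activityCounts(ae))
    expect_equal(flyInfo(back), flyInfo(ae))
    expect_equal(minuteOfDay(back), minuteOfDay(ae))
    # byte-identical second write
    f2 <- tempfile(fileext = ".csv")
    writeActivityCsv(ae, f2)
    expect_identical(readBin(f, "raw", file.size(f)),
        readBin(f2, "raw", file.size(f2)))
    # missing count column is a format error
    df <- utils::read.csv(f)
    utils::write.csv(df[, setdiff(names(df), "count")], f,
        row.names = FALSE)
    expect_error(readActivityCsv(f), "missing column.*count")
})

test_that("dead-fly filter drops only flies silent over the final day", {
    cts <- cbind(rep(1L, 2 * 1440),
                 c(rep(1L, 1440), rep(0L, 1440)))
    ae <- makeAe(cts)
    out <- filterDeadFlies(ae)
    expect_equal(ncol(out), 1L)
    expect_equal(flyInfo(out)$flyId, "f1")
})
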