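# Programmatic fixtures shared across test files.

# Write a DAM-style monitor file: 4 leading columns (index, date, time,
# status) then one count column per channel.
writeMonitorFixture <- function(path, counts, startTime = "08:00:00",
                                intervalSec = 60, status = NULL) {
    counts <- as.matrix(counts)
    n <- nrow(counts)
    if (is.null(status)) status <- rep(1, n)
    t0 <- as.numeric(substr(startTime, 1, 2)) * 3600 +
        as.numeric(substr(startTime, 4, 5)) * 60 +
        as.numeric(substr(startTime, 7, 8))
    secs <- (t0 + (seq_len(n) - 1) * intervalSec) %% 86400
    times <- sprintf("%02d:%02d:%02d", secs %/% 3600,
        (secs %% 3600) %/% 60, secs %% 60)
    rows <- vapply(seq_len(n), function(i)
        paste(c(i, "01 Jan 24", times[i], status[i], counts[i, ]),
            collapse = "\t"), character(1))
    writeLines(rows, path)
    path
}

# A minimal whole-day experiment from an explicit counts matrix.
makeAe <- function(counts, species = "test", temperatureC = 23,
                   startClock = 480, valid = NULL) {
    counts <- as.matrix(counts)
    ActivityExperiment(counts,
        flyId = paste0("f", seq_len(ncol(counts))),
        species = species, temperatureC = temperatureC,
        startClock = startClock, valid = valid)
}

# One-fly experiment with a constant count at every minute.
constantTraceAe <- function(value, nDays = 3, ...) {
    makeAe(matrix(as.integer(value), nrow = nDays * 1440, ncol = 1), ...)
}

testDialect <- function(nChannels) damDialect(nChannels = nChannels)
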