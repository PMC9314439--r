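#' Detect sleep bouts in a per-minute count series
#'
#' Sleep is scored by the standard immobility rule: a maximal run of
#' consecutive zero-count minutes of length >= `minBout` (default 5) is one
#' sleep bout, and every minute inside it is a sleep minute. Zero-runs
#' shorter than `minBout` contribute no sleep. Runs touching the start or
#' end of the recording are scored if long enough (no censoring
#' correction). A minute flagged instrument-invalid breaks a run: immobility
#' cannot be asserted without a valid reading.
#'
#' The five-minute rule was established for *D. melanogaster*; whether it
#' suits much less active species is an open question, so `minBout` is a
#' first-class parameter.
#'
#' @param counts non-negative integer vector of per-minute counts.
#' @param minBout minimum run length in minutes (>= 1, default 5).
#' @param valid logical vector of instrument validity (default all valid).
#' @return data.frame with one row per bout: `startIndex` (0-based offset
#'   into `counts`) and `length` (minutes).
#' @examples
#' detectSleepBouts(c(3, 0, 0, 0, 0, 0, 2, 0, 0, 0))
#' @export
detectSleepBouts <- function(counts, minBout = 5, valid = NULL) {
    if (any(counts < 0)) stop("data error: negative counts")
    if (minBout < 1) stop("minBout must be >= 1")
    if (is.null(valid)) valid <- rep(TRUE, length(counts))
    immobile <- counts == 0 & valid
    r <- rle(immobile)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minBout
    data.frame(startIndex = starts[keep] - 1L,
        length = as.integer(r$lengths[keep]))
}

#' Sleep bouts for every fly of an experiment
#'
#' @param x an [ActivityExperiment-class].
#' @param minBout minimum bout length in minutes.
#' @return data.frame: `flyId`, `startIndex` (the row's `minuteIndex`),
#'   `length`.
#' @seealso [detectSleepBouts()] for the scoring rule.
#' @export
sleepBouts <- function(x, minBout = 5) {
    stopifnot(is(x, "ActivityExperiment"))
    cts <- activityCounts(x)
    valid <- validMinutes(x)
    mi0 <- rowData(x)$minuteIndex[1L]
    res <- lapply(seq_len(ncol(cts)), function(j) {
        b <- detectSleepBouts(cts[, j], minBout, valid)
        if (nrow(b) == 0L) return(NULL)
        data.frame(flyId = flyInfo(x)$flyId[j],
            startIndex = b$startIndex + mi0, length = b$length)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(flyId = character(0), startIndex = integer(0),
            length = integer(0))
    out
}

#' Per-fly daily sleep summary
#'
#' Scores sleep on the undivided multi-day series, then attributes each
#' sleep minute to daytime or nighttime by that minute's clock time, so a
#' bout spanning a light transition (or midnight) is split minute-wise for
#' the day/night totals but counted as a single event. Totals are averaged
#' over the recorded days; `nBouts` is the total bout count divided by the
#' number of days (it can be fractional), and `meanBoutLength` is total
#' sleep over the whole window divided by the total bout count, so
#' `nBouts * meanBoutLength == totalSleep` on the undivided window. A fly
#' with no sleep gets `meanBoutLength = NaN` as a flagged value.
#'
#' @param x an [ActivityExperiment-class] holding whole days.
#' @param minBout minimum bout length in minutes (default 5).
#' @return data.frame per fly: `flyId`, `species`, `temperatureC`,
#'   `totalSleep`, `daySleep`, `nightSleep` (min/day), `nBouts` (bouts/day),
#'   `meanBoutLength` (min).
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 3, nDays = 3, temperaturesC = 23))
#' sleepSummary(ae)
#' @export
sleepSummary <- function(x, minBout = 5) {
    stopifnot(is(x, "ActivityExperiment"))
    .checkWholeDays(x)
    nd <- nrow(x) / 1440
    S <- .sleepIndicator(x, minBout)
    inDay <- isLight(lightSchedule(x), minuteOfDay(x))
    cd <- flyInfo(x)
    totalMin <- colSums(S)
    nB <- vapply(seq_len(ncol(S)), function(j) {
        b <- detectSleepBouts(activityCounts(x)[, j], minBout,
            validMinutes(x))
        nrow(b)
    }, integer(1))
    data.frame(flyId = cd$flyId, species = cd$species,
        temperatureC = cd$temperatureC,
        totalSleep = totalMin / nd,
        daySleep = colSums(S * inDay) / nd,
        nightSleep = colSums(S * !inDay) / nd,
        nBouts = nB / nd,
        meanBoutLength = totalMin / nB,
        row.names = NULL)
}

#' Group sleep profile in clock-time bins
#'
#' Mean sleep minutes per clock-time bin (0 to `binMinutes` per bin),
#' averaged across days within fly and reported with across-fly mean and
#' SEM per species x temperature group; the complement of the activity
#' profile in the sense that no bin can exceed its width.
#'
#' @param x an [ActivityExperiment-class] holding whole days.
#' @param binMinutes bin width; must divide 1440 (default 30).
#' @param minBout minimum bout length in minutes (default 5).
#' @return data.frame: `species`, `temperatureC`, `binStart`, `meanSleep`,
#'   `sem`, `nFlies`.
#' @export
sleepProfile <- function(x, binMinutes = 30, minBout = 5) {
    S <- .sleepIndicator(x, minBout)
    perFly <- .perFlyBins(x, binMinutes, what = "sleep", sleepMat = S)
    .groupProfile(x, perFly, binMinutes, valueName = "meanSleep")
}

# minutes x flies 0/1 matrix of scored sleep.
.sleepIndicator <- function(x, minBout) {
    cts <- activityCounts(x)
    valid <- validMinutes(x)
    S <- matrix(0L, nrow = nrow(cts), ncol = ncol(cts))
    for (j in seq_len(ncol(cts))) {
        b <- detectSleepBouts(cts[, j], minBout, valid)
        for (k in seq_len(nrow(b)))
            S[b$startIndex[k] + seq_len(b$length[k]), j] <- 1L
    }
    S
}
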