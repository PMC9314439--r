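#' Per-fly daily activity summary
#'
#' Computes, per fly, the mean total daily beam-break count over the
#' recorded whole days plus the standard clock-anchored splits: first
#' (02:00-14:00) versus second (14:00-02:00) half of the day, and daytime
#' (lights-on) versus nighttime (lights-off). All aggregates are computed on
#' `minuteOfDay` (circular clock time) so windows crossing midnight on
#' linear time are exact partitions; per fly,
#' `totalDaily == firstHalf + secondHalf == dayTotal + nightTotal` holds
#' exactly.
#'
#' Instrument-invalid minutes are excluded from all sums; a recorded day
#' with more than 5\% invalid minutes is dropped entirely and the remaining
#' days averaged.
#'
#' Ratios with zero denominators are returned as flagged values rather than
#' raising: `Inf` when only the denominator is zero, `NaN` when both sides
#' are zero.
#'
#' @param x an [ActivityExperiment-class] holding whole days
#'   (post-acclimation).
#' @param halfWindow start/end of the "first half" clock window in minutes
#'   after midnight (default `c(120, 840)`, i.e. 02:00-14:00).
#' @return data.frame with one row per fly: `flyId`, `species`,
#'   `temperatureC`, `totalDaily`, `firstHalf`, `secondHalf`, `dayTotal`,
#'   `nightTotal`, `dayNightRatio`, `halfRatio`.
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 3, nDays = 3, temperaturesC = 23))
#' activitySummary(ae)
#' @export
activitySummary <- function(x, halfWindow = c(120, 840)) {
    stopifnot(is(x, "ActivityExperiment"))
    .checkWholeDays(x)
    mod <- minuteOfDay(x)
    light <- lightSchedule(x)
    inFirst <- .inCircularWindow(mod, halfWindow[1L], halfWindow[2L])
    inDay <- isLight(light, mod)
    keepDays <- .retainedDays(x)
    cd <- flyInfo(x)
    out <- data.frame(flyId = cd$flyId, species = cd$species,
        temperatureC = cd$temperatureC,
        totalDaily = .dailyMean(x, rep(TRUE, nrow(x)), keepDays),
        firstHalf = .dailyMean(x, inFirst, keepDays),
        secondHalf = .dailyMean(x, !inFirst, keepDays),
        dayTotal = .dailyMean(x, inDay, keepDays),
        nightTotal = .dailyMean(x, !inDay, keepDays),
        row.names = NULL)
    activityRatios(out)
}

#' Recompute activity ratios from split totals
#'
#' `dayNightRatio = dayTotal / nightTotal`; `halfRatio = firstHalf /
#' secondHalf`. Zero denominators give `Inf` (numerator positive) or `NaN`
#' (both zero) as flagged values.
#'
#' @param summary data.frame with columns `dayTotal`, `nightTotal`,
#'   `firstHalf`, `secondHalf` (as produced by [activitySummary()]).
#' @return `summary` with `dayNightRatio` and `halfRatio` columns
#'   (re)computed.
#' @export
activityRatios <- function(summary) {
    summary$dayNightRatio <- summary$dayTotal / summary$nightTotal
    summary$halfRatio <- summary$firstHalf / summary$secondHalf
    summary
}

#' Per-fly totals for a complementary pair of clock windows
#'
#' Sums counts per fly per day inside a circular clock window and its
#' complement, then averages over days. The two windows must partition the
#' 1440-minute day: supply either just `windowA` (complement implied) or
#' both windows, in which case they are checked for complementarity.
#'
#' @param x an [ActivityExperiment-class] holding whole days.
#' @param windowA `c(start, end)` in minutes after midnight; the window is
#'   `[start, end)` on the circular clock (it may cross midnight).
#' @param windowB optional explicit complement; an error is raised if the
#'   two windows do not partition the day.
#' @return data.frame: `flyId`, `inWindow`, `outWindow` (counts/day).
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 2, nDays = 3, temperaturesC = 23))
#' splitTotals(ae, c(480, 1200))   # lights-on vs lights-off
#' @export
splitTotals <- function(x, windowA, windowB = NULL) {
    stopifnot(is(x, "ActivityExperiment"))
    .checkWholeDays(x)
    mod <- minuteOfDay(x)
    inA <- .inCircularWindow(mod, windowA[1L], windowA[2L])
    if (!is.null(windowB)) {
        inB <- .inCircularWindow(mod, windowB[1L], windowB[2L])
        if (any(inA == inB))
            stop("spec error: windows are not complementary")
    }
    keepDays <- .retainedDays(x)
    data.frame(flyId = flyInfo(x)$flyId,
        inWindow = .dailyMean(x, inA, keepDays),
        outWindow = .dailyMean(x, !inA, keepDays), row.names = NULL)
}

#' Group activity profile in clock-time bins
#'
#' Sums counts within each `minuteOfDay` bin per fly per day, averages the
#' bins across days within fly, then reports the across-fly mean and SEM per
#' species x temperature group. With the default 30-minute bins the profile
#' has exactly 48 bins and the bin means of a group sum to the group's mean
#' total daily activity.
#'
#' @param x an [ActivityExperiment-class] holding whole days.
#' @param binMinutes bin width; must divide 1440 (default 30).
#' @return data.frame: `species`, `temperatureC`, `binStart` (minute of
#'   day), `meanCount`, `sem`, `nFlies`. SEM is across flies; a single fly
#'   gives SEM 0 by convention.
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 4, nDays = 3, temperaturesC = 23))
#' head(activityProfile(ae))
#' @export
activityProfile <- function(x, binMinutes = 30) {
    perFly <- .perFlyBins(x, binMinutes, what = "counts")
    .groupProfile(x, perFly, binMinutes, valueName = "meanCount")
}

# ---- shared internals ----

.checkWholeDays <- function(x) {
    if (nrow(x) %% 1440L != 0L)
        stop("length error: partial day present (", nrow(x),
            " minutes is not a multiple of 1440)")
    invisible(TRUE)
}

# [start, end) on the circular 1440-min clock; end may be < start.
.inCircularWindow <- function(mod, start, end) {
    if (start < end) mod >= start & mod < end else mod >= start | mod < end
}

# Days (1-based) retained under the >5% invalid-minute drop rule.
.retainedDays <- function(x) {
    day <- rowData(x)$minuteIndex %/% 1440L
    invalidFrac <- tapply(!validMinutes(x), day, mean)
    which(invalidFrac <= 0.05)
}

# Per-fly counts/day inside a row mask, excluding invalid minutes and
# dropped days.
.dailyMean <- function(x, rowMask, keepDays) {
    if (length(keepDays) == 0L)
        stop("length error: no day passes the invalid-minute threshold")
    day <- rowData(x)$minuteIndex %/% 1440L + 1L
    use <- rowMask & validMinutes(x) & day %in% keepDays
    colSums(activityCounts(x)[use, , drop = FALSE]) / length(keepDays)
}

# Per-fly day-averaged bin values: matrix nBins x nFlies.
# what = "counts" bins beam breaks; "sleep" bins sleep minutes given an
# indicator matrix in attr.
.perFlyBins <- function(x, binMinutes, what = "counts", sleepMat = NULL) {
    stopifnot(is(x, "ActivityExperiment"))
    .checkWholeDays(x)
    if (1440 %% binMinutes != 0)
        stop("config error: binMinutes (", binMinutes,
            ") does not divide 1440")
    keepDays <- .retainedDays(x)
    if (length(keepDays) == 0L)
        stop("length error: no day passes the invalid-minute threshold")
    day <- rowData(x)$minuteIndex %/% 1440L + 1L
    bin <- minuteOfDay(x) %/% binMinutes
    mat <- if (what == "counts") activityCounts(x) * validMinutes(x)
           else sleepMat
    use <- day %in% keepDays
    g <- bin[use]
    summed <- rowsum(mat[use, , drop = FALSE], g)   # bins x flies, all days
    summed[order(as.integer(rownames(summed))), , drop = FALSE] /
        length(keepDays)
}

.groupProfile <- function(x, perFly, binMinutes, valueName) {
    cd <- flyInfo(x)
    grp <- interaction(cd$species, cd$temperatureC, drop = TRUE)
    binStart <- as.integer(rownames(perFly)) * binMinutes
    res <- lapply(levels(grp), function(g) {
        cols <- which(grp == g)
        sub <- perFly[, cols, drop = FALSE]
        mean <- rowMeans(sub)
        sem <- if (ncol(sub) > 1L)
            apply(sub, 1L, stats::sd) / sqrt(ncol(sub)) else rep(0, nrow(sub))
        df <- data.frame(species = cd$species[cols[1L]],
            temperatureC = cd$temperatureC[cols[1L]],
            binStart = binStart, value = mean, sem = sem,
            nFlies = ncol(sub), row.names = NULL)
        names(df)[names(df) == "value"] <- valueName
        df
    })
    do.call(rbind, res)
}
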