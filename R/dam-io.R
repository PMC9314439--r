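#' Read a Drosophila Activity Monitor text file
#'
#' Parses a tab-delimited DAM-style monitor file into an
#' [ActivityExperiment-class]. Readings recorded at sub-minute intervals are
#' summed into one-minute bins; readings at multi-minute intervals are
#' rejected unless the interval is exactly one minute times an integer, in
#' which case each reading is taken to cover its whole bin and is placed on
#' the minute grid (the paper-standard interval is one minute). Channel `i`
#' maps to `flyId` `"<idPrefix><i>"`, a stable, documented mapping.
#'
#' The per-row status flag (when the dialect declares one) is recorded as a
#' per-minute validity mark: a minute is marked invalid when any contributing
#' reading has status != 1. Invalid minutes are retained in the container and
#' excluded later by the analysis modules, because the flag signals hardware
#' error, not fly behavior.
#'
#' @param path path to the monitor file.
#' @param dialect a [MonitorDialect-class]; default [damDialect()].
#' @param species,temperatureC experiment metadata applied to every channel.
#' @param startClock clock time in minutes after midnight of the first
#'   reading; when `NULL` it is taken from the file's time column.
#' @param light a [LightCycle-class].
#' @param idPrefix prefix for channel-derived fly ids.
#'
#' @return An [ActivityExperiment-class] with one row per minute and one
#'   column per channel.
#' @section Errors:
#' Ragged rows raise a parse error naming the line; non-monotone or gapped
#' timestamps raise an integrity error naming the offending timestamp; an
#' empty data section is an integrity error, never an empty table.
#' @examples
#' f <- tempfile()
#' writeLines(c("1\t01 Jan 24\t08:00:00\t1\t2\t0\t1",
#'              "2\t01 Jan 24\t08:01:00\t1\t0\t3\t1"), f)
#' ae <- readDamMonitor(f, damDialect(nChannels = 3),
#'     species = "D. virilis", temperatureC = 20)
#' activityCounts(ae)
#' @export
readDamMonitor <- function(path, dialect = damDialect(), species,
                           temperatureC, startClock = NULL,
                           light = lightCycle(), idPrefix = NULL) {
    if (!file.exists(path)) stop("monitor file not found: ", path)
    validObject(dialect)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("integrity error: monitor file has an empty data section")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    needCols <- max(dialect@countOffset + dialect@nChannels - 1L,
        dialect@dateCol, dialect@timeCol,
        if (!is.na(dialect@statusCol)) dialect@statusCol else 0L)
    if (length(unique(nf)) > 1L)
        stop("parse error: ragged row at line ",
            which(nf != nf[1L])[1L], " (", nf[which(nf != nf[1L])[1L]],
            " fields, expected ", nf[1L], ")")
    if (nf[1L] < needCols)
        stop("config error: dialect declares column ", needCols,
            " but rows have only ", nf[1L], " fields")
    mat <- do.call(rbind, fields)
    times <- mat[, dialect@timeCol]
    secOfDay <- .parseTimeOfDay(times)
    # Seconds since first reading, letting the clock roll over midnight.
    rolls <- cumsum(c(0, diff(secOfDay) < 0))
    relSec <- secOfDay - secOfDay[1L] + rolls * 86400
    if (length(relSec) > 1L) {
        dstep <- diff(relSec)
        if (any(dstep <= 0))
            stop("integrity error: non-monotone timestamp at line ",
                which(dstep <= 0)[1L] + 1L, " (", times[which(dstep <= 0)[1L] + 1L],
                ")")
        interval <- min(dstep)
        gap <- which(dstep != interval)
        if (length(gap)) {
            missSec <- secOfDay[gap[1L]] + interval
            stop("integrity error: reading gap after line ", gap[1L],
                "; missing timestamp ", .secLabel(missSec %% 86400))
        }
    } else {
        interval <- 60
    }
    if (!(60 %% interval == 0 || interval %% 60 == 0))
        stop("config error: reading interval of ", interval,
            " s neither divides nor is a multiple of 60 s")
    if (interval > 60)
        stop("config error: reading interval of ", interval,
            " s exceeds the 1-min analysis grid; re-record at <= 60 s")

    cts <- mat[, seq(dialect@countOffset, length.out = dialect@nChannels),
        drop = FALSE]
    suppressWarnings(storage.mode(cts) <- "numeric")
    if (anyNA(cts))
        stop("parse error: non-numeric count at line ",
            which(rowSums(is.na(cts)) > 0)[1L])
    if (!is.na(dialect@statusCol)) {
        status <- suppressWarnings(as.numeric(mat[, dialect@statusCol]))
        rowValid <- !is.na(status) & status == 1
    } else {
        rowValid <- rep(TRUE, nrow(mat))
    }

    minuteBin <- relSec %/% 60
    binIdx <- minuteBin - minuteBin[1L] + 1L
    nMin <- max(binIdx)
    counts <- matrix(0L, nrow = nMin, ncol = dialect@nChannels)
    for (j in seq_len(dialect@nChannels))
        counts[, j] <- as.integer(rowsum(cts[, j], binIdx)[, 1L])
    valid <- as.logical(tapply(rowValid, binIdx, all))

    if (is.null(startClock)) startClock <- (secOfDay[1L] %/% 60) %% 1440
    if (is.null(idPrefix))
        idPrefix <- paste0(tools::file_path_sans_ext(basename(path)), "_ch")
    ActivityExperiment(counts,
        flyId = paste0(idPrefix, seq_len(dialect@nChannels)),
        species = species, temperatureC = temperatureC,
        startClock = startClock, light = light, valid = valid)
}

.parseTimeOfDay <- function(times) {
    parts <- strsplit(times, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
        stop("parse error: malformed time '", times[bad[1L]], "' at line ",
            bad[1L])
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3L,
        byrow = TRUE)
    if (anyNA(m))
        stop("parse error: malformed time at line ",
            which(rowSums(is.na(m)) > 0)[1L])
    m[, 1L] * 3600 + m[, 2L] * 60 + m[, 3L]
}

.secLabel <- function(s)
    sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)

#' Drop the acclimation period
#'
#' Removes the first `nDays` whole days per fly and re-anchors `minuteIndex`
#' to zero; `minuteOfDay` of retained minutes is unchanged. The standard
#' protocol records for five days and drops the first two, leaving a
#' three-day analysis window.
#'
#' @param x an [ActivityExperiment-class] covering more than `nDays` whole
#'   days.
#' @param nDays number of leading days to drop (default 2).
#' @return The truncated [ActivityExperiment-class].
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 2, nDays = 5, temperaturesC = 23))
#' nDays(dropAcclimation(ae, 2))
#' @export
dropAcclimation <- function(x, nDays = 2) {
    stopifnot(is(x, "ActivityExperiment"))
    nDays <- as.integer(nDays)
    if (nDays < 0) stop("nDays must be >= 0")
    if (nDays == 0L) return(x)
    drop <- nDays * 1440L
    if (nrow(x) <= drop)
        stop("length error: table covers ", nrow(x) / 1440,
            " days; cannot drop ", nDays, " and keep a non-empty window")
    keep <- seq.int(drop + 1L, nrow(x))
    out <- x[keep, ]
    rowData(out)$minuteIndex <- seq_along(keep) - 1L
    out
}

#' Tidy CSV round trip for activity tables
#'
#' `writeActivityCsv()` writes the long (tidy) representation with header
#' `flyId,species,temperatureC,minuteIndex,minuteOfDay,count,valid`;
#' `readActivityCsv()` reads it back into an identical
#' [ActivityExperiment-class]. Files are UTF-8 with a mandatory header row
#' and '.' decimal separator; writing is deterministic (a re-write of the
#' same table is byte-identical).
#'
#' @param x an [ActivityExperiment-class].
#' @param path CSV path.
#' @param light a [LightCycle-class] attached on read.
#' @return `readActivityCsv()` returns an [ActivityExperiment-class];
#'   `writeActivityCsv()` returns `path` invisibly.
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 1, nDays = 1, temperaturesC = 23))
#' f <- tempfile(fileext = ".csv")
#' writeActivityCsv(ae, f)
#' ae2 <- readActivityCsv(f)
#' identical(activityCounts(ae), activityCounts(ae2))
#' @export
writeActivityCsv <- function(x, path) {
    stopifnot(is(x, "ActivityExperiment"))
    cd <- flyInfo(x)
    rd <- rowData(x)
    cts <- activityCounts(x)
    n <- nrow(cts)
    df <- data.frame(
        flyId = rep(cd$flyId, each = n),
        species = rep(cd$species, each = n),
        temperatureC = rep(cd$temperatureC, each = n),
        minuteIndex = rep(rd$minuteIndex, times = ncol(cts)),
        minuteOfDay = rep(rd$minuteOfDay, times = ncol(cts)),
        count = as.vector(cts),
        valid = rep(rd$valid, times = ncol(cts)))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
        fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeActivityCsv
#' @export
readActivityCsv <- function(path, light = lightCycle()) {
    if (!file.exists(path)) stop("CSV not found: ", path)
    df <- utils::read.csv(path, fileEncoding = "UTF-8")
    need <- c("flyId", "species", "temperatureC", "minuteIndex",
        "minuteOfDay", "count")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error: CSV is missing column(s): ",
            paste(miss, collapse = ", "))
    if (!"valid" %in% names(df)) df$valid <- TRUE
    ids <- unique(df$flyId)
    # All flies must share one minute grid to form a rectangular container.
    first <- df[df$flyId == ids[1L], ]
    first <- first[order(first$minuteIndex), ]
    counts <- matrix(0L, nrow = nrow(first), ncol = length(ids))
    meta <- data.frame(flyId = ids, species = NA_character_,
        temperatureC = NA_real_)
    for (k in seq_along(ids)) {
        sub <- df[df$flyId == ids[k], ]
        sub <- sub[order(sub$minuteIndex), ]
        if (nrow(sub) != nrow(first) ||
            any(sub$minuteIndex != first$minuteIndex))
            stop("format error: flies do not share one minute grid")
        counts[, k] <- as.integer(sub$count)
        meta$species[k] <- as.character(sub$species[1L])
        meta$temperatureC[k] <- sub$temperatureC[1L]
    }
    ActivityExperiment(counts, flyId = ids, species = meta$species,
        temperatureC = meta$temperatureC,
        startClock = (first$minuteOfDay[1L] - first$minuteIndex[1L]) %% 1440,
        light = light, valid = first$valid)
}

#' Drop flies with a silent final day
#'
#' Optional dead-fly filter: removes flies whose counts are all zero over
#' their entire final recorded day. Off by default in the pipeline; whether
#' moribund flies should be excluded from activity averages is a protocol
#' choice, so the filter is exposed but never implied.
#'
#' @param x an [ActivityExperiment-class] covering at least one whole day.
#' @return The filtered [ActivityExperiment-class].
#' @export
filterDeadFlies <- function(x) {
    stopifnot(is(x, "ActivityExperiment"))
    n <- nrow(x)
    if (n < 1440L) stop("length error: need at least one whole day")
    lastDay <- seq.int(n - 1439L, n)
    alive <- colSums(activityCounts(x)[lastDay, , drop = FALSE]) > 0
    x[, alive]
}
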