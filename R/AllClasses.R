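#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

#' Light/dark schedule of a recording
#'
#' A 24-h light cycle anchored to clock time. The default reproduces a
#' standard 12-h/12-h LD incubator schedule with lights on at 08:00 and off
#' at 20:00.
#'
#' @slot lightsOn minutes after midnight at which lights switch on.
#' @slot lightsOff minutes after midnight at which lights switch off.
#'
#' @export
setClass("LightCycle",
    representation(lightsOn = "numeric", lightsOff = "numeric"))

setValidity("LightCycle", function(object) {
    on <- object@lightsOn; off <- object@lightsOff
    if (length(on) != 1L || length(off) != 1L)
        return("lightsOn and lightsOff must be single values")
    if (is.na(on) || is.na(off) || on != round(on) || off != round(off))
        return("lightsOn and lightsOff must be whole minutes")
    if (!(0 <= on && on < off && off < 1440))
        return("need 0 <= lightsOn < lightsOff < 1440")
    TRUE
})

#' @param lightsOn,lightsOff clock times in minutes after midnight.
#' @return `lightCycle()` returns a [LightCycle-class] object.
#' @examples
#' lightCycle()            # 08:00 on, 20:00 off
#' lightCycle(360, 1080)   # 06:00 on, 18:00 off
#' @rdname LightCycle-class
#' @export
lightCycle <- function(lightsOn = 480, lightsOff = 1200) {
    new("LightCycle", lightsOn = as.numeric(lightsOn),
        lightsOff = as.numeric(lightsOff))
}

#' @param object,x a `LightCycle`.
#' @param minuteOfDay integer vector of minutes 0-1439.
#' @return `isLight()` returns a logical vector: is each minute inside the
#'   lights-on window?
#' @rdname LightCycle-class
#' @export
isLight <- function(x, minuteOfDay) {
    stopifnot(is(x, "LightCycle"))
    minuteOfDay >= x@lightsOn & minuteOfDay < x@lightsOff
}

setMethod("show", "LightCycle", function(object) {
    cat(sprintf("LightCycle: lights on %s, off %s (12-h grid of 1440 min)\n",
        .clockLabel(object@lightsOn), .clockLabel(object@lightsOff)))
})

.clockLabel <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Column layout of a Drosophila Activity Monitor text file
#'
#' Describes where the timestamp, status flag and per-channel count columns
#' sit in a tab-delimited monitor file. The default layout has four leading
#' columns (record index, date, time, status) followed by 32 channel counts;
#' every offset is configurable because monitor file versions differ.
#'
#' @slot nChannels number of count channels (one fly per channel).
#' @slot countOffset 1-based index of the first count column.
#' @slot dateCol,timeCol 1-based indices of the date and time columns.
#' @slot statusCol 1-based index of the per-row status flag, or `NA_integer_`
#'   when the file has none. Rows whose status differs from 1 are retained
#'   but marked invalid; analysis functions exclude marked minutes.
#'
#' @export
setClass("MonitorDialect",
    representation(nChannels = "integer", countOffset = "integer",
        dateCol = "integer", timeCol = "integer", statusCol = "integer"))

setValidity("MonitorDialect", function(object) {
    if (object@nChannels < 1L) return("nChannels must be >= 1")
    meta <- c(object@dateCol, object@timeCol,
        if (!is.na(object@statusCol)) object@statusCol)
    counts <- seq(object@countOffset, length.out = object@nChannels)
    if (any(meta %in% counts) || anyDuplicated(meta))
        return("declared columns overlap")
    TRUE
})

#' @param nChannels,countOffset,dateCol,timeCol,statusCol see slots.
#' @return `damDialect()` returns a [MonitorDialect-class] object.
#' @examples
#' damDialect()                       # 32-channel default
#' damDialect(nChannels = 3, countOffset = 5)
#' @rdname MonitorDialect-class
#' @export
damDialect <- function(nChannels = 32L, countOffset = 5L, dateCol = 2L,
                       timeCol = 3L, statusCol = 4L) {
    new("MonitorDialect", nChannels = as.integer(nChannels),
        countOffset = as.integer(countOffset), dateCol = as.integer(dateCol),
        timeCol = as.integer(timeCol),
        statusCol = if (is.null(statusCol)) NA_integer_ else as.integer(statusCol))
}

#' Per-minute locomotor activity container
#'
#' `ActivityExperiment` extends [SummarizedExperiment] to hold beam-break
#' counts on a gapless one-minute grid: rows are minutes, columns are flies.
#' `rowData` carries `minuteIndex` (minutes since recording start, 0-based),
#' `minuteOfDay` (0-1439, anchored to the recording start clock) and `valid`
#' (FALSE for minutes flagged by the instrument status column); `colData`
#' carries `flyId`, `species` and `temperatureC`. The light schedule lives in
#' `metadata(x)$light`.
#'
#' @seealso [readDamMonitor()], [simulateActivity()], [activitySummary()],
#'   [sleepSummary()]
#' @export
setClass("ActivityExperiment", contains = "SummarizedExperiment")

setValidity("ActivityExperiment", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
        return("counts must be finite non-negative integers")
    rd <- rowData(object)
    need <- c("minuteIndex", "minuteOfDay", "valid")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    mi <- rd$minuteIndex
    if (nrow(object) > 1L && any(diff(mi) != 1L))
        return("minuteIndex must be a gapless 1-min grid")
    mod <- rd$minuteOfDay
    if (any(mod < 0 | mod > 1439))
        return("minuteOfDay must lie in 0..1439")
    if (nrow(object) > 0L &&
        any(mod != (mod[1L] + mi - mi[1L]) %% 1440))
        return("minuteOfDay inconsistent with minuteIndex")
    cd <- colData(object)
    needc <- c("flyId", "species", "temperatureC")
    if (!all(needc %in% colnames(cd)))
        return(paste("colData must contain:", paste(needc, collapse = ", ")))
    if (anyDuplicated(cd$flyId)) return("flyId must be unique")
    lt <- metadata(object)$light
    if (!is(lt, "LightCycle")) return("metadata(x)$light must be a LightCycle")
    TRUE
})

#' Construct an ActivityExperiment
#'
#' @param counts integer matrix, minutes x flies.
#' @param flyId character vector of unique fly identifiers (one per column).
#' @param species species label(s), recycled across flies.
#' @param temperatureC experimental temperature(s) in degrees Celsius,
#'   recycled across flies.
#' @param startClock clock time (minutes after midnight) of the first row.
#' @param light a [LightCycle-class]; default 08:00-20:00.
#' @param valid logical vector marking instrument-valid minutes (rows);
#'   default all `TRUE`.
#'
#' @return An [ActivityExperiment-class].
#' @examples
#' cts <- matrix(rpois(1440 * 2, 1), ncol = 2)
#' ae <- ActivityExperiment(cts, flyId = c("f1", "f2"),
#'     species = "D. melanogaster", temperatureC = 23)
#' ae
#' @export
ActivityExperiment <- function(counts, flyId, species, temperatureC,
                               startClock = 480, light = lightCycle(),
                               valid = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    n <- nrow(counts)
    if (is.null(valid)) valid <- rep(TRUE, n)
    rd <- DataFrame(minuteIndex = seq_len(n) - 1L,
        minuteOfDay = as.integer((startClock + seq_len(n) - 1L) %% 1440),
        valid = as.logical(valid))
    cd <- DataFrame(flyId = as.character(flyId),
        species = rep_len(as.character(species), ncol(counts)),
        temperatureC = rep_len(as.numeric(temperatureC), ncol(counts)))
    se <- SummarizedExperiment(assays = list(counts = counts),
        rowData = rd, colData = cd,
        metadata = list(light = light, startClock = as.integer(startClock)))
    colnames(se) <- cd$flyId
    new("ActivityExperiment", se)
}

setMethod("show", "ActivityExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf("ActivityExperiment: %d minutes (%.2f days) x %d flies\n",
        nrow(object), nrow(object) / 1440, ncol(object)))
    cat(sprintf("  species: %s\n",
        paste(unique(cd$species), collapse = ", ")))
    cat(sprintf("  temperatures (C): %s\n",
        paste(sort(unique(cd$temperatureC)), collapse = ", ")))
    show(metadata(object)$light)
    nInv <- sum(!rowData(object)$valid)
    if (nInv > 0) cat(sprintf("  %d instrument-invalid minutes\n", nInv))
})

#' Accessors for ActivityExperiment
#'
#' `activityCounts()` returns the minutes-x-flies count matrix, `flyInfo()`
#' the per-fly metadata as a data.frame, `minuteOfDay()` the clock anchoring
#' of each row, `validMinutes()` the instrument-validity flags, and
#' `lightSchedule()` the [LightCycle-class]. `nDays()` gives the (possibly
#' fractional) number of recorded days.
#'
#' @param x an [ActivityExperiment-class].
#' @return See each accessor's description.
#' @name ActivityExperiment-accessors
#' @aliases activityCounts flyInfo minuteOfDay validMinutes lightSchedule nDays
NULL

#' @rdname ActivityExperiment-accessors
#' @export
activityCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname ActivityExperiment-accessors
#' @export
flyInfo <- function(x) as.data.frame(colData(x))

#' @rdname ActivityExperiment-accessors
#' @export
minuteOfDay <- function(x) rowData(x)$minuteOfDay

#' @rdname ActivityExperiment-accessors
#' @export
validMinutes <- function(x) rowData(x)$valid

#' @rdname ActivityExperiment-accessors
#' @export
lightSchedule <- function(x) metadata(x)$light

#' @rdname ActivityExperiment-accessors
#' @export
nDays <- function(x) nrow(x) / 1440

#' Species-level generative profile for the synthetic-data module
#'
#' Encodes the behavioral structure the analyses assume: a bimodal diurnal
#' activity rate (baseline plus circular-Gaussian morning and evening peaks),
#' night attenuation of awake activity, a unimodal thermal performance curve
#' scaling activity with temperature, geometric sleep/wake bout lengths, and
#' a truncated-Normal/uniform mixture of preferred temperatures on a 14-32
#' degree gradient.
#'
#' @slot name species label.
#' @slot baselineRate expected counts/min while awake, outside peaks, at the
#'   thermal optimum, in light.
#' @slot morningPeak,eveningPeak numeric `(center, width, height)`: center in
#'   minutes of day, width (Gaussian sd) in minutes, height in counts/min.
#'   Peaks are circular (wrapped at 1440) so a peak near midnight is
#'   well-defined.
#' @slot nightAttenuation multiplicative factor (>= 0) on the awake rate
#'   during lights-off.
#' @slot tpcTrue numeric `(tOpt, pMax, breadth)`: Gaussian thermal
#'   performance curve, normalized to 1 at `tOpt` when scaling activity.
#' @slot sleepMeanBout,wakeMeanBout mean bout lengths in minutes; sleep bouts
#'   are forced >= 5 min so scored sleep is non-degenerate.
#' @slot prefTemp,prefSpread center (degrees C) and sd of the preferred
#'   temperature distribution, truncated to [14, 32].
#' @slot uniformFraction probability a fly ignores the gradient and sits
#'   uniformly on it.
#'
#' @seealso [speciesProfile()], [makeSpeciesPanel()], [simulateActivity()]
#' @export
setClass("SpeciesProfile",
    representation(name = "character", baselineRate = "numeric",
        morningPeak = "numeric", eveningPeak = "numeric",
        nightAttenuation = "numeric", tpcTrue = "numeric",
        sleepMeanBout = "numeric", wakeMeanBout = "numeric",
        prefTemp = "numeric", prefSpread = "numeric",
        uniformFraction = "numeric"))

setValidity("SpeciesProfile", function(object) {
    p <- object
    if (length(p@morningPeak) != 3L || length(p@eveningPeak) != 3L)
        return("peaks must be (center, width, height)")
    if (length(p@tpcTrue) != 3L)
        return("tpcTrue must be (tOpt, pMax, breadth)")
    if (p@baselineRate < 0) return("baselineRate must be >= 0")
    if (p@morningPeak[2L] <= 0 || p@eveningPeak[2L] <= 0)
        return("peak widths must be > 0")
    if (p@morningPeak[3L] < 0 || p@eveningPeak[3L] < 0)
        return("peak heights must be >= 0")
    if (p@nightAttenuation < 0) return("nightAttenuation must be >= 0")
    if (p@tpcTrue[2L] <= 0 || p@tpcTrue[3L] <= 0)
        return("tpc pMax and breadth must be > 0")
    if (p@sleepMeanBout < 5) return("sleepMeanBout must be >= 5 min")
    if (p@wakeMeanBout < 1) return("wakeMeanBout must be >= 1 min")
    if (p@uniformFraction < 0 || p@uniformFraction > 1)
        return("uniformFraction must lie in [0, 1]")
    if (p@prefTemp < 14 || p@prefTemp > 32)
        return("prefTemp must lie in [14, 32]")
    if (p@prefSpread <= 0) return("prefSpread must be > 0")
    TRUE
})

#' @param name,baselineRate,morningPeak,eveningPeak,nightAttenuation,tpcTrue
#'   see slots.
#' @param sleepMeanBout,wakeMeanBout,prefTemp,prefSpread,uniformFraction see
#'   slots.
#' @return `speciesProfile()` returns a [SpeciesProfile-class].
#' @examples
#' speciesProfile("demo", baselineRate = 1.2)
#' @rdname SpeciesProfile-class
#' @export
speciesProfile <- function(name, baselineRate = 1,
                           morningPeak = c(510, 45, 2 * baselineRate),
                           eveningPeak = c(1170, 45, 2 * baselineRate),
                           nightAttenuation = 0.5,
                           tpcTrue = c(24, 1, 5),
                           sleepMeanBout = 30, wakeMeanBout = 30,
                           prefTemp = 24, prefSpread = 2,
                           uniformFraction = 0.05) {
    new("SpeciesProfile", name = as.character(name),
        baselineRate = as.numeric(baselineRate),
        morningPeak = as.numeric(morningPeak),
        eveningPeak = as.numeric(eveningPeak),
        nightAttenuation = as.numeric(nightAttenuation),
        tpcTrue = as.numeric(tpcTrue),
        sleepMeanBout = as.numeric(sleepMeanBout),
        wakeMeanBout = as.numeric(wakeMeanBout),
        prefTemp = as.numeric(prefTemp),
        prefSpread = as.numeric(prefSpread),
        uniformFraction = as.numeric(uniformFraction))
}

setMethod("show", "SpeciesProfile", function(object) {
    cat(sprintf(paste0("SpeciesProfile '%s': baseline %.2f counts/min, ",
        "T_opt %.1f C, pref %.1f +/- %.1f C\n"), object@name,
        object@baselineRate, object@tpcTrue[1L], object@prefTemp,
        object@prefSpread))
})

#' Simulation run settings
#'
#' @slot nFlies flies per species x temperature.
#' @slot nDays recorded days per fly (acclimation included if you intend to
#'   drop it downstream).
#' @slot temperaturesC experimental temperatures, each in [14, 32].
#' @slot seed integer seed; identical (profile, config) pairs reproduce
#'   identical tables.
#' @slot light a [LightCycle-class].
#' @export
setClass("SimulationConfig",
    representation(nFlies = "integer", nDays = "integer",
        temperaturesC = "numeric", seed = "integer", light = "LightCycle"))

setValidity("SimulationConfig", function(object) {
    if (object@nFlies < 1L) return("nFlies must be >= 1")
    if (object@nDays < 1L) return("nDays must be >= 1")
    if (length(object@temperaturesC) < 1L)
        return("at least one temperature required")
    if (any(object@temperaturesC < 14 | object@temperaturesC > 32))
        return("temperatures must lie within [14, 32]")
    TRUE
})

#' @param nFlies,nDays,temperaturesC,seed,light see slots.
#' @return `simulationConfig()` returns a [SimulationConfig-class].
#' @examples
#' simulationConfig(nFlies = 8, nDays = 5, temperaturesC = c(17, 23, 29))
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(nFlies = 16, nDays = 5,
                             temperaturesC = c(17, 20, 23, 26, 29),
                             seed = 1L, light = lightCycle()) {
    new("SimulationConfig", nFlies = as.integer(nFlies),
        nDays = as.integer(nDays), temperaturesC = as.numeric(temperaturesC),
        seed = as.integer(seed), light = light)
}

#' A temperature-gradient preference assay
#'
#' Holds one assay's probe calibration (position along the gradient axis,
#' temperature at that position) and the observed fly positions. Probe
#' temperatures must be strictly monotone along the axis; fly positions may
#' overshoot the probe span by at most 2\% of the span (photo digitization
#' jitter), beyond which construction fails.
#'
#' @slot assayId assay identifier.
#' @slot species species label.
#' @slot condition experimental condition, e.g. `"control"` or
#'   `"antenna_ablated"`.
#' @slot probes data.frame with columns `position`, `temperatureC`.
#' @slot flyPositions numeric axis positions, one per fly.
#' @slot assayClock free-text clock metadata (assays run 14:00-20:00).
#'
#' @seealso [assignFlyTemperatures()], [binPreference()],
#'   [preferredTemperature()]
#' @export
setClass("GradientAssay",
    representation(assayId = "character", species = "character",
        condition = "character", probes = "data.frame",
        flyPositions = "numeric", assayClock = "character"))

setValidity("GradientAssay", function(object) {
    pr <- object@probes
    if (!all(c("position", "temperatureC") %in% names(pr)))
        return("probes need columns position, temperatureC")
    if (nrow(pr) < 2L) return("at least 2 probes required")
    o <- order(pr$position)
    dT <- diff(pr$temperatureC[o])
    if (any(dT == 0) || (any(dT > 0) && any(dT < 0)))
        return("probe temperatures must be strictly monotone along position")
    span <- diff(range(pr$position))
    tol <- 0.02 * span
    fp <- object@flyPositions
    if (length(fp) && (any(fp < min(pr$position) - tol) ||
            any(fp > max(pr$position) + tol)))
        return("fly positions beyond 2% tolerance outside the probe span")
    TRUE
})

#' @param assayId,species,condition,probes,flyPositions,assayClock see slots.
#' @return `gradientAssay()` returns a [GradientAssay-class].
#' @examples
#' probes <- data.frame(position = c(0, 36), temperatureC = c(14, 32))
#' gradientAssay("a1", "D. melanogaster", probes = probes,
#'     flyPositions = c(10, 18, 25))
#' @rdname GradientAssay-class
#' @export
gradientAssay <- function(assayId, species, condition = "control", probes,
                          flyPositions, assayClock = "") {
    new("GradientAssay", assayId = as.character(assayId),
        species = as.character(species), condition = as.character(condition),
        probes = as.data.frame(probes),
        flyPositions = as.numeric(flyPositions),
        assayClock = as.character(assayClock))
}

setMethod("show", "GradientAssay", function(object) {
    cat(sprintf("GradientAssay '%s' (%s, %s): %d flies, %d probes %.1f-%.1f C\n",
        object@assayId, object@species, object@condition,
        length(object@flyPositions), nrow(object@probes),
        min(object@probes$temperatureC), max(object@probes$temperatureC)))
})

#' Nine-range temperature preference distribution
#'
#' Percentages of flies in the nine canonical gradient ranges: below 16
#' degrees ("15"), seven 2-degree ranges over 16-30, and above 30 ("31").
#' Aggregate distributions (mean over assays) additionally carry a per-bin
#' SEM and refuse further aggregation.
#'
#' @slot label assay identifier or aggregate label.
#' @slot binLabels the nine range labels.
#' @slot percentages percentage of flies per range; sums to 100.
#' @slot sem per-bin standard error over assays (aggregate only, else `NA`).
#' @slot n number of flies (single assay) or assays (aggregate).
#' @slot aggregate logical flag.
#' @export
setClass("PreferenceDistribution",
    representation(label = "character", binLabels = "character",
        percentages = "numeric", sem = "numeric", n = "integer",
        aggregate = "logical"))

setValidity("PreferenceDistribution", function(object) {
    if (length(object@binLabels) != 9L || length(object@percentages) != 9L)
        return("exactly 9 bins required")
    if (any(object@percentages < 0)) return("percentages must be >= 0")
    if (abs(sum(object@percentages) - 100) > 1e-9)
        return("percentages must sum to 100")
    TRUE
})

setMethod("show", "PreferenceDistribution", function(object) {
    cat(sprintf("PreferenceDistribution '%s'%s (n = %d)\n", object@label,
        if (object@aggregate) " [aggregate]" else "", object@n))
    df <- data.frame(range = object@binLabels,
        pct = round(object@percentages, 2))
    if (object@aggregate) df$sem <- round(object@sem, 2)
    print(df, row.names = FALSE)
})

#' @param x a `PreferenceDistribution`.
#' @return `as.data.frame()` gives columns `label`, `range`, `percent` (and
#'   `sem` for aggregates).
#' @rdname PreferenceDistribution-class
#' @export
setMethod("as.data.frame", "PreferenceDistribution", function(x, ...) {
    df <- data.frame(label = x@label, range = x@binLabels,
        percent = x@percentages, stringsAsFactors = FALSE)
    if (x@aggregate) df$sem <- x@sem
    df
})

#' A fitted thermal performance curve
#'
#' @slot model model name (`"quadratic"`, `"gaussian"`, `"briere2"`,
#'   `"weibull"`).
#' @slot params named fitted parameters.
#' @slot rss residual sum of squares.
#' @slot aic Akaike Information Criterion, `n*log(rss/n) + 2*(k + 1)` with
#'   the error variance counted as a parameter.
#' @slot nObs number of (temperature, performance) points fitted.
#' @slot tOpt temperature of maximal predicted performance (degrees C).
#' @slot pMax predicted performance at `tOpt`.
#' @slot extrapolated `TRUE` when `tOpt` falls outside the sampled
#'   temperature range.
#' @slot degenerate `TRUE` when the response carried no information (all
#'   performances equal).
#' @seealso [fitTpcModel()], [selectBestTpc()], [fitTpc()]
#' @export
setClass("TPCFit",
    representation(model = "character", params = "numeric", rss = "numeric",
        aic = "numeric", nObs = "integer", tOpt = "numeric", pMax = "numeric",
        extrapolated = "logical", degenerate = "logical"))

setValidity("TPCFit", function(object) {
    if (object@rss < 0) return("rss must be >= 0")
    TRUE
})

setMethod("show", "TPCFit", function(object) {
    cat(sprintf(
        "TPCFit [%s]: T_opt = %.2f C, P_max = %.3f, rss = %.4g, AIC = %.2f%s%s\n",
        object@model, object@tOpt, object@pMax, object@rss, object@aic,
        if (object@extrapolated) " (extrapolated)" else "",
        if (object@degenerate) " (degenerate)" else ""))
})
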