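#' The nine canonical gradient temperature ranges
#'
#' Flies below 16 degrees form the "15" range, flies above 30 degrees the
#' "31" range, and 16-30 degrees is partitioned into seven 2-degree ranges.
#' Interior bins are half-open `[lo, hi)` with the last closed at 30, so
#' 16.0 falls in 16-18 and 30.0 in 28-30.
#'
#' @return character vector of 9 labels.
#' @export
prefBinLabels <- function() {
    c("15", "16-18", "18-20", "20-22", "22-24", "24-26", "26-28", "28-30",
      "31")
}

#' Map fly positions to temperatures through the probe calibration
#'
#' Linear interpolation between the two probes bracketing each fly
#' position; positions slightly outside the probe span (within the 2\%
#' tolerance enforced by [GradientAssay-class]) are clamped to the nearest
#' probe's temperature. Output order matches fly order. Exact on probe
#' points, monotone between them, and invariant under affine rescaling of
#' the position axis applied to probes and flies alike.
#'
#' @param assay a [GradientAssay-class].
#' @return numeric vector of per-fly temperatures (degrees C).
#' @examples
#' probes <- data.frame(position = c(0, 36), temperatureC = c(14, 32))
#' a <- gradientAssay("a1", "demo", probes = probes, flyPositions = 18)
#' assignFlyTemperatures(a)   # 23
#' @export
assignFlyTemperatures <- function(assay) {
    stopifnot(is(assay, "GradientAssay"))
    validObject(assay)
    pr <- assay@probes[order(assay@probes$position), ]
    stats::approx(x = pr$position, y = pr$temperatureC,
        xout = assay@flyPositions, rule = 2)$y
}

#' Nine-range preference distribution of one assay
#'
#' @param temps per-fly temperatures in degrees C, all within \[14, 32\].
#' @param label distribution label (e.g. the assay id).
#' @return A [PreferenceDistribution-class] with percentages summing to
#'   100.
#' @examples
#' d <- binPreference(c(15.2, 16.0, 29.9, 30.5))
#' as.data.frame(d)
#' @export
binPreference <- function(temps, label = "assay") {
    if (length(temps) == 0L) stop("usage error: no fly temperatures")
    if (any(temps < 14 - 1e-9 | temps > 32 + 1e-9))
        stop("data error: temperatures outside [14, 32]")
    idx <- ifelse(temps < 16, 1L,
        ifelse(temps > 30, 9L, pmin(floor((temps - 16) / 2), 6) + 2L))
    counts <- tabulate(idx, nbins = 9L)
    new("PreferenceDistribution", label = as.character(label),
        binLabels = prefBinLabels(),
        percentages = 100 * counts / length(temps),
        sem = rep(NA_real_, 9L), n = length(temps), aggregate = FALSE)
}

#' Per-assay preferred temperature
#'
#' The sample median of the assay's individual fly temperatures (mean of
#' the middle two for even n) — the per-assay replicate value used for all
#' group statistics, the assay (not the fly) being the replicate unit.
#'
#' @param temps per-fly temperatures (>= 1 value).
#' @return numeric scalar, the preferred temperature in degrees C.
#' @examples
#' preferredTemperature(c(18, 20, 22, 30))   # 21
#' @export
preferredTemperature <- function(temps) {
    if (length(temps) == 0L) stop("usage error: no fly temperatures")
    stats::median(temps)
}

#' Preferred-temperature table for a set of assays
#'
#' @param assays list of [GradientAssay-class] objects.
#' @return data.frame: `assayId`, `species`, `condition`, `preferredC`.
#' @export
assayPreferredTemperatures <- function(assays) {
    do.call(rbind, lapply(assays, function(a) {
        data.frame(assayId = a@assayId, species = a@species,
            condition = a@condition,
            preferredC = preferredTemperature(assignFlyTemperatures(a)),
            row.names = NULL)
    }))
}

#' Aggregate preference distributions across replicate assays
#'
#' Per-bin mean percentage and standard error across assays (the assay is
#' the replicate unit; distributions are typically aggregated over at
#' least eight repeats). Aggregates of aggregates are refused.
#'
#' @param dists list of >= 2 single-assay [PreferenceDistribution-class]
#'   objects with matching bin labels.
#' @param label label of the aggregate.
#' @return An aggregate [PreferenceDistribution-class] with `sem` filled.
#' @export
aggregateDistributions <- function(dists, label = "aggregate") {
    if (length(dists) < 2L) stop("usage error: need >= 2 assays")
    if (any(vapply(dists, function(d) d@aggregate, logical(1))))
        stop("usage error: refusing to aggregate an aggregate")
    labs <- lapply(dists, function(d) d@binLabels)
    if (!all(vapply(labs, identical, logical(1), labs[[1L]])))
        stop("usage error: mismatched bin labels")
    P <- do.call(rbind, lapply(dists, function(d) d@percentages))
    m <- colMeans(P)
    sem <- apply(P, 2L, stats::sd) / sqrt(nrow(P))
    new("PreferenceDistribution", label = as.character(label),
        binLabels = labs[[1L]], percentages = m, sem = sem,
        n = length(dists), aggregate = TRUE)
}

#' Compare preferred temperatures between two groups of assays
#'
#' Two-sided Mann-Whitney U test on per-assay median preferred
#' temperatures — the comparison used for control versus antenna-ablated
#' flies. Groups smaller than 5 assays get a warning note but the test is
#' still computed.
#'
#' @param groupA,groupB numeric vectors of per-assay preferred
#'   temperatures, or data.frames with a `preferredC` column.
#' @return list: `U`, `pValue`, `shift` (difference of group medians, A
#'   minus B), `direction` (`"warmer"`, `"cooler"` or `"none"`), `notes`.
#' @seealso [mannWhitney()]
#' @export
comparePreference <- function(groupA, groupB) {
    a <- if (is.data.frame(groupA)) groupA$preferredC else as.numeric(groupA)
    b <- if (is.data.frame(groupB)) groupB$preferredC else as.numeric(groupB)
    notes <- character(0)
    if (length(a) < 5L || length(b) < 5L)
        notes <- c(notes, "group smaller than 5 assays")
    mw <- mannWhitney(a, b)
    shift <- stats::median(a) - stats::median(b)
    list(U = unname(mw$statistic), pValue = mw$p.value, shift = shift,
        direction = if (shift > 0) "warmer" else if (shift < 0) "cooler"
            else "none",
        notes = c(notes, mw$notes))
}

#' Read gradient assays from CSV tables
#'
#' Expects a probes table (`assayId`, `position`, `temperatureC`), a flies
#' table (`assayId`, `position`) and an optional metadata table
#' (`assayId`, `species`, `condition`).
#'
#' @param probesCsv,fliesCsv,metaCsv file paths; `metaCsv` may be `NULL`.
#' @return list of [GradientAssay-class] objects.
#' @export
readGradientAssays <- function(probesCsv, fliesCsv, metaCsv = NULL) {
    for (f in c(probesCsv, fliesCsv))
        if (!file.exists(f)) stop("input error: missing table ", f)
    probes <- utils::read.csv(probesCsv)
    flies <- utils::read.csv(fliesCsv)
    meta <- if (!is.null(metaCsv) && file.exists(metaCsv))
        utils::read.csv(metaCsv) else NULL
    need <- c("assayId", "position", "temperatureC")
    if (!all(need %in% names(probes)))
        stop("format error: probes table needs ",
            paste(need, collapse = ", "))
    if (!all(c("assayId", "position") %in% names(flies)))
        stop("format error: flies table needs assayId, position")
    lapply(unique(probes$assayId), function(id) {
        m <- meta[meta$assayId == id, , drop = FALSE]
        gradientAssay(assayId = id,
            species = if (!is.null(m) && nrow(m)) m$species[1L] else "unknown",
            condition = if (!is.null(m) && nrow(m) && "condition" %in%
                names(m)) m$condition[1L] else "control",
            probes = probes[probes$assayId == id,
                c("position", "temperatureC")],
            flyPositions = flies$position[flies$assayId == id])
    })
}
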