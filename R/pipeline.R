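#' Pipeline configuration
#'
#' Collects every analysis setting in one validated list. The defaults
#' reproduce the standard protocol exactly: 2 acclimation days dropped, a
#' 3-day analysis window recorded at 1-min resolution, lights on
#' 08:00-20:00, the 5-min sleep rule, 30-min profile bins, and the five
#' experimental temperatures 17/20/23/26/29 degrees.
#'
#' When `activityCsv` (and for the gradient arm `probesCsv` / `fliesCsv`)
#' are `NULL` the pipeline simulates the synthetic species panel instead.
#'
#' @param outDir output directory for result tables.
#' @param activityCsv optional tidy activity CSV (see [readActivityCsv()]).
#' @param probesCsv,fliesCsv,assayMetaCsv optional gradient-assay tables
#'   (see [readGradientAssays()]).
#' @param species character vector of panel species to simulate (`NULL` =
#'   all 11).
#' @param nFlies flies per species x temperature when simulating.
#' @param acclimationDays,analysisDays protocol windows in days.
#' @param temperaturesC experimental temperatures when simulating.
#' @param lightsOn,lightsOff light schedule in minutes after midnight.
#' @param minSleepBout sleep rule threshold in minutes.
#' @param binMinutes profile bin width in minutes.
#' @param deadFlyFilter drop flies silent over their final day (default
#'   off).
#' @param tpcMinTemps,tpcMinFlies minimum design for TPC fitting.
#' @param nAssays,fliesPerAssay gradient-assay design when simulating.
#' @param ablatedShiftC shift (degrees C) applied to the preferred
#'   temperature of simulated antenna-ablated flies (negative = cooler).
#' @param seed master seed; every downstream random draw derives from it.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(outDir = "thermofly_out", activityCsv = NULL,
                           probesCsv = NULL, fliesCsv = NULL,
                           assayMetaCsv = NULL, species = NULL,
                           nFlies = 16, acclimationDays = 2,
                           analysisDays = 3,
                           temperaturesC = c(17, 20, 23, 26, 29),
                           lightsOn = 480, lightsOff = 1200,
                           minSleepBout = 5, binMinutes = 30,
                           deadFlyFilter = FALSE, tpcMinTemps = 4,
                           tpcMinFlies = 3, nAssays = 8,
                           fliesPerAssay = 40, ablatedShiftC = -3,
                           seed = 1) {
    cfg <- list(outDir = outDir, activityCsv = activityCsv,
        probesCsv = probesCsv, fliesCsv = fliesCsv,
        assayMetaCsv = assayMetaCsv, species = species,
        nFlies = as.integer(nFlies),
        acclimationDays = as.integer(acclimationDays),
        analysisDays = as.integer(analysisDays),
        temperaturesC = as.numeric(temperaturesC),
        lightsOn = as.integer(lightsOn), lightsOff = as.integer(lightsOff),
        minSleepBout = as.integer(minSleepBout),
        binMinutes = as.integer(binMinutes),
        deadFlyFilter = isTRUE(deadFlyFilter),
        tpcMinTemps = as.integer(tpcMinTemps),
        tpcMinFlies = as.integer(tpcMinFlies),
        nAssays = as.integer(nAssays),
        fliesPerAssay = as.integer(fliesPerAssay),
        ablatedShiftC = as.numeric(ablatedShiftC), seed = as.integer(seed))
    if (cfg$analysisDays < 1L) stop("config error: analysisDays must be >= 1")
    if (cfg$acclimationDays < 0L)
        stop("config error: acclimationDays must be >= 0")
    if (1440 %% cfg$binMinutes != 0)
        stop("config error: binMinutes must divide 1440")
    lightCycle(cfg$lightsOn, cfg$lightsOff)  # validates the schedule
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys raise a
#' config error. An empty file reproduces every protocol default.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("config error: unknown field(s): ", paste(bad, collapse = ", "))
    if (!is.null(vals$temperaturesC))
        vals$temperaturesC <- unlist(vals$temperaturesC)
    do.call(pipelineConfig, vals)
}

#' Run the activity/sleep arm of the pipeline
#'
#' Emits per-fly activity and sleep summaries, 30-min activity and sleep
#' profiles, the per-bout table, Kruskal-Wallis + Dunn comparisons across
#' temperatures per species (total activity and total sleep), TPC fits per
#' species, and a run manifest. Inputs are either the configured tidy CSV
#' or the simulated species panel.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, a named list of the emitted data.frames (plus
#'   `tpcFits`, the [TPCFit-class] list).
#' @export
runActivityPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    log <- .pipelineLogger(config$outDir)
    tables <- .loadActivityTables(config, log)

    actSum <- do.call(rbind, lapply(tables, activitySummary))
    slpSum <- do.call(rbind, lapply(tables, sleepSummary,
        minBout = config$minSleepBout))
    actProf <- do.call(rbind, lapply(tables, activityProfile,
        binMinutes = config$binMinutes))
    slpProf <- do.call(rbind, lapply(tables, sleepProfile,
        binMinutes = config$binMinutes, minBout = config$minSleepBout))
    bouts <- do.call(rbind, lapply(tables, sleepBouts,
        minBout = config$minSleepBout))
    log("summaries", nrow(actSum), "per-fly activity rows")

    kw <- .temperatureComparisons(actSum, "totalDaily", "activity")
    kwS <- .temperatureComparisons(slpSum, "totalSleep", "sleep")
    tpcFits <- tryCatch(optimalActivityTemperature(actSum,
            minTemps = config$tpcMinTemps, minFlies = config$tpcMinFlies,
            seed = config$seed),
        error = function(e) { log("tpc", 0, conditionMessage(e)); NULL })
    tpcTab <- if (!is.null(tpcFits)) tpcFitTable(tpcFits) else NULL
    log("tpc", length(tpcFits), "species fitted")

    out <- list(activitySummary = actSum, sleepSummary = slpSum,
        activityProfile = actProf, sleepProfile = slpProf,
        sleepBouts = bouts, kwActivity = kw$kw, dunnActivity = kw$dunn,
        kwSleep = kwS$kw, dunnSleep = kwS$dunn, tpcTable = tpcTab)
    for (nm in names(out))
        if (!is.null(out[[nm]]))
            utils::write.csv(out[[nm]],
                file.path(config$outDir, paste0(.snake(nm), ".csv")),
                row.names = FALSE)
    .writeManifest(config, names(out))
    out$tpcFits <- tpcFits
    invisible(out)
}

#' Run the temperature-preference arm of the pipeline
#'
#' Emits per-assay and aggregate nine-range distributions, per-assay
#' preferred temperatures, the control-versus-ablated Mann-Whitney table,
#' and the preferred-versus-optimal comparison joining assay medians with
#' each species' TPC optimum.
#'
#' @param config a `PipelineConfig`.
#' @param tpcFits optional named list of [TPCFit-class] per species (e.g.
#'   from [runActivityPipeline()]); when `NULL` the join reads
#'   `tpc_table.csv` from `outDir` if present, else flags the optimum as
#'   missing.
#' @return Invisibly, a named list of the emitted data.frames.
#' @export
runTemprefPipeline <- function(config, tpcFits = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    log <- .pipelineLogger(config$outDir)
    assays <- .loadAssays(config, log)

    prefs <- assayPreferredTemperatures(assays)
    dists <- do.call(rbind, lapply(assays, function(a)
        cbind(species = a@species, condition = a@condition,
            as.data.frame(binPreference(assignFlyTemperatures(a),
                label = a@assayId)))))
    grp <- split(assays, vapply(assays, function(a)
        paste(a@species, a@condition, sep = "|"), character(1)))
    agg <- do.call(rbind, lapply(names(grp), function(g) {
        as <- grp[[g]]
        if (length(as) < 2L) return(NULL)
        d <- aggregateDistributions(lapply(as, function(a)
            binPreference(assignFlyTemperatures(a), label = a@assayId)),
            label = g)
        parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
        cbind(species = parts[1L], condition = parts[2L],
            as.data.frame(d))
    }))
    log("tempref", nrow(prefs), "assays scored")

    cmp <- do.call(rbind, lapply(split(prefs, prefs$species), function(sub) {
        a <- sub[sub$condition == "control", ]
        b <- sub[sub$condition == "antenna_ablated", ]
        if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
        r <- comparePreference(a, b)
        data.frame(species = sub$species[1L], U = r$U, pValue = r$pValue,
            shift = r$shift, direction = r$direction,
            notes = paste(r$notes, collapse = "; "), row.names = NULL)
    }))

    join <- .preferredVsOptimal(prefs, tpcFits, config)
    out <- list(preferredTemperatures = prefs, assayDistributions = dists,
        aggregateDistributions = agg, ablationTests = cmp,
        preferredVsOptimal = join)
    for (nm in names(out))
        if (!is.null(out[[nm]]))
            utils::write.csv(out[[nm]],
                file.path(config$outDir, paste0(.snake(nm), ".csv")),
                row.names = FALSE)
    .writeManifest(config, names(out), suffix = "tempref")
    invisible(out)
}

#' Run both pipeline arms
#'
#' @param config a `PipelineConfig`.
#' @return Invisibly, the combined named list of emitted tables.
#' @export
runFullPipeline <- function(config) {
    act <- runActivityPipeline(config)
    pref <- runTemprefPipeline(config, tpcFits = act$tpcFits)
    invisible(c(act, pref))
}

# ---- internals ----

.panelSubset <- function(config) {
    panel <- makeSpeciesPanel(config$seed)
    if (!is.null(config$species)) {
        miss <- setdiff(config$species, names(panel))
        if (length(miss))
            stop("config error: unknown panel species: ",
                paste(miss, collapse = ", "))
        panel <- panel[config$species]
    }
    panel
}

.loadActivityTables <- function(config, log) {
    if (!is.null(config$activityCsv)) {
        ae <- tryCatch(readActivityCsv(config$activityCsv,
                light = lightCycle(config$lightsOn, config$lightsOff)),
            error = function(e) stop("stage read_activity: ",
                conditionMessage(e)))
        log("read_activity", ncol(ae), "flies read")
        tables <- list(ae)
    } else {
        panel <- .panelSubset(config)
        tables <- lapply(seq_along(panel), function(i)
            simulateActivity(panel[[i]], simulationConfig(
                nFlies = config$nFlies,
                nDays = config$acclimationDays + config$analysisDays,
                temperaturesC = config$temperaturesC,
                seed = config$seed + i,
                light = lightCycle(config$lightsOn, config$lightsOff))))
        log("simulate", length(tables), "species simulated")
    }
    tables <- lapply(tables, function(ae) {
        ae <- tryCatch(dropAcclimation(ae, config$acclimationDays),
            error = function(e) stop("stage drop_acclimation: ",
                conditionMessage(e)))
        need <- config$analysisDays * 1440L
        if (nrow(ae) < need)
            stop("stage validate_window: only ", nrow(ae) / 1440,
                " days left after acclimation; need ", config$analysisDays)
        ae <- ae[seq_len(need), ]
        if (config$deadFlyFilter) {
            before <- ncol(ae)
            ae <- filterDeadFlies(ae)
            log("dead_fly_filter", ncol(ae),
                paste0(before - ncol(ae), " flies dropped"))
        }
        ae
    })
    tables
}

.loadAssays <- function(config, log) {
    if (!is.null(config$probesCsv) || !is.null(config$fliesCsv)) {
        if (is.null(config$probesCsv))
            stop("stage read_assays: missing probes table")
        if (is.null(config$fliesCsv))
            stop("stage read_assays: missing flies table")
        assays <- readGradientAssays(config$probesCsv, config$fliesCsv,
            config$assayMetaCsv)
        log("read_assays", length(assays), "assays read")
        return(assays)
    }
    panel <- .panelSubset(config)
    assays <- list()
    for (i in seq_along(panel)) {
        prof <- panel[[i]]
        shifted <- speciesProfile(prof@name,
            baselineRate = prof@baselineRate,
            morningPeak = prof@morningPeak, eveningPeak = prof@eveningPeak,
            nightAttenuation = prof@nightAttenuation, tpcTrue = prof@tpcTrue,
            sleepMeanBout = prof@sleepMeanBout,
            wakeMeanBout = prof@wakeMeanBout,
            prefTemp = min(max(prof@prefTemp + config$ablatedShiftC, 14), 32),
            prefSpread = prof@prefSpread,
            uniformFraction = prof@uniformFraction)
        for (j in seq_len(config$nAssays)) {
            assays <- c(assays,
                simulateGradientAssay(prof, nFlies = config$fliesPerAssay,
                    seed = config$seed + 10000L + i * 100L + j,
                    assayId = sprintf("%s_ctrl_%02d", prof@name, j),
                    condition = "control"),
                simulateGradientAssay(shifted,
                    nFlies = config$fliesPerAssay,
                    seed = config$seed + 20000L + i * 100L + j,
                    assayId = sprintf("%s_abl_%02d", prof@name, j),
                    condition = "antenna_ablated"))
        }
    }
    log("simulate_assays", length(assays), "assays simulated")
    assays
}

.temperatureComparisons <- function(summary, metric, label) {
    kwRows <- list(); dunnRows <- list()
    for (sp in unique(summary$species)) {
        sub <- summary[summary$species == sp, ]
        temps <- sort(unique(sub$temperatureC))
        if (length(temps) < 2L) next
        groups <- lapply(temps, function(tc)
            sub[[metric]][sub$temperatureC == tc])
        names(groups) <- as.character(temps)
        kw <- kruskalWallis(groups, pMethod = "chisq")
        kwRows[[sp]] <- data.frame(species = sp, metric = label,
            H = unname(kw$statistic), df = unname(kw$parameter),
            pValue = kw$p.value, row.names = NULL)
        d <- dunnBonferroni(groups)
        dunnRows[[sp]] <- cbind(species = sp, metric = label, d)
    }
    list(kw = do.call(rbind, kwRows), dunn = do.call(rbind, dunnRows))
}

.preferredVsOptimal <- function(prefs, tpcFits, config) {
    ctrl <- prefs[prefs$condition == "control", ]
    med <- tapply(ctrl$preferredC, ctrl$species, stats::median)
    tab <- if (!is.null(tpcFits)) tpcFitTable(tpcFits) else {
        f <- file.path(config$outDir, "tpc_table.csv")
        if (file.exists(f)) utils::read.csv(f) else NULL
    }
    sp <- sort(unique(ctrl$species))
    data.frame(species = sp,
        preferredC = as.numeric(med[sp]),
        tOptC = if (is.null(tab)) NA_real_
            else tab$tOpt[match(sp, tab$species)],
        tOptMissing = if (is.null(tab)) TRUE else !(sp %in% tab$species),
        row.names = NULL)
}

.pipelineLogger <- function(outDir) {
    path <- file.path(outDir, "pipeline_log.txt")
    function(stage, n, what)
        cat(sprintf("[%s] n=%s %s\n", stage, n, what), file = path,
            append = TRUE)
}

.writeManifest <- function(config, tables, suffix = "activity") {
    manifest <- list(
        pipeline = suffix,
        package = "ThermoFly",
        version = as.character(utils::packageVersion("ThermoFly")),
        seed = config$seed,
        config = unclass(config),
        tables = paste0(.snake(tables), ".csv"))
    jsonlite::write_json(manifest,
        file.path(config$outDir, paste0("manifest_", suffix, ".json")),
        auto_unbox = TRUE, null = "null", pretty = TRUE)
}

.snake <- function(x) tolower(gsub("([A-Z])", "_\\1", x))
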