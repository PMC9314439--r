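#' Thermal scaling of the generative activity rate
#'
#' The generator's true thermal performance curve is Gaussian in
#' temperature and normalized to 1 at the optimum:
#' `scale(T) = exp(-(T - tOpt)^2 / (2 * breadth^2))`.
#'
#' @param profile a [SpeciesProfile-class].
#' @param temperatureC temperature(s) in degrees C.
#' @return numeric scaling factor(s) in (0, 1].
#' @export
tpcScaleTrue <- function(profile, temperatureC) {
    stopifnot(is(profile, "SpeciesProfile"))
    tOpt <- profile@tpcTrue[1L]; breadth <- profile@tpcTrue[3L]
    exp(-(temperatureC - tOpt)^2 / (2 * breadth^2))
}

# Per-minute awake firing rate over one day (length 1440), at temperature T.
.dayRate <- function(profile, temperatureC, light) {
    m <- 0:1439
    circGauss <- function(peak) {
        d <- ((m - peak[1L] + 720) %% 1440) - 720
        peak[3L] * exp(-d^2 / (2 * peak[2L]^2))
    }
    base <- profile@baselineRate + circGauss(profile@morningPeak) +
        circGauss(profile@eveningPeak)
    gate <- ifelse(isLight(light, m), 1, profile@nightAttenuation)
    tpcScaleTrue(profile, temperatureC) * gate * base
}

#' Simulate per-minute locomotor activity
#'
#' Per fly, a two-state alternating renewal process (wake/sleep) gates an
#' inhomogeneous Poisson count process. Bout lengths are geometric at minute
#' resolution: wake bouts have support >= 1 min with the profile's mean;
#' sleep bouts have support >= 5 min (shifted geometric) so scored sleep is
#' consistent with the five-minute immobility rule. While awake the Poisson
#' rate is `tpcScale(T) * nightGate(t) * (baseline + morningPeak(t) +
#' eveningPeak(t))`; while asleep the rate is zero. The initial state is
#' drawn from the stationary wake probability
#' `wakeMeanBout / (wakeMeanBout + sleepMeanBout)`.
#'
#' Identical `(profile, config)` pairs (the seed lives in the config)
#' reproduce identical tables.
#'
#' @param profile a [SpeciesProfile-class].
#' @param config a [SimulationConfig-class]; one cohort of `nFlies` flies is
#'   simulated at each configured temperature.
#' @return An [ActivityExperiment-class] with `nFlies *
#'   length(temperaturesC)` columns; fly ids are
#'   `"<species>_T<temp>_f<k>"`.
#' @seealso [expectedDailyActivity()] for the closed-form expectation used
#'   as a Monte-Carlo oracle.
#' @examples
#' ae <- simulateActivity(speciesProfile("demo"),
#'     simulationConfig(nFlies = 2, nDays = 3, temperaturesC = c(17, 26)))
#' ae
#' @export
simulateActivity <- function(profile, config) {
    stopifnot(is(profile, "SpeciesProfile"), is(config, "SimulationConfig"))
    validObject(profile); validObject(config)
    set.seed(config@seed)
    M <- config@nDays * 1440L
    light <- config@light
    nT <- length(config@temperaturesC)
    counts <- matrix(0L, nrow = M, ncol = config@nFlies * nT)
    flyId <- character(config@nFlies * nT)
    tempOf <- numeric(config@nFlies * nT)
    startClock <- light@lightsOn  # recordings anchored at lights-on
    wakeFrac <- profile@wakeMeanBout /
        (profile@wakeMeanBout + profile@sleepMeanBout)
    col <- 0L
    for (tc in config@temperaturesC) {
        rate <- rep(.dayRate(profile, tc, light), length.out = M + 1439L)
        rate <- rate[(startClock %% 1440) + seq_len(M)]
        if (any(!is.finite(rate)))
            stop("profile error: non-finite activity rate")
        for (i in seq_len(config@nFlies)) {
            awake <- .simulateWakeVector(profile, M, wakeFrac)
            col <- col + 1L
            counts[, col] <- stats::rpois(M, rate * awake)
            flyId[col] <- sprintf("%s_T%g_f%02d", profile@name, tc, i)
            tempOf[col] <- tc
        }
    }
    ActivityExperiment(counts, flyId = flyId, species = profile@name,
        temperatureC = tempOf, startClock = startClock, light = light)
}

# 0/1 awake indicator of length M from the alternating renewal process.
.simulateWakeVector <- function(profile, M, wakeFrac) {
    pw <- 1 / profile@wakeMeanBout
    ps <- 1 / (profile@sleepMeanBout - 4)   # sleep = 5 + Geom, mean as stated
    startAwake <- stats::runif(1) < wakeFrac
    lens <- integer(0); states <- logical(0); tot <- 0L
    while (tot < M) {
        k <- max(16L, ceiling(2 * (M - tot) /
            (profile@wakeMeanBout + profile@sleepMeanBout)))
        w <- 1L + stats::rgeom(k, pw)
        s <- 5L + stats::rgeom(k, ps)
        if (startAwake && length(states) == 0L || length(states) == 0L) {
            newLens <- if (startAwake) as.vector(rbind(w, s))
                       else as.vector(rbind(s, w))
            newStates <- if (startAwake) rep(c(TRUE, FALSE), k)
                         else rep(c(FALSE, TRUE), k)
        } else {
            contAwake <- !states[length(states)]
            newLens <- if (contAwake) as.vector(rbind(w, s))
                       else as.vector(rbind(s, w))
            newStates <- if (contAwake) rep(c(TRUE, FALSE), k)
                         else rep(c(FALSE, TRUE), k)
        }
        lens <- c(lens, newLens); states <- c(states, newStates)
        tot <- tot + sum(newLens)
    }
    rep(states, lens)[seq_len(M)]
}

#' Closed-form expected daily activity of the generator
#'
#' The analytic expectation of a simulated fly's total daily count: the
#' integral of the awake firing rate over one day times the stationary awake
#' fraction. Used as the independent oracle for Monte-Carlo checks of
#' [simulateActivity()].
#'
#' @param profile a [SpeciesProfile-class].
#' @param temperatureC temperature in degrees C.
#' @param light a [LightCycle-class].
#' @return Expected counts per day (numeric scalar).
#' @export
expectedDailyActivity <- function(profile, temperatureC,
                                  light = lightCycle()) {
    stopifnot(is(profile, "SpeciesProfile"))
    wakeFrac <- profile@wakeMeanBout /
        (profile@wakeMeanBout + profile@sleepMeanBout)
    sum(.dayRate(profile, temperatureC, light)) * wakeFrac
}

#' Default probe calibration for a 14-32 degree gradient
#'
#' Four probes on a 36-unit axis with a linear temperature profile, matching
#' the common practice of monitoring the field at 4 or 6 points.
#'
#' @param nProbes 4 or 6.
#' @return data.frame with columns `position`, `temperatureC`.
#' @export
defaultGradientProbes <- function(nProbes = 4) {
    pos <- seq(0, 36, length.out = nProbes)
    data.frame(position = pos,
        temperatureC = 14 + (32 - 14) * pos / 36)
}

#' Simulate a temperature-gradient preference assay
#'
#' Each fly's latent temperature is drawn from a mixture: with probability
#' `uniformFraction` uniform on \[14, 32\] (the fly ignores the gradient),
#' otherwise Normal(`prefTemp`, `prefSpread`) truncated to \[14, 32\]. The
#' latent temperature is inverted through the probe calibration (piecewise
#' linear) to an axis position.
#'
#' @param profile a [SpeciesProfile-class].
#' @param probes probe calibration data.frame (`position`, `temperatureC`)
#'   spanning 14-32 degrees monotonically; default
#'   [defaultGradientProbes()].
#' @param nFlies flies per assay; assays typically hold 30-50 flies.
#' @param seed integer seed.
#' @param assayId,condition assay metadata.
#' @return A [GradientAssay-class].
#' @examples
#' a <- simulateGradientAssay(speciesProfile("demo", prefTemp = 24),
#'     nFlies = 40, seed = 7)
#' preferredTemperature(assignFlyTemperatures(a))
#' @export
simulateGradientAssay <- function(profile, probes = defaultGradientProbes(),
                                  nFlies = 40, seed = 1,
                                  assayId = paste0(profile@name, "_assay"),
                                  condition = "control") {
    stopifnot(is(profile, "SpeciesProfile"))
    probes <- as.data.frame(probes)
    o <- order(probes$position)
    dT <- diff(probes$temperatureC[o])
    if (any(dT == 0) || (any(dT > 0) && any(dT < 0)))
        stop("calibration error: probe temperatures not monotone along axis")
    set.seed(as.integer(seed))
    n <- as.integer(nFlies)
    uniform <- stats::runif(n) < profile@uniformFraction
    lo <- stats::pnorm(14, profile@prefTemp, profile@prefSpread)
    hi <- stats::pnorm(32, profile@prefTemp, profile@prefSpread)
    latent <- stats::qnorm(stats::runif(n, lo, hi), profile@prefTemp,
        profile@prefSpread)
    latent[uniform] <- stats::runif(sum(uniform), 14, 32)
    latent <- pmin(pmax(latent, 14), 32)
    pos <- stats::approx(x = probes$temperatureC[o],
        y = probes$position[o], xout = latent, rule = 2)$y
    gradientAssay(assayId = assayId, species = profile@name,
        condition = condition, probes = probes, flyPositions = pos)
}
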