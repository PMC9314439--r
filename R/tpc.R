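#' The thermal performance curve model library
#'
#' Four unimodal forms covering the shapes commonly fitted to
#' temperature-performance data. Each model is a list with `name`,
#' `nParams`, a prediction function `fun(T, p)`, and parameter `lower` /
#' `upper` bounds (some data-scaled at fit time):
#'
#' * `quadratic`: `P = a + b*T + c*T^2` (concave; fitted by exact linear
#'   least squares).
#' * `gaussian`: `P = pmax * exp(-(T - topt)^2 / (2 * breadth^2))`.
#' * `briere2`: `P = a * T * (T - tmin) * (tmax - T)^(1/m)` on
#'   `[tmin, tmax]`, 0 outside — the left-skewed ectotherm curve with a
#'   free exponent.
#' * `weibull`: the reparameterized Weibull curve with height `a` at its
#'   optimum `topt`, breadth `b` and shape `d > 1`; 0 where undefined.
#'
#' @return Named list of model definitions.
#' @seealso [fitTpcModel()], [fitTpc()]
#' @export
tpcModels <- function() {
    list(
        quadratic = list(name = "quadratic", nParams = 3L,
            fun = function(T, p) p[1L] + p[2L] * T + p[3L] * T^2,
            lower = c(a = -Inf, b = -Inf, c = -Inf),
            upper = c(a = Inf, b = Inf, c = Inf)),
        gaussian = list(name = "gaussian", nParams = 3L,
            fun = function(T, p)
                p[1L] * exp(-(T - p[2L])^2 / (2 * p[3L]^2)),
            lower = c(pmax = 1e-8, topt = 0, breadth = 0.3),
            upper = c(pmax = NA, topt = 50, breadth = 30)),
        briere2 = list(name = "briere2", nParams = 4L,
            fun = function(T, p) {
                out <- p[1L] * T * (T - p[2L]) *
                    (pmax(p[3L] - T, 0))^(1 / p[4L])
                out[T < p[2L] | T > p[3L]] <- 0
                out
            },
            lower = c(a = 1e-10, tmin = -15, tmax = 28, m = 1),
            upper = c(a = NA, tmin = 15, tmax = 60, m = 12)),
        weibull = list(name = "weibull", nParams = 4L,
            fun = function(T, p) {
                a <- p[1L]; topt <- p[2L]; b <- p[3L]; d <- p[4L]
                cst <- ((d - 1) / d)^(1 / d)
                base <- (T - topt) / b + cst
                out <- numeric(length(T))
                ok <- base > 0
                out[ok] <- a * cst^(1 - d) * base[ok]^(d - 1) *
                    exp(-base[ok]^d + (d - 1) / d)
                out
            },
            lower = c(a = 1e-8, topt = 0, b = 0.5, d = 1.05),
            upper = c(a = NA, topt = 50, b = 40, d = 15))
    )
}

#' Fit one thermal performance model
#'
#' Bounded nonlinear least squares via Levenberg-Marquardt with seeded
#' multi-starts drawn uniformly within the parameter bounds (plus one
#' moment-based heuristic start), keeping the best local optimum. The
#' quadratic model is linear in its parameters and is solved exactly.
#'
#' `aic = n * log(rss / n) + 2 * (nParams + 1)`, the Gaussian-error
#' least-squares form with the error variance counted as a parameter.
#' `tOpt` is found in closed form for the quadratic (`-b / (2c)`) and by a
#' 0.01-degree grid search over `[min(temps) - 5, max(temps) + 5]`
#' otherwise; a fit whose optimum falls outside the sampled temperature
#' range is flagged `extrapolated`.
#'
#' @param temps temperatures (degrees C); at least `nParams + 1` distinct
#'   values.
#' @param perf performance values (finite), same length.
#' @param model a model definition from [tpcModels()], or its name.
#' @param seed integer seed for the multi-start draws.
#' @param nStarts number of random starts (default 25).
#' @return A [TPCFit-class].
#' @examples
#' fitTpcModel(c(20, 23, 26), c(80, 90, 80), "quadratic")
#' @export
fitTpcModel <- function(temps, perf, model, seed = 1, nStarts = 25) {
    if (is.character(model)) {
        model <- tpcModels()[[match.arg(model, names(tpcModels()))]]
    }
    temps <- as.numeric(temps); perf <- as.numeric(perf)
    if (length(temps) != length(perf)) stop("temps and perf lengths differ")
    if (any(!is.finite(temps)) || any(!is.finite(perf)))
        stop("temps and perf must be finite")
    n <- length(temps)
    if (length(unique(temps)) < model$nParams)
        stop("under-determined error: need at least ", model$nParams,
            " distinct temperatures for the ", model$name, " model")
    degenerate <- length(unique(perf)) == 1L

    if (model$name == "quadratic") {
        fit <- stats::lm(perf ~ temps + I(temps^2))
        par <- stats::coef(fit)
        par[is.na(par)] <- 0
        names(par) <- c("a", "b", "c")
        rss <- sum(stats::resid(fit)^2)
    } else {
        sc <- .tpcScaleBounds(model, perf)
        par <- .tpcMultiStart(model, temps, perf, sc, seed, nStarts)
        rss <- sum((perf - model$fun(temps, par))^2)
    }

    aic <- n * log(max(rss, 1e-300) / n) + 2 * (model$nParams + 1)
    opt <- .tpcOptimum(model, par, temps)
    new("TPCFit", model = model$name, params = par, rss = rss, aic = aic,
        nObs = as.integer(n), tOpt = opt$tOpt, pMax = opt$pMax,
        extrapolated = opt$tOpt < min(temps) - 1e-9 ||
            opt$tOpt > max(temps) + 1e-9,
        degenerate = degenerate)
}

.tpcScaleBounds <- function(model, perf) {
    lower <- model$lower; upper <- model$upper
    top <- max(abs(perf)) * 3 + 1e-6
    if ("pmax" %in% names(upper) && is.na(upper["pmax"]))
        upper["pmax"] <- top
    if ("a" %in% names(upper) && is.na(upper["a"]))
        upper["a"] <- if (model$name == "briere2") top else top
    list(lower = lower, upper = upper)
}

.tpcHeuristicStart <- function(model, temps, perf, sc) {
    tb <- temps[which.max(perf)]
    pm <- max(perf)
    st <- switch(model$name,
        gaussian = c(pmax = pm, topt = tb, breadth = diff(range(temps)) / 3),
        briere2 = c(a = pm / max(tb * (tb - 5) * 2, 1), tmin = 5,
            tmax = max(temps) + 6, m = 2),
        weibull = c(a = pm, topt = tb, b = diff(range(temps)) / 2, d = 2))
    pmin(pmax(st, sc$lower + 1e-6), sc$upper - 1e-6)
}

.tpcMultiStart <- function(model, temps, perf, sc, seed, nStarts) {
    set.seed(as.integer(seed))
    k <- model$nParams
    resid <- function(p) perf - model$fun(temps, p)
    starts <- c(list(.tpcHeuristicStart(model, temps, perf, sc)),
        lapply(seq_len(nStarts), function(i) {
            s <- stats::runif(k, sc$lower, sc$upper)
            names(s) <- names(sc$lower)
            s
        }))
    ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
        ptol = 1e-15)
    best <- NULL; bestRss <- Inf
    for (s in starts) {
        f <- tryCatch(minpack.lm::nls.lm(par = s, lower = sc$lower,
            upper = sc$upper, fn = resid, control = ctrl),
            error = function(e) NULL)
        if (is.null(f)) next
        r <- sum(resid(f$par)^2)
        if (is.finite(r) && r < bestRss) { bestRss <- r; best <- f$par }
    }
    if (is.null(best))
        stop("fit error: no start converged for model ", model$name)
    # polish the winner
    f <- tryCatch(minpack.lm::nls.lm(par = best, lower = sc$lower,
        upper = sc$upper, fn = resid, control = ctrl),
        error = function(e) NULL)
    if (!is.null(f) && sum(resid(f$par)^2) <= bestRss) best <- f$par
    best
}

.tpcOptimum <- function(model, par, temps) {
    if (model$name == "quadratic" && par["c"] < 0) {
        tOpt <- as.numeric(-par["b"] / (2 * par["c"]))
        lo <- min(temps) - 5; hi <- max(temps) + 5
        tOpt <- min(max(tOpt, lo), hi)
    } else {
        grid <- seq(min(temps) - 5, max(temps) + 5, by = 0.01)
        tOpt <- grid[which.max(model$fun(grid, par))]
    }
    list(tOpt = tOpt, pMax = as.numeric(model$fun(tOpt, par)))
}

#' Select the best thermal performance fit by AIC
#'
#' Returns the fit with the lowest AIC among non-degenerate fits. Ties are
#' broken by fewer parameters, then by the fixed model order quadratic <
#' gaussian < briere2 < weibull. If every fit is degenerate (flat
#' response), the first fit is returned with its degenerate flag set.
#'
#' @param fits list of [TPCFit-class] objects.
#' @return The selected [TPCFit-class].
#' @export
selectBestTpc <- function(fits) {
    if (length(fits) == 0L) stop("usage error: empty fit list")
    ok <- !vapply(fits, function(f) f@degenerate, logical(1))
    if (!any(ok)) return(fits[[1L]])
    fits <- fits[ok]
    modelOrder <- match(vapply(fits, function(f) f@model, character(1)),
        names(tpcModels()))
    aics <- vapply(fits, function(f) f@aic, numeric(1))
    nps <- vapply(fits, function(f) length(f@params), numeric(1))
    fits[[order(aics, nps, modelOrder)[1L]]]
}

#' Fit all models and select the best
#'
#' @param temps,perf data as in [fitTpcModel()].
#' @param seed integer seed for multi-starts.
#' @param models model definitions to try (default the full library,
#'   skipping models with too few distinct temperatures).
#' @return list with elements `best` (the selected [TPCFit-class]) and
#'   `fits` (all fitted models).
#' @examples
#' T <- seq(17, 29, 1)
#' P <- 100 * exp(-(T - 25)^2 / 32)
#' fitTpc(T, P)$best
#' @export
fitTpc <- function(temps, perf, seed = 1, models = tpcModels()) {
    feasible <- Filter(function(m)
        length(unique(temps)) >= m$nParams, models)
    if (length(feasible) == 0L)
        stop("under-determined error: too few distinct temperatures")
    fits <- lapply(feasible, function(m)
        fitTpcModel(temps, perf, m, seed = seed))
    list(best = selectBestTpc(fits), fits = fits)
}

#' Optimal activity temperature per species
#'
#' Performance is the per-temperature mean of each fly's total daily
#' activity; all library models are fitted to the species' temperature
#' means and the lowest-AIC fit is returned. Mirrors the comparison of
#' preferred versus activity-optimal temperatures: the selected fit's
#' `tOpt` is the species' activity optimum.
#'
#' @param summary per-fly activity summary (from [activitySummary()]),
#'   possibly spanning several species.
#' @param minTemps minimum distinct temperatures per species (default 4;
#'   fewer raises an under-determined error, mirroring species not assayed
#'   at the hottest condition).
#' @param minFlies minimum flies per temperature (default 3).
#' @param seed integer seed for the fits.
#' @return Named list (by species) of selected [TPCFit-class] objects.
#' @export
optimalActivityTemperature <- function(summary, minTemps = 4, minFlies = 3,
                                       seed = 1) {
    res <- lapply(split(summary, summary$species), function(sub) {
        tab <- table(sub$temperatureC)
        if (any(tab < minFlies))
            stop("under-determined error: fewer than ", minFlies,
                " flies at some temperature for species ",
                sub$species[1L])
        if (length(tab) < minTemps)
            stop("under-determined error: species ", sub$species[1L],
                " has ", length(tab), " temperature levels; need >= ",
                minTemps)
        agg <- tapply(sub$totalDaily, sub$temperatureC, mean)
        fitTpc(as.numeric(names(agg)), as.numeric(agg), seed = seed)$best
    })
    res
}

#' Flatten TPC fits to a table
#'
#' @param fits named list of [TPCFit-class] (e.g. from
#'   [optimalActivityTemperature()]).
#' @return data.frame: `species`, `model`, `tOpt`, `pMax`, `rss`, `aic`,
#'   `extrapolated`, `degenerate`, and the fitted parameters serialized as
#'   `name=value` pairs.
#' @export
tpcFitTable <- function(fits) {
    do.call(rbind, lapply(names(fits), function(sp) {
        f <- fits[[sp]]
        data.frame(species = sp, model = f@model, tOpt = f@tOpt,
            pMax = f@pMax, rss = f@rss, aic = f@aic,
            extrapolated = f@extrapolated, degenerate = f@degenerate,
            params = paste(sprintf("%s=%.6g", names(f@params), f@params),
                collapse = ";"),
            row.names = NULL)
    }))
}
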