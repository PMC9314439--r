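test_that("a quadratic through exact points is recovered in closed form", {
    f <- fitTpcModel(c(20, 23, 26), c(80, 90, 80), "quadratic")
    expect_equal(f@tOpt, 23, tolerance = 1e-8)
    expect_equal(f@pMax, 90, tolerance = 1e-8)
    expect_lt(f@rss, 1e-12)
})

test_that("noiseless data from each library model is refit exactly", {
    T <- seq(17, 29, 1)
    truth <- list(
        quadratic = c(a = -500, b = 48, c = -0.96),
        gaussian = c(pmax = 100, topt = 25, breadth = 4),
        briere2 = c(a = 0.08, tmin = 8, tmax = 33, m = 2.5),
        weibull = c(a = 100, topt = 25, b = 8, d = 3))
    models <- tpcModels()
    for (nm in names(models)) {
        P <- models[[nm]]$fun(T, truth[[nm]])
        f <- fitTpcModel(T, P, models[[nm]], seed = 11)
        expect_lt(f@rss, 1e-6)
        expect_lt(max(abs(f@params - truth[[nm]])), 1e-3)
    }
})

test_that("gaussian noiseless recovery hits the stated tolerances", {
    T <- seq(17, 29, 1)
    P <- 100 * exp(-(T - 25)^2 / (2 * 16))
    f <- fitTpcModel(T, P, "gaussian", seed = 2)
    expect_lt(abs(f@tOpt - 25), 1e-3)
    expect_lt(abs(f@pMax - 100), 1e-3)
    expect_lt(f@rss, 1e-6)
})

test_that("selection is argmin AIC with parsimony tie-breaking", {
    mkFit <- function(model, aic, np) new("TPCFit", model = model,
        params = setNames(numeric(np), paste0("p", seq_len(np))),
        rss = 1, aic = aic, nObs = 10L, tOpt = 25, pMax = 1,
        extrapolated = FALSE, degenerate = FALSE)
    fits <- list(mkFit("quadratic", 10.0, 3), mkFit("gaussian", 8.5, 3),
        mkFit("briere2", 12.1, 4))
    expect_equal(selectBestTpc(fits)@model, "gaussian")
    # equal rss: the AIC penalty puts the 3-parameter model first
    n <- 10; rss <- 2
    aic3 <- n * log(rss / n) + 2 * 4
    aic4 <- n * log(rss / n) + 2 * 5
    expect_gt(aic4, aic3)
    tie <- list(mkFit("weibull", 5, 4), mkFit("gaussian", 5, 3))
    expect_equal(selectBestTpc(tie)@model, "gaussian")
    expect_error(selectBestTpc(list()), "usage error")
})

test_that("rss is invariant to data permutation", {
    set.seed(3)
    T <- seq(17, 29, 1)
    P <- 100 * exp(-(T - 24)^2 / 40) + rnorm(13, 0, 2)
    perm <- sample(13)
    f1 <- fitTpcModel(T, P, "gaussian", seed = 5)
    f2 <- fitTpcModel(T[perm], P[perm], "gaussian", seed = 5)
    expect_equal(f1@rss, f2@rss, tolerance = 1e-8)
})

test_that("fit preconditions and degenerate responses are flagged", {
    expect_error(fitTpcModel(c(20, 23), c(1, 2), "gaussian"),
        "under-determined")
    f <- fitTpcModel(seq(17, 29, 3), rep(50, 5), "quadratic")
    expect_true(f@degenerate)
    # a flat species response propagates the degenerate flag
    summ <- data.frame(flyId = paste0("f", 1:20),
        species = "flat", temperatureC = rep(c(17, 20, 23, 26, 29), 4),
        totalDaily = 100)
    fit <- optimalActivityTemperature(summ)$flat
    expect_true(fit@degenerate)
})

test_that("the species activity optimum is recovered from simulation", {
    p <- speciesProfile("warm", baselineRate = 1.2, tpcTrue = c(26, 1, 4))
    ae <- simulateActivity(p, simulationConfig(nFlies = 30, nDays = 3,
        temperaturesC = c(17, 20, 23, 26, 29), seed = 21))
    s <- activitySummary(ae)
    fit <- optimalActivityTemperature(s, seed = 3)$warm
    expect_gte(fit@tOpt, 25)
    expect_lte(fit@tOpt, 27)
    # with the hottest condition absent the fit still stands, and an
    # optimum beyond the sampled range would be flagged extrapolated
    s4 <- s[s$temperatureC != 29, ]
    fit4 <- optimalActivityTemperature(s4, seed = 3)$warm
    expect_s4_class(fit4, "TPCFit")
    expect_equal(fit4@extrapolated, fit4@tOpt > 26 || fit4@tOpt < 17)
    expect_error(
        optimalActivityTemperature(s[s$temperatureC %in% c(17, 20, 23), ]),
        "under-determined")
})
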