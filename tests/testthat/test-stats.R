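test_that("Kruskal-Wallis reproduces the hand-computed example", {
    h <- kruskalWallis(list(1:3, 4:6, 7:9))
    expect_equal(unname(h$statistic), 7.2)
    expect_equal(unname(h$parameter), 2)
    # identical groups carry no rank separation
    same <- kruskalWallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
    expect_equal(unname(same$statistic), 0)
    expect_equal(same$p.value, 1)
})

test_that("H matches the rank-ANOVA oracle on random data with ties", {
    set.seed(67)
    for (i in 1:500) {
        k <- sample(2:4, 1)
        groups <- lapply(seq_len(k), function(j)
            sample(1:8, sample(3:8, 1), replace = TRUE))
        if (length(unique(unlist(groups))) == 1L) next
        expect_equal(unname(kruskalWallis(groups)$statistic),
            oracleKwH(groups), tolerance = 1e-12)
    }
})

test_that("H and p agree with the base R cross-check", {
    set.seed(71)
    for (i in 1:25) {
        groups <- lapply(1:3, function(j) rnorm(10))
        mine <- kruskalWallis(groups)
        ref <- kruskal.test(groups)
        expect_equal(unname(mine$statistic), unname(ref$statistic),
            tolerance = 1e-12)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    }
})

test_that("Dunn z and Bonferroni adjustment follow their definitions", {
    d <- dunnBonferroni(list(1:3, 4:6, 7:9))
    expect_equal(nrow(d), 3L)
    extreme <- d[d$group_i == "1" & d$group_j == "3", ]
    expect_equal(abs(extreme$z), 6 / sqrt(5), tolerance = 1e-12)
    expect_equal(d$p_adjusted, pmin(1, 3 * d$p_raw))
    expect_true(all(d$p_adjusted >= d$p_raw))
    same <- dunnBonferroni(list(rep(1, 3), rep(1, 3), rep(1, 3)))
    expect_equal(same$p_adjusted, rep(1, 3))
    # k groups give k(k-1)/2 pairwise rows
    d4 <- dunnBonferroni(lapply(1:4, function(i) rnorm(5)))
    expect_equal(nrow(d4), 6L)
})

test_that("U statistics match the pair-counting oracle", {
    expect_equal(unname(mannWhitney(1:3, 4:6)$statistic), 0)
    set.seed(73)
    for (i in 1:500) {
        a <- sample(1:10, sample(2:8, 1), replace = TRUE)
        b <- sample(1:10, sample(2:8, 1), replace = TRUE)
        expect_equal(unname(mannWhitney(a, b)$statistic), oracleU(a, b),
            tolerance = 1e-12)
    }
})

test_that("exact Mann-Whitney p matches enumeration and base R", {
    set.seed(79)
    for (i in 1:40) {
        a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
        mine <- mannWhitney(a, b)
        expect_match(mine$method, "exact")
        expect_equal(mine$p.value, oracleExactMwP(a, b), tolerance = 1e-12)
        expect_equal(mine$p.value, wilcox.test(a, b, exact = TRUE)$p.value,
            tolerance = 1e-12)
    }
    ident <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
    expect_equal(ident$p.value, 1)
})

test_that("rank tests are invariant under monotone transformation", {
    set.seed(83)
    x <- rnorm(12); y <- rnorm(12); z <- rnorm(12)
    mono <- function(v) exp(3 * v) + 1
    expect_equal(kruskalWallis(list(x, y, z))$statistic,
        kruskalWallis(list(mono(x), mono(y), mono(z)))$statistic)
    expect_equal(mannWhitney(x, y)$p.value,
        mannWhitney(mono(x), mono(y))$p.value)
    expect_equal(spearmanRank(x, y)$estimate,
        spearmanRank(mono(x), mono(y))$estimate)
})

test_that("Spearman rho matches its definition and the brute force", {
    expect_equal(unname(spearmanRank(1:3, c(6, 5, 4))$estimate), -1)
    expect_equal(unname(spearmanRank(1:5, exp(1:5))$estimate), 1)
    set.seed(89)
    for (i in 1:500) {
        n <- sample(4:12, 1)
        x <- sample(1:6, n, replace = TRUE)
        y <- sample(1:6, n, replace = TRUE)
        if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
        expect_equal(unname(spearmanRank(x, y)$estimate), oracleRho(x, y),
            tolerance = 1e-12)
    }
    flat <- spearmanRank(rep(1, 5), 1:5)
    expect_true(is.na(flat$estimate))
})

test_that("small-sample Spearman p is the exact permutation value", {
    set.seed(97)
    for (i in 1:10) {
        n <- sample(4:6, 1)
        x <- sample(100, n); y <- sample(100, n)
        mine <- spearmanRank(x, y)
        expect_match(mine$method, "permutation")
        expect_equal(mine$p.value, oracleExactSpearmanP(x, y),
            tolerance = 1e-12)
    }
})

test_that("tiny-group Kruskal-Wallis falls back to exact permutation", {
    g <- list(c(1, 5), c(2, 8), c(9, 3, 4))
    r <- kruskalWallis(g)
    expect_match(r$method, "permutation")
    expect_gte(r$p.value, 0)
    expect_lte(r$p.value, 1)
    # the permutation p is a valid tail probability of the observed H
    r2 <- kruskalWallis(g, pMethod = "chisq")
    expect_equal(unname(r$statistic), unname(r2$statistic))
})
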