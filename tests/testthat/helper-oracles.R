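# Independent oracles. Each deliberately recomputes its quantity by a
# different mechanism than the package implementation.

# Sleep bouts by exhaustive fixed-width windows: a minute is a sleep minute
# iff it lies inside some k-window of all-zero valid minutes; bouts are the
# maximal runs of such minutes.
oracleSleepBouts <- function(counts, k = 5, valid = rep(TRUE, length(counts))) {
    n <- length(counts)
    zero <- counts == 0 & valid
    inWin <- rep(FALSE, n)
    if (n >= k) {
        w <- stats::filter(as.numeric(zero), rep(1, k), sides = 1)
        for (e in which(!is.na(w) & w == k)) inWin[(e - k + 1):e] <- TRUE
    }
    r <- rle(inWin)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(startIndex = starts[r$values] - 1L,
        length = as.integer(r$lengths[r$values]))
}

# Kruskal-Wallis H via the general one-way rank ANOVA identity
# H = (N - 1) * sum(ni * (Rbar_i - Rbar)^2) / sum((r_ij - Rbar)^2),
# which absorbs ties without an explicit correction factor.
oracleKwH <- function(groups) {
    x <- unlist(groups)
    r <- rank(x)
    N <- length(x)
    g <- rep(seq_along(groups), lengths(groups))
    rb <- mean(r)
    num <- sum(tapply(r, g, function(v) length(v) * (mean(v) - rb)^2))
    den <- sum((r - rb)^2)
    (N - 1) * num / den
}

# Mann-Whitney U by direct pair counting.
oracleU <- function(a, b) {
    u1 <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    min(u1, length(a) * length(b) - u1)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to group a (no ties assumed).
oracleExactMwP <- function(a, b) {
    n1 <- length(a); N <- n1 + length(b)
    r <- rank(c(a, b))
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sets <- utils::combn(N, n1)
    us <- apply(sets, 2L, function(s) sum(seq_len(N)[s]) - n1 * (n1 + 1) / 2)
    m <- ncol(sets)
    min(1, 2 * min(sum(us <= u1) / m, sum(us >= u1) / m))
}

# Spearman rho via the explicit product-moment formula on midranks.
oracleRho <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exact two-sided Spearman permutation p using the no-ties identity
# rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)).
oracleExactSpearmanP <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    stopifnot(!anyDuplicated(rx), !anyDuplicated(ry))
    rhoOf <- function(p) 1 - 6 * sum((rx - ry[p])^2) / (n * (n^2 - 1))
    obs <- abs(rhoOf(seq_len(n)))
    perms <- oraclePermutations(n)
    mean(abs(apply(perms, 1L, rhoOf)) >= obs - 1e-12)
}

# Iterative (non-recursive) permutation generator, distinct from the
# package-internal recursive one.
oraclePermutations <- function(n) {
    out <- matrix(1L, 1L, 1L)
    for (m in 2:n) {
        prev <- out
        blocks <- lapply(seq_len(m), function(pos) {
            left <- prev[, seq_len(pos - 1L), drop = FALSE]
            right <- if (pos <= m - 1L)
                prev[, pos:(m - 1L), drop = FALSE]
                else prev[, 0, drop = FALSE]
            cbind(left, m, right)
        })
        out <- do.call(rbind, blocks)
    }
    out
}

# Piecewise-linear interpolation by explicit probe bracketing (manual
# search + lerp), clamped at the span ends.
oracleInterp <- function(probes, positions) {
    pr <- probes[order(probes$position), ]
    vapply(positions, function(p) {
        if (p <= pr$position[1L]) return(pr$temperatureC[1L])
        np <- nrow(pr)
        if (p >= pr$position[np]) return(pr$temperatureC[np])
        i <- 1L
        while (pr$position[i + 1L] < p) i <- i + 1L
        f <- (p - pr$position[i]) / (pr$position[i + 1L] - pr$position[i])
        pr$temperatureC[i] + f * (pr$temperatureC[i + 1L] - pr$temperatureC[i])
    }, numeric(1))
}
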