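#' Kruskal-Wallis rank-sum test (first principles)
#'
#' H is computed from midranks with the standard tie correction:
#' `H = (12 / (N (N + 1))) * sum(n_i * (Rbar_i - (N + 1) / 2)^2)`, divided
#' by `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`. The
#' p-value comes from the chi-squared distribution with `k - 1` degrees of
#' freedom, the standard identification under which H is reported as a
#' chi-squared statistic; an exact permutation p-value (full enumeration)
#' is used instead for tiny samples.
#'
#' @param groups list of >= 2 numeric vectors, each non-empty.
#' @param pMethod `"auto"` (permutation when N <= 10 and some group has
#'   fewer than 5 values, chi-squared otherwise), `"chisq"`, or
#'   `"permutation"` (total N <= 12).
#' @return An `htest`-style list with `statistic` (tie-corrected H),
#'   `parameter` (df), `p.value`, `n` (group sizes) and `notes`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskalWallis <- function(groups, pMethod = c("auto", "chisq",
                                              "permutation")) {
    pMethod <- match.arg(pMethod)
    .checkGroups(groups)
    ni <- lengths(groups)
    k <- length(groups)
    x <- unlist(groups, use.names = FALSE)
    N <- length(x)
    notes <- character(0)
    if (length(unique(x)) == 1L) {
        return(structure(list(
            statistic = c("Kruskal-Wallis H" = 0), parameter = c(df = k - 1),
            p.value = 1, method = "Kruskal-Wallis rank sum test",
            data.name = "groups", n = ni,
            notes = "degenerate: all values identical"), class = "htest"))
    }
    H <- .kwStatistic(x, ni)
    usePerm <- pMethod == "permutation" ||
        (pMethod == "auto" && N <= 10 && min(ni) < 5)
    if (usePerm) {
        if (N > 12) stop("permutation enumeration limited to N <= 12")
        perms <- .groupAssignments(ni)
        Hs <- vapply(perms, function(idx) .kwStatistic(x[idx], ni),
            numeric(1))
        p <- mean(Hs >= H - 1e-12)
        method <- "Kruskal-Wallis rank sum test (exact permutation)"
        notes <- c(notes, "exact permutation p")
    } else {
        p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
        method <- "Kruskal-Wallis rank sum test (chi-squared approximation)"
        if (any(duplicated(x))) notes <- c(notes, "ties: midranks used")
    }
    structure(list(statistic = c("Kruskal-Wallis H" = H),
        parameter = c(df = k - 1), p.value = p, method = method,
        data.name = "groups", n = ni, notes = notes), class = "htest")
}

.kwStatistic <- function(x, ni) {
    N <- length(x)
    r <- rank(x)
    ends <- cumsum(ni)
    starts <- ends - ni + 1L
    rbar <- vapply(seq_along(ni), function(i)
        mean(r[starts[i]:ends[i]]), numeric(1))
    H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
    t <- table(x)
    H / (1 - sum(t^3 - t) / (N^3 - N))
}

# All distinct assignments of N observations into groups of sizes ni,
# returned as index vectors ordered group-by-group.
.groupAssignments <- function(ni) {
    N <- sum(ni)
    rec <- function(avail, sizes) {
        if (length(sizes) == 0L) return(list(integer(0)))
        if (length(sizes) == 1L) return(list(avail))
        first <- avail[1L]  # fix the first element to kill duplicate orders
        out <- list()
        picks <- utils::combn(avail, sizes[1L], simplify = FALSE)
        for (p in picks) {
            rest <- rec(setdiff(avail, p), sizes[-1L])
            out <- c(out, lapply(rest, function(r) c(p, r)))
        }
        out
    }
    rec(seq_len(N), ni)
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' For each group pair after a Kruskal-Wallis test,
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - sum(t^3 - t) /
#' (12 (N - 1))) * (1 / n_i + 1 / n_j))` on the pooled midranks, with
#' two-sided normal p-values Bonferroni-adjusted over all `k (k - 1) / 2`
#' pairs.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param labels group labels (defaults to names or indices).
#' @return data.frame: `group_i`, `group_j`, `z`, `p_raw`, `p_adjusted`.
#' @examples
#' dunnBonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
dunnBonferroni <- function(groups, labels = NULL) {
    .checkGroups(groups)
    ni <- lengths(groups)
    k <- length(groups)
    if (is.null(labels))
        labels <- if (!is.null(names(groups))) names(groups)
                  else as.character(seq_len(k))
    x <- unlist(groups, use.names = FALSE)
    N <- length(x)
    r <- rank(x)
    ends <- cumsum(ni); starts <- ends - ni + 1L
    rbar <- vapply(seq_len(k), function(i) mean(r[starts[i]:ends[i]]),
        numeric(1))
    t <- table(x)
    sigma2 <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
    pairs <- utils::combn(k, 2L)
    m <- ncol(pairs)
    z <- p <- numeric(m)
    for (c in seq_len(m)) {
        i <- pairs[1L, c]; j <- pairs[2L, c]
        se <- sqrt(sigma2 * (1 / ni[i] + 1 / ni[j]))
        z[c] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
        p[c] <- 2 * stats::pnorm(-abs(z[c]))
    }
    data.frame(group_i = labels[pairs[1L, ]], group_j = labels[pairs[2L, ]],
        z = z, p_raw = p, p_adjusted = pmin(1, m * p), row.names = NULL)
}

#' Mann-Whitney U test (first principles)
#'
#' `U = min(U1, U2)` from pooled midranks. The p-value is exact (full
#' enumeration of the U distribution) when `n1 + n2 <= 20` and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @param alternative only `"two.sided"` is offered as default; one-sided
#'   alternatives are available but non-standard here.
#' @return An `htest`-style list with `statistic` (U), `p.value`, `n` and
#'   `notes`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$statistic   # U = 0
#' @export
mannWhitney <- function(a, b, alternative = c("two.sided", "less",
                                              "greater")) {
    alternative <- match.arg(alternative)
    if (length(a) == 0L || length(b) == 0L)
        stop("both samples must be non-empty")
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    x <- c(a, b)
    r <- rank(x)
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U2 <- n1 * n2 - U1
    U <- min(U1, U2)
    ties <- any(duplicated(x))
    notes <- character(0)
    if (N <= 20 && !ties) {
        freq <- .uDistribution(n1, n2)
        tot <- sum(freq)
        pLe <- sum(freq[seq_len(U1 + 1L)]) / tot          # P(U1 <= u1)
        pGe <- sum(freq[seq.int(U1 + 1L, n1 * n2 + 1L)]) / tot
        p <- switch(alternative,
            two.sided = min(1, 2 * min(pLe, pGe)),
            less = pLe, greater = pGe)
        method <- "Mann-Whitney U test (exact)"
        notes <- c(notes, "exact enumeration")
    } else {
        mu <- n1 * n2 / 2
        t <- table(x)
        sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
        if (sigma2 <= 0) {
            p <- 1
            notes <- c(notes, "degenerate: zero variance (all tied)")
        } else {
            z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
            if (U1 == mu) z <- 0
            p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
        }
        method <- "Mann-Whitney U test (normal approximation)"
        if (ties) notes <- c(notes, "ties: midranks, tie correction")
    }
    structure(list(statistic = c(U = U), p.value = p, method = method,
        data.name = "a vs b", n = c(n1, n2), notes = notes),
        class = "htest")
}

# Exact null frequencies of U1 over 0..n1*n2 (no ties), by the standard
# recursion c(n1, n2, u) = c(n1-1, n2, u-n2) + c(n1, n2-1, u).
.uDistribution <- function(n1, n2) {
    maxU <- n1 * n2
    # f[[i+1]][[j+1]] = frequency vector over u = 0..i*j
    f <- vector("list", n1 + 1L)
    for (i in 0:n1) {
        f[[i + 1L]] <- vector("list", n2 + 1L)
        for (j in 0:n2) {
            if (i == 0L || j == 0L) {
                f[[i + 1L]][[j + 1L]] <- 1
                next
            }
            v <- numeric(i * j + 1L)
            a <- f[[i]][[j + 1L]]       # c(i-1, j, u - j)
            v[seq_along(a) + j] <- v[seq_along(a) + j] + a
            b <- f[[i + 1L]][[j]]       # c(i, j-1, u)
            v[seq_along(b)] <- v[seq_along(b)] + b
            f[[i + 1L]][[j + 1L]] <- v
        }
    }
    f[[n1 + 1L]][[n2 + 1L]]
}

#' Spearman rank correlation (first principles)
#'
#' `rho` is the Pearson correlation of midranks. The p-value is an exact
#' permutation value (full enumeration) for `n <= 8` and the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#' Zero rank variance in either variable gives a flagged undefined result.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An `htest`-style list with `estimate` (rho), `p.value`, `n` and
#'   `notes`.
#' @examples
#' spearmanRank(1:3, c(6, 5, 4))$estimate   # -1
#' @export
spearmanRank <- function(x, y) {
    if (length(x) != length(y)) stop("x and y lengths differ")
    n <- length(x)
    if (n < 3L) stop("need n >= 3")
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
        return(structure(list(estimate = c(rho = NA_real_),
            p.value = NA_real_, method = "Spearman rank correlation",
            data.name = "x vs y", n = n,
            notes = "degenerate: zero rank variance"), class = "htest"))
    }
    rho <- stats::cor(rx, ry)
    notes <- character(0)
    if (n <= 8L) {
        perms <- .permutations(n)
        rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
        method <- "Spearman rank correlation (exact permutation)"
        notes <- c(notes, "exact permutation p")
    } else {
        tStat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
        p <- 2 * stats::pt(-abs(tStat), df = n - 2)
        method <- "Spearman rank correlation (t approximation)"
    }
    structure(list(estimate = c(rho = rho), p.value = min(p, 1),
        method = method, data.name = "x vs y", n = n, notes = notes),
        class = "htest")
}

.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    }))
}

.checkGroups <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need a list of >= 2 groups")
    if (any(lengths(groups) < 1L)) stop("every group must be non-empty")
    invisible(TRUE)
}
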