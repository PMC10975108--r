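# Nonparametric inference layer: rank correlations with covariate
# adjustment, rank-sum and k-group tests, Dunn's unequal-n multiple
# comparisons, ordered trend, rank two-way interaction, chi-square.
# All p-values are two-sided.

.rankTies <- function(x) {
  r <- rank(x, ties.method = "average")
  t <- as.numeric(table(r))
  list(ranks = r, tie_sizes = t)
}

#' Spearman rank correlation
#'
#' r_s is the Pearson correlation of average-ranked x and y; the two-sided
#' p-value uses the t approximation with n - 2 df.
#'
#' @param x,y paired numeric vectors, complete cases, n >= 3.
#' @return a [TestResult-class] with estimate `rs`.
#' @examples
#' pValue(spearmanTest(1:5, c(2, 1, 4, 3, 5)))
#' @export
spearmanTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (any(!ok)) {
    message(sum(!ok), " incomplete pair(s) dropped")
    x <- x[ok]; y <- y[ok]
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance: correlation undefined", call. = FALSE)
  rs <- cor(rx, ry)
  p <- .spearmanP(rs, n, df = n - 2)
  .TestResult("Spearman rank correlation",
              statistic = c(rs = rs), p = p,
              parameter = c(df = n - 2, n = n), estimate = c(rs = rs))
}

.spearmanP <- function(r, n, df) {
  if (abs(r) >= 1) return(0)
  tv <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tv), df = df)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms x, y and every covariate column (average ranks),
#' residualizes ranked x and ranked y on the ranked covariate matrix by
#' least squares with intercept, and correlates the residuals. The
#' two-sided p-value uses the t approximation with n - 2 - k df, k the
#' number of (effective) covariate columns. Categorical covariates must be
#' indicator-coded first (see [encodeCovariates()]). Collinear covariates
#' trigger a reduced-rank warning; the pivoted least-squares fit then acts
#' as a pseudo-inverse.
#'
#' @param x,y paired numeric vectors.
#' @param covariates numeric matrix or data.frame of covariate columns
#'   (may be `NULL` or zero-column: then this is exactly [spearmanTest()]).
#' @return a [TestResult-class] with estimate `rs_partial`.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0))
    return(spearmanTest(x, y))
  cv <- as.matrix(covariates)
  storage.mode(cv) <- "double"
  stopifnot(length(x) == length(y), nrow(cv) == length(x))
  ok <- complete.cases(x, y, cv)
  if (any(!ok)) {
    message(sum(!ok), " incomplete row(s) dropped")
    x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  }
  n <- length(x)
  k <- ncol(cv)
  if (n <= k + 2) stop("need n > k + 2 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rcv <- apply(cv, 2, rank)
  Q <- cbind(1, rcv)
  fit <- lm.fit(Q, cbind(rx, ry))
  if (fit$rank < ncol(Q)) {
    warning("collinear covariates: effective rank ", fit$rank - 1,
            " of ", k, "; pivoted fit used", call. = FALSE)
    k <- fit$rank - 1
  }
  res <- fit$residuals
  # residual rank variation at or below numerical noise means the
  # covariates explain x or y completely: nothing is left to correlate
  tol <- 1e-10 * n
  degenerate <- sd(res[, 1]) <= tol || sd(res[, 2]) <= tol
  rs <- if (degenerate) 0 else cor(res[, 1], res[, 2])
  df <- n - 2 - k
  p <- .spearmanP(rs, n, df = df)
  .TestResult("Partial Spearman rank correlation",
              statistic = c(rs_partial = rs), p = p,
              parameter = c(df = df, n = n, k = k),
              estimate = c(rs_partial = rs))
}

#' Indicator-code categorical covariates
#'
#' Builds a numeric covariate matrix from a data.frame, expanding factor
#' and character columns into treatment indicators with the first level as
#' reference.
#'
#' @param df covariate `data.frame`.
#' @return numeric matrix with one column per numeric covariate or
#'   non-reference factor level.
#' @export
encodeCovariates <- function(df) {
  stopifnot(is.data.frame(df))
  if (ncol(df) == 0) return(matrix(numeric(0), nrow(df), 0))
  df[] <- lapply(df, function(col)
    if (is.character(col) || is.logical(col)) factor(col) else col)
  mm <- model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic W (sum of joint ranks of the first sample) with the
#' tie-corrected normal approximation, two-sided. For combined samples of
#' at most `exactMax` observations the null distribution is enumerated
#' over all label assignments (valid under ties) and the two-sided p is
#' the probability of a deviation |W - E(W)| at least as large as
#' observed.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exactMax enumerate exactly when `length(a) + length(b)` is at
#'   most this (default 12).
#' @return a [TestResult-class] with statistic `W` (and `z` for the
#'   normal path).
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 12) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  if (N <= exactMax) {
    sums <- combn(N, na, function(i) sum(r[i]))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(.TestResult("Wilcoxon rank-sum (exact)",
                       statistic = c(W = W), p = p,
                       parameter = c(n_a = na, n_b = nb)))
  }
  t <- as.numeric(table(r))
  v <- na * nb / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  z <- if (v > 0) (W - mu) / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  .TestResult("Wilcoxon rank-sum (normal approximation)",
              statistic = c(W = W, z = z), p = p,
              parameter = c(n_a = na, n_b = nb))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 df
#' (delegates the statistic to [stats::kruskal.test()]); attaches
#' median (P25, P75) summaries per group.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return a [TestResult-class] with statistic `H`.
#' @export
kruskalWallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need >= 2 non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(seq_along(groups), lengths(groups)))
  gs <- .groupSummaryTable(x, lab)
  gs$group <- names(groups) %||% as.character(seq_along(groups))
  if (length(unique(x)) == 1)
    return(.TestResult("Kruskal-Wallis", statistic = c(H = 0), p = 1,
                       parameter = c(df = length(groups) - 1), groups = gs))
  kt <- kruskal.test(x, lab)
  .TestResult("Kruskal-Wallis",
              statistic = c(H = unname(kt$statistic)),
              p = kt$p.value,
              parameter = c(df = unname(kt$parameter)),
              groups = gs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dunn's test for unequal sample sizes
#'
#' Post-hoc pairwise comparisons on joint ranks following Kruskal-Wallis.
#' For groups i, j: `z = (Rbar_i - Rbar_j) / sqrt(V * (1/n_i + 1/n_j))`
#' with `V = N(N+1)/12 - sum(t^3 - t)/(12(N-1))` (joint-rank variance with
#' tie correction). Unadjusted two-sided p-values are multiplicity-adjusted
#' over all k(k-1)/2 pairs (Bonferroni by default, Holm optional), capped
#' at 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups; >= 3 for a
#'   genuinely multiple comparison).
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return list of [TestResult-class], one per pair, each labelled
#'   `"i vs j"`; adjusted p in `p.value`, raw p in `parameter["p_raw"]`.
#' @export
dunnTest <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2 || any(!lengths(groups)))
    stop("need >= 2 non-empty groups", call. = FALSE)
  nms <- names(groups) %||% as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  t <- as.numeric(table(r))
  V <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  rbar <- tapply(r, lab, mean)
  n <- lengths(groups)
  pairs <- combn(k, 2)
  zs <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(V * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  praw <- ifelse(zs == 0 & V == 0, 1, 2 * pnorm(-abs(zs)))
  padj <- p.adjust(praw, method = if (adjust == "none") "none" else adjust)
  out <- lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    .TestResult("Dunn's test",
                statistic = c(z = zs[c2]), p = padj[c2],
                parameter = c(p_raw = praw[c2], n_i = n[i], n_j = n[j]),
                adjusted = adjust != "none",
                label = paste(nms[i], "vs", nms[j]))
  })
  names(out) <- vapply(out, function(t2) t2@label, character(1))
  out
}

# Jonckheere-Terpstra building blocks -------------------------------------

.jtStatistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, function(a, b) (b > a) + 0.5 * (b == a))
    s <- s + sum(cmp)
  }
  s
}

#' Jonckheere-Terpstra trend test
#'
#' Ordered-alternative rank test across k >= 3 ordered groups: the JT
#' statistic counts cross-group pairs concordant with the group order
#' (ties counted one half). The tie-corrected normal approximation gives a
#' two-sided p; for combined n at most `exactMax` the permutation null is
#' enumerated over all multiset arrangements and the two-sided p is the
#' deviation probability.
#'
#' @param groups ordered list of numeric vectors, smallest-risk first.
#' @param exactMax total-n bound for exact enumeration (default 10).
#' @return a [TestResult-class] with statistic `JT` (and `z`).
#' @export
trendTest <- function(groups, exactMax = 10) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3)
    stop("trend test needs >= 3 ordered groups; use wilcoxonRankSum for 2",
         call. = FALSE)
  if (any(!lengths(groups))) stop("empty group", call. = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  JT <- .jtStatistic(groups)
  mu <- (N^2 - sum(n^2)) / 4
  if (N <= exactMax) {
    x <- unlist(groups, use.names = FALSE)
    subsets <- .multisetAssignments(N, n)
    devs <- vapply(subsets, function(idx) {
      gs <- split(x[idx], rep(seq_along(n), n))
      abs(.jtStatistic(gs) - mu)
    }, numeric(1))
    p <- mean(devs >= abs(JT - mu) - 1e-9)
    return(.TestResult("Jonckheere-Terpstra (exact)",
                       statistic = c(JT = JT), p = p,
                       parameter = c(n = N)))
  }
  t <- as.numeric(table(rank(unlist(groups, use.names = FALSE))))
  v <- (N * (N - 1) * (2 * N + 5) -
          sum(n * (n - 1) * (2 * n + 5)) -
          sum(t * (t - 1) * (2 * t + 5))) / 72 +
    sum(n * (n - 1) * (n - 2)) * sum(t * (t - 1) * (t - 2)) /
      (36 * N * (N - 1) * (N - 2)) +
    sum(n * (n - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
  z <- if (v > 0) (JT - mu) / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  .TestResult("Jonckheere-Terpstra (normal approximation)",
              statistic = c(JT = JT, z = z), p = p, parameter = c(n = N))
}

# All orderings of 1..N into consecutive blocks of sizes n (as index
# vectors); enumeration of distinct assignments of positions to groups.
.multisetAssignments <- function(N, n) {
  recurse <- function(avail, sizes) {
    if (!length(sizes)) return(list(integer(0)))
    picks <- combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- recurse(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  recurse(seq_len(N), n)
}

#' Scheirer-Ray-Hare rank interaction test
#'
#' Two-way rank-based test: the outcome is jointly ranked, a two-way
#' fixed-effects ANOVA decomposition (sequential sums of squares) is run
#' on the ranks, and each effect's statistic is its sum of squares divided
#' by the total mean square of the ranks, referred to chi-square. Only the
#' interaction term is reported here, on (a-1)(b-1) df.
#'
#' @param outcome numeric vector.
#' @param factor_a,factor_b crossed grouping labels; every cell must be
#'   non-empty.
#' @return a [TestResult-class] with statistic `H_interaction`.
#' @export
rankInteraction <- function(outcome, factor_a, factor_b) {
  ok <- complete.cases(outcome, factor_a, factor_b)
  outcome <- outcome[ok]
  A <- droplevels(factor(factor_a[ok]))
  B <- droplevels(factor(factor_b[ok]))
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]),
         call. = FALSE)
  }
  N <- length(outcome)
  df <- (nlevels(A) - 1) * (nlevels(B) - 1)
  r <- rank(outcome)
  ssTot <- sum((r - mean(r))^2)
  if (ssTot == 0)
    return(.TestResult("Scheirer-Ray-Hare interaction",
                       statistic = c(H_interaction = 0), p = 1,
                       parameter = c(df = df, n = N)))
  msTot <- ssTot / (N - 1)
  an <- anova(lm(r ~ A * B))
  ssInt <- an["A:B", "Sum Sq"]
  H <- ssInt / msTot
  .TestResult("Scheirer-Ray-Hare interaction",
              statistic = c(H_interaction = H),
              p = pchisq(H, df = df, lower.tail = FALSE),
              parameter = c(df = df, n = N))
}

#' Pearson chi-square test on a contingency table
#'
#' Drops zero-margin rows/columns with a warning, applies the Pearson
#' chi-square with (r-1)(c-1) df and no continuity correction, and logs a
#' small-cell warning when any expected count is below 5.
#'
#' @param table matrix of non-negative counts.
#' @return a [TestResult-class] with statistic `chisq`.
#' @export
chiSquareTable <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || sum(tab) < 1)
    stop("counts must be non-negative with positive total", call. = FALSE)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2x2 table after dropping zero margins",
         call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count(s) below 5: chi-square approximation may be poor",
            call. = FALSE)
  .TestResult("Pearson chi-square",
              statistic = c(chisq = unname(ct$statistic)),
              p = ct$p.value,
              parameter = c(df = unname(ct$parameter)))
}

#' Rank-regression R-squared
#'
#' R^2 of the least-squares fit of ranked y on ranked x; identically the
#' square of the Spearman correlation. The scale on which a PRS "explains"
#' variation of an outcome under rank regression.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return R^2 in \[0, 1\].
#' @export
rankRSquared <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance", call. = FALSE)
  cor(rx, ry)^2
}
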