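# Inference layer: hand-derived values, independent oracles and rank
# invariances.

test_that("Spearman matches hand-ranked computation and base R", {
  expect_equal(unname(statValue(spearmanTest(1:3, 3:1))["rs"]), -1)
  expect_equal(unname(statValue(spearmanTest(1:10, 1:10))["rs"]), 1)
  # d^2 = (1,1,1,1,0): rs = 1 - 6*4/(5*24) = 0.8
  r <- spearmanTest(1:5, c(2, 1, 4, 3, 5))
  expect_equal(unname(statValue(r)["rs"]), 0.8)
  set.seed(51)
  x <- rnorm(40); y <- rnorm(40)
  mine <- spearmanTest(x, y)
  base <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(unname(statValue(mine)["rs"]), unname(base$estimate))
  expect_equal(pValue(mine), base$p.value, tolerance = 1e-10)
  expect_error(spearmanTest(rep(1, 5), 1:5), "zero rank variance")
})

test_that("partial Spearman reduces, vanishes and matches the oracle", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pValue(partialSpearman(x, y, NULL)),
               pValue(spearmanTest(x, y)))
  # both monotone in one covariate, no noise: partial correlation ~ 0
  z <- sort(rnorm(40))
  r0 <- partialSpearman(exp(z), z^3 + z, cbind(z = z))
  expect_lt(abs(unname(statValue(r0))), 1e-10)
  # random instances against the explicit projection oracle
  for (i in 1:20) {
    n <- sample(10:50, 1)
    k <- sample(1:3, 1)
    x <- rnorm(n); y <- rnorm(n)
    cv <- matrix(rnorm(n * k), n, k)
    expect_equal(unname(statValue(partialSpearman(x, y, cv))),
                 partialSpearmanOracle(x, y, cv), tolerance = 1e-10)
  }
})

test_that("partial Spearman is near zero under conditional independence", {
  set.seed(53)
  n <- 10000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- -z + rnorm(n)
  expect_lt(abs(unname(statValue(partialSpearman(x, y, cbind(z))))), 0.05)
})

test_that("collinear covariates warn and fall back gracefully", {
  set.seed(54)
  x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
  expect_warning(r <- partialSpearman(x, y, cbind(z, 2 * z)), "collinear")
  expect_equal(unname(statValue(r)),
               unname(statValue(partialSpearman(x, y, cbind(z)))),
               tolerance = 1e-10)
})

test_that("rank-sum test: exact enumeration and tie-corrected normal", {
  r <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(unname(statValue(r)["W"]), 3)
  expect_equal(pValue(r), 1 / 3)
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pValue(same), 1)
  # monotone-transform invariance
  set.seed(55)
  a <- rnorm(20); b <- rnorm(25) + 0.5
  expect_equal(pValue(wilcoxonRankSum(exp(a), exp(b))),
               pValue(wilcoxonRankSum(a, b)))
  # agreement with wilcox.test (no ties, no continuity correction)
  base <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(pValue(wilcoxonRankSum(a, b)), base$p.value,
               tolerance = 1e-10)
  baseEx <- wilcox.test(c(5, 7, 9), c(1, 2, 3, 4), exact = TRUE)
  expect_equal(pValue(wilcoxonRankSum(c(5, 7, 9), c(1, 2, 3, 4))),
               baseEx$p.value)
})

test_that("Kruskal-Wallis hand value, degenerate case and 2-group identity", {
  k <- kruskalWallis(list(c(1, 2), c(3, 4)))
  expect_equal(unname(statValue(k)["H"]), 2.4)
  expect_equal(pValue(kruskalWallis(list(rep(2, 4), rep(2, 5)))), 1)
  # k = 2: H equals squared tie-corrected rank-sum z
  set.seed(56)
  a <- round(rnorm(30), 1); b <- round(rnorm(20) + 0.3, 1)
  H <- unname(statValue(kruskalWallis(list(a, b)))["H"])
  z <- unname(statValue(wilcoxonRankSum(a, b, exactMax = 0))["z"])
  expect_equal(H, z^2, tolerance = 1e-10)
  expect_error(kruskalWallis(list(1:3)), "2 non-empty")
})

test_that("Dunn pairwise z, adjustment and null behavior", {
  d <- dunnTest(list(g1 = c(1, 2), g2 = c(3, 4)))
  expect_equal(unname(statValue(d[[1]])["z"]), -2 / sqrt(5 / 3))
  expect_equal(unname(statValue(d[[1]])["z"]), -1.5492, tolerance = 1e-4)
  dEq <- dunnTest(list(a = c(1, 4), b = c(2, 3)))
  expect_equal(unname(statValue(dEq[[1]])["z"]), 0)
  expect_equal(pValue(dEq[[1]]), 1)
  # Bonferroni familywise error under the null is conservative
  set.seed(57)
  rej <- vapply(1:2000, function(i) {
    g <- split(rnorm(60), rep(1:3, each = 20))
    any(vapply(dunnTest(g), pValue, numeric(1)) < 0.05)
  }, logical(1))
  fwer <- mean(rej)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("trend test statistic, exact p and tie midpoint", {
  jt <- trendTest(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(statValue(jt)["JT"]), 12)
  # of the 90 assignments only the perfectly increasing and perfectly
  # decreasing ones deviate this far: p = 2/90
  expect_equal(pValue(jt), 2 / 90, tolerance = 1e-9)
  same <- trendTest(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(pValue(same), 1)
  # exact p against a from-scratch permutation oracle
  groups <- list(c(1, 3), c(2, 4), c(5, 6))
  x <- unlist(groups)
  n <- lengths(groups)
  mu <- (sum(n)^2 - sum(n^2)) / 4
  obs <- jtOracle(groups)
  labs <- rep(seq_along(n), n)
  perms <- allLabelPermutations(labs)
  devs <- vapply(perms, function(p) {
    abs(jtOracle(split(x, p)) - mu)
  }, numeric(1))
  pOracle <- mean(devs >= abs(obs - mu) - 1e-9)
  expect_equal(pValue(trendTest(groups)), pOracle, tolerance = 1e-9)
  expect_error(trendTest(list(1:3, 4:6)), "3 ordered groups")
})

test_that("trend statistic matches the naive oracle on larger samples", {
  set.seed(58)
  groups <- list(rnorm(15), rnorm(20) + 0.3, rnorm(12) + 0.6)
  expect_equal(unname(statValue(trendTest(groups))["JT"]),
               jtOracle(groups))
})

test_that("rank interaction test: degenerate input, null, power", {
  const <- rankInteraction(rep(1, 24), rep(1:3, 8), rep(1:2, 12))
  expect_equal(unname(statValue(const)), 0)
  expect_equal(pValue(const), 1)
  expect_error(rankInteraction(rnorm(4), c(1, 1, 2, 2), c(1, 1, 2, 2)),
               "empty design cell")
  # planted crossover interaction at large n is detected
  set.seed(59)
  n <- 900
  A <- rep(1:3, each = n / 3)
  B <- rep(rep(1:2, each = n / 6), 3)
  y <- rnorm(n) + ifelse((A == 1) == (B == 1), 1, -1)
  expect_lt(pValue(rankInteraction(y, A, B)), 0.001)
  # additive effects alone do not trigger it
  y2 <- rnorm(n) + 0.5 * A + 0.8 * B
  expect_gt(pValue(rankInteraction(y2, A, B)), 0.001)
})

test_that("chi-square table: hand values, scaling and guards", {
  expect_equal(unname(statValue(chiSquareTable(matrix(10, 2, 2)))), 0)
  expect_equal(pValue(chiSquareTable(matrix(10, 2, 2))), 1)
  t2 <- matrix(c(20, 0, 0, 20), 2, 2)
  r2 <- suppressWarnings(chiSquareTable(t2))
  expect_equal(unname(statValue(r2)), 40)
  expect_equal(unname(r2@parameter["df"]), 1)
  r3 <- suppressWarnings(chiSquareTable(3 * t2))
  expect_equal(unname(statValue(r3)), 120)
  expect_warning(chiSquareTable(rbind(t2 + 5, c(0, 0))), "zero row")
  expect_warning(chiSquareTable(matrix(c(2, 3, 1, 4), 2)), "below 5")
})

test_that("rank R-squared is the squared Spearman correlation", {
  expect_equal(rankRSquared(1:10, exp(1:10)), 1)
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  expect_equal(rankRSquared(x, y), 0.8^2)
  set.seed(60)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(rankRSquared(a, b), 0.002)
})

test_that("rank procedures are invariant under increasing transforms", {
  set.seed(61)
  x <- rnorm(50); y <- rnorm(50)
  g <- split(rnorm(60), rep(1:3, each = 20))
  expect_equal(pValue(spearmanTest(exp(x), exp(y))),
               pValue(spearmanTest(x, y)))
  expect_equal(pValue(kruskalWallis(lapply(g, exp))),
               pValue(kruskalWallis(g)))
  expect_equal(pValue(trendTest(lapply(g, exp))), pValue(trendTest(g)))
  expect_equal(rankRSquared(exp(x), exp(y)), rankRSquared(x, y))
})
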