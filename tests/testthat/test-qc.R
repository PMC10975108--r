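# Genotype QC: MAF, missing rate, the Hardy-Weinberg exact test and the
# filter chain.

test_that("MAF is computed from called genotypes and folded", {
  expect_equal(computeMaf(c(0, 0, 1, 2)), 0.375)
  expect_equal(computeMaf(c(0, 0, 0)), 0)
  expect_equal(computeMaf(c(0, NA, 2)), 0.5)
  expect_equal(computeMaf(c(2, 2, 2, 1)), 1 - 7 / 8)
  expect_error(computeMaf(c(NA, NA)), "missing")
})

test_that("missing rate counts NA fraction", {
  expect_equal(missingRate(c(0, 1, 2, NA)), 0.25)
  expect_equal(missingRate(rep(NA_real_, 4)), 1)
  expect_equal(missingRate(c(0, 1)), 0)
})

test_that("HWE exact test matches hand enumeration on tiny tables", {
  expect_equal(hweExactTest(0, 0, 7), 1)       # monomorphic
  expect_equal(hweExactTest(3, 0, 0), 1)
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)   # 2 subjects, alleles (2,2)
  expect_error(hweExactTest(-1, 0, 1), "non-negative")
  # (25,50,25): equals the full enumeration at n = 100
  expect_equal(hweExactTest(25, 50, 25), hweOracleP(25, 50, 25))
})

test_that("exact test agrees with the log-factorial oracle over a grid", {
  set.seed(401)
  for (rep in 1:300) {
    n <- sample(1:50, 1)
    nAA <- sample(0:n, 1)
    nAB <- sample(0:(n - nAA), 1)
    nBB <- n - nAA - nAB
    expect_equal(hweExactTest(nAA, nAB, nBB), hweOracleP(nAA, nAB, nBB),
                 tolerance = 1e-10)
  }
})

test_that("exact and chi-square paths agree in decision under HWE", {
  # balanced draws at n = 5000: both should (essentially always) accept
  set.seed(402)
  agree <- vapply(1:200, function(i) {
    p <- runif(1, 0.1, 0.5)
    g <- sample(0:2, 5000, replace = TRUE,
                prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    cts <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    pe <- hweExactTest(cts[1], cts[2], cts[3])
    pc <- hweExactTest(cts[1], cts[2], cts[3], method = "chisq")
    (pe < 1e-6) == (pc < 1e-6)
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("QC chain orders filters and partitions verdicts", {
  sim <- makePreset("qc_stress", seed = 1)
  rep <- applyQcChain(sim$genotypes)
  tab <- qcTable(rep)
  counts <- table(factor(tab$verdict,
                         c("pass", "fail_missing", "fail_maf", "fail_hwe")))
  expect_equal(sum(counts), 85)
  expect_equal(unname(counts[["fail_missing"]]), 9)
  expect_equal(unname(counts[["fail_maf"]]), 8)
  expect_equal(unname(counts[["fail_hwe"]]), 13)
  expect_equal(length(retainedSnps(rep)), 55)
  # retained order preserves input order
  expect_identical(retainedSnps(rep),
                   tab$snp_id[tab$verdict == "pass"])
  # idempotence: re-running on the retained submatrix excludes nothing
  g2 <- keepRetained(sim$genotypes, rep)
  rep2 <- applyQcChain(g2)
  expect_equal(length(excludedSnps(rep2)), 0)
})

test_that("clean matrices and vacuous thresholds pass everything", {
  panel <- toyPanel(rep(0, 5), mafs = rep(0.3, 5))
  g <- genGenotypes(panel, 300, seed = 8)
  expect_equal(length(excludedSnps(applyQcChain(g))), 0)
  gm <- genGenotypes(panel, 300, missingRate = 0.5, seed = 9)
  repv <- applyQcChain(gm, mafMin = 0, hwePMin = 0, missingMax = 1)
  tab <- qcTable(repv)
  expect_true(all(tab$verdict[tab$n_called >= 1] == "pass"))
  expect_error(applyQcChain(matrix(numeric(0), 0, 0)), "empty")
})

test_that("lowering the MAF threshold never shrinks the retained set", {
  sim <- makePreset("qc_stress", seed = 5)
  r1 <- applyQcChain(sim$genotypes, mafMin = 0.05)
  r2 <- applyQcChain(sim$genotypes, mafMin = 0.01)
  r3 <- applyQcChain(sim$genotypes, mafMin = 0)
  expect_lte(length(retainedSnps(r1)), length(retainedSnps(r2)))
  expect_lte(length(retainedSnps(r2)), length(retainedSnps(r3)))
})
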