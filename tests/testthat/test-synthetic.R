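# Synthetic-cohort generator: determinism, genotype model fidelity,
# marginals and planted effects.

test_that("panel generation honors cardinality, uniqueness and the seed", {
  p <- genSnpPanel(55, mafRange = c(0.05, 0.5), betaScale = 0.02, seed = 1)
  expect_equal(nrow(p), 55)
  expect_false(anyDuplicated(p$snp_id) > 0)
  expect_true(all(p$effect_allele != p$other_allele))
  expect_true(all(p$source_maf >= 0.05 & p$source_maf <= 0.5))
  expect_identical(p, genSnpPanel(55, c(0.05, 0.5), 0.02, seed = 1))
  expect_equal(nrow(genSnpPanel(1, seed = 3)), 1)
  expect_error(genSnpPanel(5, mafRange = c(0.2, 0.6)), "mafRange")
  # signed weights: both signs present in a panel of realistic size
  expect_true(any(p$beta > 0) && any(p$beta < 0))
})

test_that("genotype model follows the inbreeding parameterization", {
  panel <- toyPanel(rep(0.01, 4), mafs = c(0.1, 0.2, 0.3, 0.4))
  gF1 <- genGenotypes(panel, 500, inbreedingF = 1, seed = 2)
  expect_false(any(dosageMatrix(gF1) == 1))
  # F = 0, p = 0.3: frequencies of dosage (2,1,0) near (0.09, 0.42, 0.49)
  panel1 <- toyPanel(0.01, mafs = 0.3)
  g <- genGenotypes(panel1, 10000, seed = 5)
  d <- dosageMatrix(g)[1, ]
  expected <- c(`0` = 0.49, `1` = 0.42, `2` = 0.09)
  for (k in names(expected)) {
    phat <- mean(d == as.numeric(k))
    tol <- 3 * sqrt(expected[[k]] * (1 - expected[[k]]) / 10000)
    expect_lt(abs(phat - expected[[k]]), tol)
  }
  expect_false(anyNA(dosageMatrix(g)))
  gm <- genGenotypes(panel1, 200, missingRate = 0.3, seed = 6)
  expect_gt(mean(is.na(dosageMatrix(gm))), 0.15)
  expect_identical(dosageMatrix(gm),
                   dosageMatrix(genGenotypes(panel1, 200,
                                             missingRate = 0.3, seed = 6)))
})

test_that("simulated genotypes under HWE pass the exact test", {
  panel <- toyPanel(rep(0, 40), mafs = runif(40, 0.05, 0.5))
  g <- genGenotypes(panel, 1000, seed = 11)
  d <- dosageMatrix(g)
  ps <- apply(d, 1, function(col)
    hweExactTest(sum(col == 2), sum(col == 1), sum(col == 0)))
  expect_true(all(ps > 1e-6))
})

test_that("subject marginals match their targets", {
  s <- genSubjects(10000, vitdMedian = 33.63, seed = 7)
  med <- median(s$vitd)
  expect_gt(med, 32.5)
  expect_lt(med, 34.8)
  expect_true(all(s$age_months >= 44 & s$age_months <= 80))
  expect_true(all(s$sex %in% c("male", "female")))
  expect_equal(nrow(genSubjects(1, seed = 1)), 1)
  expect_identical(genSubjects(50, seed = 9), genSubjects(50, seed = 9))
})

test_that("phenotype planting hits its rank-correlation targets", {
  lms <- syntheticLmsReference()
  panel <- genSnpPanel(20, seed = 21)
  g <- genGenotypes(panel, 10000, seed = 22)
  s <- genSubjects(10000, seed = 23)
  # null effects: |r_s| below the ~4/sqrt(n) null band
  s0 <- genPhenotypes(s, g, panel, lms, effectPrs = 0, effectVitd = 0,
                      seed = 24)
  expect_lt(abs(cor(rank(s0$prs_true), rank(s0$zbmi_true))), 0.05)
  # planted 0.10: inside the Fisher-z band at n = 10000
  s1 <- genPhenotypes(s, g, panel, lms, effectPrs = 0.10, effectVitd = 0,
                      seed = 25)
  r <- cor(rank(s1$prs_true), rank(s1$zbmi_true))
  expect_gt(r, 0.07)
  expect_lt(r, 0.13)
  # noise-free, PRS-only: perfect monotone map
  s2 <- genPhenotypes(s, g, panel, lms, effectPrs = 1, effectVitd = 0,
                      noiseSd = 0, seed = 26)
  expect_equal(cor(rank(s2$prs_true), rank(s2$zbmi_true)), 1)
  # misaligned ids
  bad <- s
  bad$subject_id <- rev(bad$subject_id)
  expect_error(genPhenotypes(bad, g, panel, lms), "aligned")
})

test_that("planted effects average to target across replicates", {
  lms <- syntheticLmsReference()
  rs <- vapply(1:40, function(i) {
    panel <- genSnpPanel(20, seed = i)
    g <- genGenotypes(panel, 1046, seed = i + 1000)
    s <- genSubjects(1046, seed = i + 2000)
    s <- genPhenotypes(s, g, panel, lms, effectPrs = 0.10,
                       effectVitd = -0.11, seed = i + 3000)
    cor(rank(s$prs_true), rank(s$zbmi_true))
  }, numeric(1))
  # MC SE of the mean ~ 0.03/sqrt(40) ~ 0.005
  expect_lt(abs(mean(rs) - 0.10), 0.02)
})

test_that("presets have the engineered structure and are reproducible", {
  sim <- makePreset("qc_stress", seed = 3)
  expect_equal(nrow(sim$panel), 85)
  d <- dosageMatrix(sim$genotypes)
  expect_equal(dim(d), c(85, 1046))
  expect_equal(sum(apply(d, 1, function(x) all(is.na(x)))), 9)
  coh <- makePreset("study_cohort", seed = 3)
  expect_equal(dim(dosageMatrix(coh$genotypes)), c(55, 1046))
  expect_true(all(c("weight", "height", "zbmi_true", "prs_true") %in%
                    names(coh$subjects)))
  coh2 <- makePreset("study_cohort", seed = 3)
  expect_identical(coh$subjects, coh2$subjects)
  expect_error(makePreset("nope"), "arg")
})
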