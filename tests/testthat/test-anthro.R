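# LMS anthropometry: BMI, z-score with restricted adjustment, inverse,
# reference lookup, cohort scoring.

test_that("BMI is weight over squared height in metres", {
  expect_equal(computeBmi(16, 100), 16)
  expect_equal(computeBmi(20, 110), 20 / 1.21)
  expect_error(computeBmi(0, 100), "positive")
  expect_error(computeBmi(16, -5), "positive")
})

test_that("z-score hits the closed-form cases", {
  expect_equal(lmsZscore(16, L = -1.5, M = 16, S = 0.1), 0)
  expect_equal(lmsZscore(17.6, L = 1, M = 16, S = 0.1), 1)
  # L -> 0 limit: Box-Cox and log forms agree
  z1 <- lmsZscore(18, L = 1e-6, M = 16, S = 0.09)
  z2 <- log(18 / 16) / 0.09
  expect_equal(z1, z2, tolerance = 1e-6)
  expect_error(lmsZscore(-1, 1, 16, 0.1), "positive")
})

test_that("restricted adjustment branches and inverse round-trip", {
  L <- -1.5; M <- 16; S <- 0.09
  zs <- seq(-5, 5, by = 0.25)
  X <- lmsInverse(zs, L, M, S)
  expect_equal(lmsZscore(X, L, M, S), zs, tolerance = 1e-9)
  # closed forms on the restricted branch
  sd3 <- M * (1 + L * S * 3)^(1 / L)
  sd2 <- M * (1 + L * S * 2)^(1 / L)
  expect_equal(lmsInverse(4, L, M, S), sd3 + (sd3 - sd2))
  expect_equal(lmsInverse(0, L, M, S), M)
  expect_equal(lmsInverse(1.5, 1, M, S), M * (1 + S * 1.5))
})

test_that("z is continuous and strictly increasing across the seams", {
  L <- -1.6; M <- 15.5; S <- 0.085
  for (zb in c(-3, 3)) {
    xb <- lmsInverse(zb, L, M, S)
    lo <- lmsZscore(xb * (1 - 1e-9), L, M, S)
    hi <- lmsZscore(xb * (1 + 1e-9), L, M, S)
    expect_lt(abs(lmsZscore(xb, L, M, S) - zb), 1e-12)
    expect_lt(lo, hi)
  }
  xs <- seq(8, 30, by = 0.05)
  zs <- lmsZscore(xs, L, M, S)
  expect_true(all(diff(zs) > 0))
})

test_that("reference lookup uses the completed-month rule", {
  ref <- syntheticLmsReference()
  r60 <- lookupLms(ref, "male", 60)
  expect_identical(lookupLms(ref, "male", 60.4), r60)
  expect_identical(lookupLms(ref, "male", 60.6),
                   lookupLms(ref, "male", 61))
  expect_error(lookupLms(ref, "male", 200), "outside")
  expect_error(lookupLms(ref, "female", 20), "outside")
})

test_that("cohort scoring recovers planted z and skips incomplete rows", {
  sim <- makePreset("study_cohort", seed = 6)
  res <- suppressMessages(zbmiForCohort(sim$subjects, sim$lms))
  expect_lt(max(abs(res$zbmi - sim$subjects$zbmi_true)), 1e-9)
  # subject at the reference median scores zero
  ref <- syntheticLmsReference()
  trip <- lookupLms(ref, "female", 50)
  one <- data.frame(subject_id = "x", sex = "female", age_months = 50,
                    height = 100, weight = trip$M * 1.0)
  expect_equal(suppressMessages(zbmiForCohort(one, ref))$zbmi, 0)
  # missing height: skipped with reason
  two <- data.frame(subject_id = c("a", "b"), sex = "male",
                    age_months = 60, height = c(105, NA),
                    weight = c(17, 16))
  out <- suppressMessages(zbmiForCohort(two, ref))
  expect_true(is.na(out$zbmi[2]))
  expect_equal(attr(out, "skipped")$subject_id, "b")
})

test_that("sex and age act only through the LMS triple", {
  ref <- syntheticLmsReference()
  t1 <- lookupLms(ref, "male", 48)
  t2 <- lookupLms(ref, "female", 72)
  x <- 15.2
  expect_equal(lmsZscore(x, t1$L, t1$M, t1$S),
               lmsZscore(x, t1$L, t1$M, t1$S))
  expect_false(isTRUE(all.equal(lmsZscore(x, t1$L, t1$M, t1$S),
                                lmsZscore(x, t2$L, t2$M, t2$S))))
})
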