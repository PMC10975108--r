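# Seeded synthetic-cohort generator: SNP weight panels, HWE (or
# inbreeding-perturbed) genotypes, subject tables with a log-normal
# 25(OH)D marginal, and phenotypes with planted rank-correlation effects.
# All randomness flows from one integer seed via .childSeed() so that
# module-level draws are independent streams.

#' Generate a synthetic SNP weight panel
#'
#' Draws `m` biallelic SNPs with unique ids, effect/other alleles, effect
#' sizes symmetric about zero on the GWAS per-allele scale, and an
#' effect-allele frequency uniform on `mafRange`. Weights are signed:
#' a BMI GWAS reports both risk and protective alleles, and an all-positive
#' panel could never produce the negative score medians seen with the
#' rescaled PRS.
#'
#' @param m number of SNPs (>= 1).
#' @param mafRange length-2 interval inside (0, 0.5] for the effect-allele
#'   frequency (default `c(0.05, 0.5)`).
#' @param betaScale standard deviation of the normal effect-size draw
#'   (default 0.02, typical of BMI GWAS per-allele betas).
#' @param seed integer seed.
#' @return `data.frame` with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `source_maf`.
#' @export
genSnpPanel <- function(m, mafRange = c(0.05, 0.5), betaScale = 0.02,
                        seed = 1) {
  m <- .assertScalarCount(m, "m")
  if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must be an interval inside (0, 0.5]", call. = FALSE)
  if (betaScale <= 0) stop("betaScale must be positive", call. = FALSE)
  set.seed(.childSeed(seed, 101))
  bases <- c("A", "C", "G", "T")
  eff <- sample(bases, m, replace = TRUE)
  oth <- vapply(eff, function(e) sample(setdiff(bases, e), 1), character(1))
  panel <- data.frame(
    snp_id = sprintf("rs%07d", sample.int(9999999, m)),
    effect_allele = eff,
    other_allele = unname(oth),
    beta = rnorm(m, 0, betaScale),
    source_maf = runif(m, mafRange[1], mafRange[2]),
    stringsAsFactors = FALSE)
  validateSnpPanel(panel)
  panel
}

#' Simulate genotype dosages for a panel
#'
#' Per SNP with effect-allele frequency p and inbreeding coefficient F,
#' genotype probabilities are `p^2 + F p q` (dosage 2), `2 p q (1 - F)`
#' (dosage 1) and `q^2 + F p q` (dosage 0) — Hardy-Weinberg proportions at
#' F = 0, a heterozygote deficit as F grows. Entries are then masked
#' missing independently at the SNP's missing rate.
#'
#' @param panel SNP panel from [genSnpPanel()] (needs `source_maf`).
#' @param n number of subjects.
#' @param inbreedingF per-SNP inbreeding coefficient in \[0, 1\]
#'   (recycled; default 0).
#' @param missingRate per-SNP missing probability in \[0, 1\] (recycled;
#'   default 0).
#' @param seed integer seed.
#' @return a [SnpGenotypes-class], SNPs x subjects, panel in `rowData`.
#' @export
genGenotypes <- function(panel, n, inbreedingF = 0, missingRate = 0,
                         seed = 1) {
  validateSnpPanel(panel)
  if (!"source_maf" %in% names(panel))
    stop("panel needs a source_maf column to simulate from", call. = FALSE)
  n <- .assertScalarCount(n, "n")
  m <- nrow(panel)
  FF <- rep_len(.assertProb(inbreedingF, "inbreedingF"), m)
  mr <- rep_len(.assertProb(missingRate, "missingRate"), m)
  set.seed(.childSeed(seed, 202))
  d <- matrix(NA_real_, m, n,
              dimnames = list(panel$snp_id, sprintf("S%05d", seq_len(n))))
  for (j in seq_len(m)) {
    p <- panel$source_maf[j]
    q <- 1 - p
    probs <- c(q^2 + FF[j] * p * q,      # dosage 0
               2 * p * q * (1 - FF[j]),  # dosage 1
               p^2 + FF[j] * p * q)      # dosage 2
    g <- sample(0:2, n, replace = TRUE, prob = probs)
    if (mr[j] > 0) g[runif(n) < mr[j]] <- NA
    d[j, ] <- g
  }
  SnpGenotypes(d, panel = panel)
}

#' Generate a synthetic subject table
#'
#' Draws demographic and covariate marginals typical of a rural Chinese
#' preschool cohort: sex Bernoulli(0.5); age uniform on 44-80 months;
#' serum 25(OH)D log-normal with the given median (sdlog 0.32, matching a
#' right-skewed IQR of roughly 27-41 ng/mL at the default median); birth
#' size, delivery mode, breastfeeding, supplement use, caregiver education
#' and a socio-economic score with realistic marginals. Covariates are
#' generated independently of genotype (no confounding) unless
#' `confounded = TRUE`, which tilts supplement use and SES with 25(OH)D.
#'
#' @param n number of subjects.
#' @param vitdMedian median of the 25(OH)D distribution in ng/mL
#'   (default 33.63).
#' @param seed integer seed.
#' @param confounded logical; off by default.
#' @return `data.frame`, one row per subject.
#' @export
genSubjects <- function(n, vitdMedian = 33.63, seed = 1,
                        confounded = FALSE) {
  n <- .assertScalarCount(n, "n")
  if (vitdMedian <= 0) stop("vitdMedian must be positive", call. = FALSE)
  set.seed(.childSeed(seed, 303))
  sdlog <- 0.32
  vitd <- exp(rnorm(n, log(vitdMedian), sdlog))
  df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_months = runif(n, 44, 80),
    vitd = vitd,
    birth_length = rnorm(n, 50.1, 1.4),
    birth_weight = rnorm(n, 3260, 400),
    premature = sample(c("Yes", "No"), n, TRUE, prob = c(0.037, 0.963)),
    delivery = sample(c("Unknown", "Vaginal", "Caesarean"), n, TRUE,
                      prob = c(0.011, 0.604, 0.385)),
    only_child = sample(c("Unknown", "Yes", "No"), n, TRUE,
                        prob = c(0.031, 0.133, 0.836)),
    breastfeeding = sample(c("Yes", "No"), n, TRUE, prob = c(0.896, 0.104)),
    vitd_supplement = sample(c("Yes", "No"), n, TRUE,
                             prob = c(0.034, 0.966)),
    yyb = sample(c("Yes", "No"), n, TRUE, prob = c(0.498, 0.502)),
    parental_care = sample(c("Yes", "No"), n, TRUE, prob = c(0.718, 0.282)),
    caregiver_edu = sample(
      c("Primary school or below", "Junior middle school",
        "High school or above"), n, TRUE, prob = c(0.293, 0.496, 0.211)),
    ses = rnorm(n, 47.8, 4.4),
    stringsAsFactors = FALSE)
  if (confounded) {
    # supplement users and higher-SES families run slightly higher 25(OH)D
    bump <- 0.15 * (df$vitd_supplement == "Yes") +
      0.05 * scale(df$ses)[, 1]
    df$vitd <- df$vitd * exp(bump)
  }
  df
}

# Normal scores (rank-based inverse-normal transform), ties averaged.
.normalScores <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Plant phenotype effects and derive anthropometry
#'
#' Builds a latent zBMI with configurable rank-correlation targets: the
#' latent z combines normal scores of the subject's true PRS and of
#' 25(OH)D with independent Gaussian noise, using coefficients
#' `2 sin(pi r / 6)` — the bivariate-normal inversion of the
#' Spearman/Pearson map — so the realized Spearman correlations match the
#' requested `effectPrs` and `effectVitd`. Weight and height are then set
#' by inverting the LMS reference at the latent z, so re-scoring the
#' cohort recovers the planted z exactly.
#'
#' @param subjects table from [genSubjects()].
#' @param genotypes [SnpGenotypes-class] aligned with `subjects`
#'   (same ids, same order).
#' @param panel SNP weight panel.
#' @param lms LMS reference table covering the cohort's ages.
#' @param effectPrs target Spearman correlation of the true PRS with zBMI
#'   (default 0.10).
#' @param effectVitd target Spearman correlation of 25(OH)D with zBMI
#'   (default -0.11).
#' @param noiseSd `NULL` (default) scales noise so Var(z) = 1; `0` gives
#'   a deterministic z (requires the two effect loadings to be scaled up
#'   to unit variance, done automatically).
#' @param seed integer seed.
#' @return `subjects` with added columns `height`, `weight`, `zbmi_true`,
#'   `prs_true`.
#' @export
genPhenotypes <- function(subjects, genotypes, panel, lms,
                          effectPrs = 0.10, effectVitd = -0.11,
                          noiseSd = NULL, seed = 1) {
  stopifnot(is(genotypes, "SnpGenotypes"))
  if (!identical(as.character(subjects$subject_id), subjectIds(genotypes)))
    stop("subject ids of table and genotypes are not aligned", call. = FALSE)
  validateLmsReference(lms)
  n <- nrow(subjects)
  set.seed(.childSeed(seed, 404))
  prs <- suppressMessages(computePrs(genotypes, panel))
  if (any(prs$unscorable))
    stop("cannot plant effects: unscorable subjects present", call. = FALSE)
  aP <- 2 * sin(pi * effectPrs / 6)
  aV <- 2 * sin(pi * effectVitd / 6)
  if (aP^2 + aV^2 > 1 + 1e-12)
    stop("effect targets too large: loadings exceed unit variance",
         call. = FALSE)
  sigma <- if (is.null(noiseSd)) sqrt(max(0, 1 - aP^2 - aV^2)) else noiseSd
  if (sigma == 0 && aP^2 + aV^2 > 0) {
    # renormalize loadings so Var(z) = 1 in the noise-free case
    s <- sqrt(aP^2 + aV^2)
    aP <- aP / s; aV <- aV / s
  }
  z <- aP * .normalScores(prs$score) + aV * .normalScores(subjects$vitd) +
    sigma * rnorm(n)
  height <- 70 + 0.62 * subjects$age_months + rnorm(n, 0, 2.5)
  month <- floor(subjects$age_months + 0.5)
  key <- paste(subjects$sex, month)
  uk <- !duplicated(key)
  trip <- lapply(which(uk), function(i)
    lookupLms(lms, subjects$sex[i], subjects$age_months[i]))
  names(trip) <- key[uk]
  L <- vapply(trip[key], `[[`, numeric(1), "L")
  M <- vapply(trip[key], `[[`, numeric(1), "M")
  S <- vapply(trip[key], `[[`, numeric(1), "S")
  bmi <- lmsInverse(z, L, M, S)
  subjects$height <- height
  subjects$weight <- bmi * (height / 100)^2
  subjects$zbmi_true <- z
  subjects$prs_true <- prs$score
  subjects
}

#' Built-in simulation presets
#'
#' `study_cohort`: 1046 subjects genotyped at 55 clean SNPs with planted
#' effects of +0.10 (true PRS vs zBMI) and -0.11 (25(OH)D vs zBMI) — the
#' validation cohort for effect-recovery checks.
#'
#' `qc_stress`: 85 candidate SNPs of which 8 have population effect-allele
#' frequency 0.002 (sample MAF below 1% with overwhelming probability at
#' n = 1046), 13 have inbreeding F = 0.9 (HWE exact p far below 1e-6), 9
#' are fully missing, and 55 are well-behaved — so the default QC chain
#' retains exactly the 55 clean SNPs.
#'
#' @param name `"study_cohort"` or `"qc_stress"`.
#' @param seed integer seed.
#' @return named list with `panel`, `genotypes`, `subjects`, `lms`.
#' @export
makePreset <- function(name = c("study_cohort", "qc_stress"), seed = 1) {
  name <- match.arg(name)
  lms <- syntheticLmsReference()
  n <- 1046
  if (name == "study_cohort") {
    panel <- genSnpPanel(55, mafRange = c(0.05, 0.5), betaScale = 0.02,
                         seed = .childSeed(seed, 1))
    genotypes <- genGenotypes(panel, n, seed = .childSeed(seed, 2))
    subjects <- genSubjects(n, vitdMedian = 33.63,
                            seed = .childSeed(seed, 3))
    subjects <- genPhenotypes(subjects, genotypes, panel, lms,
                              effectPrs = 0.10, effectVitd = -0.11,
                              seed = .childSeed(seed, 4))
    return(list(panel = panel, genotypes = genotypes, subjects = subjects,
                lms = lms))
  }
  # qc_stress: 55 clean + 8 rare + 13 HWE-departed + 9 fully missing,
  # interleaved deterministically across the panel
  m <- 85
  panel <- genSnpPanel(m, mafRange = c(0.1, 0.5), betaScale = 0.02,
                       seed = .childSeed(seed, 5))
  set.seed(.childSeed(seed, 6))
  slots <- sample(rep(c("clean", "rare", "hwe", "missing"),
                      c(55, 8, 13, 9)))
  panel$source_maf[slots == "rare"] <- 0.002
  FF <- ifelse(slots == "hwe", 0.9, 0)
  mr <- ifelse(slots == "missing", 1, 0)
  genotypes <- genGenotypes(panel, n, inbreedingF = FF, missingRate = mr,
                            seed = .childSeed(seed, 7))
  subjects <- genSubjects(n, vitdMedian = 33.63, seed = .childSeed(seed, 8))
  list(panel = panel, genotypes = genotypes, subjects = subjects, lms = lms)
}

#' Synthetic LMS reference table
#'
#' A smooth synthetic BMI-for-age LMS reference for both sexes over 36-84
#' months, shaped like real preschool references (median BMI dipping
#' toward the adiposity rebound then rising; mild negative skew power;
#' coefficient of variation near 8-9%). It is a stand-in for validation
#' and simulation — not a measurement standard; real WHO tables are
#' drop-in replacements via the same CSV schema (see
#' [readLmsReference()]).
#'
#' @return `data.frame` with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
syntheticLmsReference <- function() {
  age <- 36:84
  grid <- expand.grid(age_months = age, sex = c("male", "female"),
                      stringsAsFactors = FALSE)[, c("sex", "age_months")]
  a <- grid$age_months
  male <- grid$sex == "male"
  # median dips to ~15.3 near 62 months, slight sex offset
  grid$M <- 15.35 + 0.00045 * (a - 62)^2 + ifelse(male, 0.10, -0.05)
  grid$L <- -1.6 + 0.004 * (a - 60) + ifelse(male, 0.05, 0)
  grid$S <- 0.082 + 0.0002 * (a - 36) + ifelse(male, 0.002, 0)
  grid <- grid[order(grid$sex, grid$age_months), ]
  rownames(grid) <- NULL
  validateLmsReference(grid)
  grid
}
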