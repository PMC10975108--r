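# End-to-end analysis: QC -> PRS -> risk groups -> zBMI -> vitamin D
# status -> outlier filter -> descriptive and inferential tables.

#' Classify vitamin D status
#'
#' Serum 25(OH)D at or below the cutoff is insufficient; above it is
#' sufficient. The boundary is inclusive on the insufficient side
#' (25(OH)D = 30 ng/mL is insufficient at the default cutoff).
#'
#' @param vitd serum 25(OH)D in ng/mL (>= 0); vectorized.
#' @param cutoff ng/mL, default 30.
#' @return factor with levels `insufficient`, `sufficient`.
#' @examples
#' classifyVitd(c(30, 30.01))
#' @export
classifyVitd <- function(vitd, cutoff = 30) {
  if (any(is.na(vitd)) || any(vitd < 0))
    stop("25(OH)D must be non-negative and non-missing", call. = FALSE)
  factor(ifelse(vitd <= cutoff, "insufficient", "sufficient"),
         levels = c("insufficient", "sufficient"))
}

#' Flag subjects outside mean +/- k SD
#'
#' Single pass: for each monitored continuous variable, the mean and SD
#' are computed on the pre-filter sample and any subject falling outside
#' mean +/- `kSd` SD on any monitored variable is excluded. A
#' zero-variance variable excludes nobody (with a warning).
#'
#' @param data `data.frame` containing the monitored variables.
#' @param vars character vector of column names to monitor.
#' @param kSd multiplier, default 4; `Inf` disables the filter.
#' @return list with `kept` (row indices), `excluded` (row indices) and
#'   `reasons` (data.frame of subject row, variable, value).
#' @export
filterOutliers <- function(data, vars, kSd = 4) {
  stopifnot(all(vars %in% names(data)))
  out <- rep(FALSE, nrow(data))
  reasons <- data.frame(row = integer(), variable = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  for (v in vars) {
    x <- data[[v]]
    if (sum(!is.na(x)) < 2) stop("need >= 2 non-missing values in ", v,
                                 call. = FALSE)
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (s == 0) {
      warning("zero variance in ", v, ": nothing excluded", call. = FALSE)
      next
    }
    bad <- !is.na(x) & abs(x - mu) > kSd * s
    if (any(bad))
      reasons <- rbind(reasons, data.frame(
        row = which(bad), variable = v, value = x[bad],
        stringsAsFactors = FALSE))
    out <- out | bad
  }
  list(kept = which(!out), excluded = which(out), reasons = reasons)
}

#' Summarize one variable the way the tables report it
#'
#' Continuous variables: median (P25, P75) by linear-interpolation
#' quartiles. Categorical: count (percent to one decimal; percents may
#' not total 100 due to rounding).
#'
#' @param values vector.
#' @param type `"continuous"` or `"categorical"`.
#' @return `data.frame`: one row (`median`, `p25`, `p75`) for continuous;
#'   one row per level (`level`, `n`, `percent`, `text`) for categorical.
#' @export
summarizeDescriptives <- function(values, type = c("continuous",
                                                   "categorical")) {
  type <- match.arg(type)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  if (type == "continuous") {
    q <- .p50p25p75(values)
    return(data.frame(median = q[1], p25 = q[2], p75 = q[3],
                      text = sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3]),
                      row.names = NULL))
  }
  tab <- table(values)
  pct <- round(100 * as.numeric(tab) / length(values), 1)
  data.frame(level = names(tab), n = as.integer(tab), percent = pct,
             text = sprintf("%d (%.1f)", as.integer(tab), pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Analysis configuration
#'
#' Thresholds and covariate rosters for [runAnalysis()], with the study
#' defaults: MAF >= 1%, HWE exact p >= 1e-6, missing rate <= 5%,
#' vitamin D cutoff 30 ng/mL, 10%/10% risk tails, mean +/- 4 SD outlier
#' rule on zBMI and 25(OH)D, alpha 0.05. Model II adjusts for age, sex,
#' birth length and birth weight; model III further adjusts for the
#' remaining covariates.
#'
#' @param mafMin,hwePMin,missingMax QC thresholds.
#' @param vitdCutoff ng/mL boundary for vitamin D status.
#' @param lowFraction,highFraction risk-group tail fractions.
#' @param outlierSd k of the mean +/- k SD exclusion.
#' @param outlierVars variables monitored by the outlier rule.
#' @param alpha two-sided significance level (recorded, not enforced).
#' @param modelII,modelIII covariate column names for the adjusted
#'   correlation models; `modelII` must be a subset of `modelIII`.
#' @return named list of settings.
#' @export
analysisConfig <- function(mafMin = 0.01, hwePMin = 1e-6, missingMax = 0.05,
                           vitdCutoff = 30, lowFraction = 0.10,
                           highFraction = 0.10, outlierSd = 4,
                           outlierVars = c("zbmi", "vitd"), alpha = 0.05,
                           modelII = c("age_months", "sex", "birth_length",
                                       "birth_weight"),
                           modelIII = c("age_months", "sex", "birth_length",
                                        "birth_weight", "premature",
                                        "delivery", "only_child",
                                        "breastfeeding", "vitd_supplement",
                                        "yyb", "parental_care",
                                        "caregiver_edu", "ses")) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, hwePMin >= 0, hwePMin <= 1,
            missingMax >= 0, missingMax <= 1, vitdCutoff > 0,
            lowFraction > 0, lowFraction < 0.5,
            highFraction > 0, highFraction < 0.5,
            outlierSd > 0, alpha > 0, alpha < 1)
  if (!all(modelII %in% modelIII))
    stop("model II covariates must be a subset of model III", call. = FALSE)
  list(mafMin = mafMin, hwePMin = hwePMin, missingMax = missingMax,
       vitdCutoff = vitdCutoff, lowFraction = lowFraction,
       highFraction = highFraction, outlierSd = outlierSd,
       outlierVars = outlierVars, alpha = alpha,
       modelII = modelII, modelIII = modelIII)
}

.modelCovariates <- function(df, roster) {
  have <- intersect(roster, names(df))
  if (!length(have)) return(NULL)
  encodeCovariates(df[have])
}

#' Run the full analysis pipeline
#'
#' QC-filters the SNPs, computes the rescaled PRS and decile risk groups,
#' scores zBMI against the LMS reference, classifies vitamin D status,
#' applies the mean +/- 4 SD outlier filter, and builds the four result
#' tables: descriptives by risk group with global tests; Spearman
#' correlations of PRS, 25(OH)D and zBMI under models I/II/III; zBMI by
#' risk group (with Dunn pairs) and by vitamin D status; and the
#' stratified subgroup table with the ordered trend test within
#' vitamin-D-sufficient children and the rank interaction test.
#'
#' @param genotypes [SnpGenotypes-class] for the full candidate panel.
#' @param subjects subject `data.frame` (ids aligned with `genotypes`),
#'   with anthropometry, 25(OH)D and covariates.
#' @param lms LMS reference table.
#' @param panel optional SNP weight panel (defaults to
#'   `rowData(genotypes)`).
#' @param config list from [analysisConfig()].
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return a [RunReport-class].
#' @export
runAnalysis <- function(genotypes, subjects, lms, panel = NULL,
                        config = analysisConfig(), seed = 1L) {
  stopifnot(is(genotypes, "SnpGenotypes"))
  if (!identical(as.character(subjects$subject_id), subjectIds(genotypes)))
    stop("subject ids of table and genotypes are not aligned", call. = FALSE)
  nInvited <- nrow(subjects)

  qc <- applyQcChain(genotypes, mafMin = config$mafMin,
                     hwePMin = config$hwePMin,
                     missingMax = config$missingMax)
  gRet <- keepRetained(genotypes, qc)
  if (!is.null(panel)) panel <- panel[panel$snp_id %in% rownames(gRet), ]

  prs <- suppressMessages(computePrs(gRet, panel))
  anth <- suppressMessages(zbmiForCohort(subjects, lms))

  df <- subjects
  df$score <- prs$score[match(df$subject_id, prs$subject_id)]
  df$unscorable <- prs$unscorable[match(df$subject_id, prs$subject_id)]
  df$zbmi <- anth$zbmi[match(df$subject_id, anth$subject_id)]
  df$bmi <- anth$bmi[match(df$subject_id, anth$subject_id)]

  dropUnscorable <- which(df$unscorable | is.na(df$score))
  dropAnthro <- setdiff(which(is.na(df$zbmi)), dropUnscorable)
  keep <- setdiff(seq_len(nrow(df)), c(dropUnscorable, dropAnthro))
  df <- df[keep, , drop = FALSE]

  filt <- filterOutliers(df, intersect(config$outlierVars, names(df)),
                         kSd = config$outlierSd)
  nOutlier <- length(filt$excluded)
  df <- df[filt$kept, , drop = FALSE]
  if (nrow(df) == 0) stop("no subjects left after exclusions", call. = FALSE)

  df$risk_group <- classifyRisk(df$score, config$lowFraction,
                                config$highFraction)
  df$vitd_status <- classifyVitd(df$vitd, config$vitdCutoff)

  flow <- c(invited = nInvited,
            excluded_unscorable = length(dropUnscorable),
            excluded_anthropometry = length(dropAnthro),
            excluded_outlier = nOutlier,
            analyzed = nrow(df))

  tables <- list(
    descriptives = .tableDescriptives(df),
    correlations = .tableCorrelations(df, config),
    group_comparisons = .tableGroups(df),
    subgroup_comparisons = .tableSubgroups(df)
  )

  rep <- new("RunReport", flow = as.integer(flow), qc = qc, data = df,
             tables = tables, config = config, seed = as.integer(seed))
  names(rep@flow) <- names(flow)
  rep
}

# Descriptives by risk group with global tests (KW for continuous,
# chi-square for categorical).
.tableDescriptives <- function(df) {
  cont <- intersect(c("age_months", "birth_length", "birth_weight", "ses",
                      "score", "vitd", "zbmi"), names(df))
  cat_ <- intersect(c("sex", "premature", "delivery", "only_child",
                      "breastfeeding", "vitd_supplement", "yyb",
                      "parental_care", "caregiver_edu"), names(df))
  byGroup <- split(seq_len(nrow(df)), df$risk_group)
  rows <- list()
  for (v in cont) {
    groups <- lapply(byGroup, function(i) df[[v]][i])
    kw <- kruskalWallis(groups)
    rows[[v]] <- list(variable = v, type = "continuous",
                      overall = summarizeDescriptives(df[[v]], "continuous"),
                      by_group = groupSummaries(kw), test = kw)
  }
  for (v in cat_) {
    tab <- table(df[[v]], df$risk_group)
    ct <- tryCatch(chiSquareTable(tab), error = function(e) NULL)
    rows[[v]] <- list(variable = v, type = "categorical",
                      overall = summarizeDescriptives(df[[v]], "categorical"),
                      counts = tab, test = ct)
  }
  rows
}

# Spearman models I/II/III for the three variable pairs.
.tableCorrelations <- function(df, config) {
  pairs <- list(c("score", "vitd"), c("score", "zbmi"), c("vitd", "zbmi"))
  cov2 <- .modelCovariates(df, config$modelII)
  cov3 <- .modelCovariates(df, config$modelIII)
  out <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "~")
    out[[key]] <- list(
      model_I = spearmanTest(df[[p[1]]], df[[p[2]]]),
      model_II = partialSpearman(df[[p[1]]], df[[p[2]]], cov2),
      model_III = partialSpearman(df[[p[1]]], df[[p[2]]], cov3))
  }
  out
}

# zBMI by risk group (KW + Dunn pairs) and by vitamin D status (Wilcoxon).
.tableGroups <- function(df) {
  byRisk <- split(df$zbmi, df$risk_group)
  byVitd <- split(df$zbmi, df$vitd_status)
  list(
    zbmi_by_risk = kruskalWallis(byRisk),
    zbmi_by_risk_pairs = dunnTest(byRisk),
    zbmi_by_vitd = wilcoxonRankSum(byVitd$insufficient, byVitd$sufficient),
    vitd_status_n = as.data.frame(table(status = df$vitd_status),
                                  responseName = "n"))
}

# Stratified comparisons, trend within sufficiency, and interaction.
.tableSubgroups <- function(df) {
  out <- list()
  for (g in levels(df$risk_group)) {
    sub <- df[df$risk_group == g, ]
    byV <- split(sub$zbmi, sub$vitd_status)
    out[[paste0("vitd_within_", g)]] <- list(
      test = wilcoxonRankSum(byV$insufficient, byV$sufficient),
      summaries = .groupSummaryTable(sub$zbmi, sub$vitd_status))
  }
  for (s in levels(df$vitd_status)) {
    sub <- df[df$vitd_status == s, ]
    byR <- split(sub$zbmi, sub$risk_group)
    out[[paste0("risk_within_", s)]] <- list(
      test = kruskalWallis(byR),
      pairs = dunnTest(byR),
      summaries = .groupSummaryTable(sub$zbmi, sub$risk_group))
  }
  suff <- df[df$vitd_status == "sufficient", ]
  out$trend_risk_within_sufficient <-
    trendTest(split(suff$zbmi, suff$risk_group))
  out$interaction <- rankInteraction(df$zbmi, df$risk_group, df$vitd_status)
  out
}
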