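#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor lm.fit median pchisq pnorm pt quantile rbinom rnorm
#'   runif sd setNames complete.cases qnorm anova lm as.formula model.matrix
#'   p.adjust kruskal.test chisq.test
#' @importFrom utils combn head read.csv write.csv read.delim write.table
NULL

#' SnpGenotypes: a genotype dosage container
#'
#' An S4 container for biallelic SNP genotypes, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are SNPs, columns are
#' subjects, and the single assay `"dosage"` holds effect-allele copy counts
#' in \{0, 1, 2\} with `NA` for missing calls. SNP metadata (effect allele,
#' other allele, per-allele effect size `beta`, and any simulation truth)
#' lives in `rowData`; subject metadata may live in `colData`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [SnpGenotypes()] for construction, [dosageMatrix()],
#'   [snpInfo()], [applyQcChain()], [computePrs()].
#' @export
setClass("SnpGenotypes", contains = "SummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    vals <- d[!is.na(d)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "subject ids (colnames) must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param dosage numeric matrix of effect-allele dosages, SNPs in rows and
#'   subjects in columns; values 0/1/2/NA. Must carry row and column names,
#'   or a `panel` / `subjectIds` to supply them.
#' @param panel optional SNP panel `data.frame` (see [genSnpPanel()]) whose
#'   `snp_id` matches the rows; stored in `rowData`.
#' @param subjects optional subject `data.frame` with a `subject_id` column
#'   matching the columns; stored in `colData`.
#'
#' @return a [SnpGenotypes-class] object.
#' @examples
#' panel <- genSnpPanel(3, seed = 1)
#' g <- genGenotypes(panel, n = 5, seed = 1)
#' dosageMatrix(g)
#' @export
SnpGenotypes <- function(dosage, panel = NULL, subjects = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.null(panel)) {
    validateSnpPanel(panel)
    if (is.null(rownames(dosage))) rownames(dosage) <- panel$snp_id
    stopifnot(identical(rownames(dosage), panel$snp_id))
  }
  if (!is.null(subjects)) {
    if (is.null(colnames(dosage))) colnames(dosage) <- subjects$subject_id
    stopifnot(identical(colnames(dosage), as.character(subjects$subject_id)))
  }
  rd <- if (is.null(panel)) S4Vectors::DataFrame(row.names = rownames(dosage))
        else S4Vectors::DataFrame(panel[setdiff(names(panel), "snp_id")],
                                  row.names = panel$snp_id)
  cd <- if (is.null(subjects)) S4Vectors::DataFrame(row.names = colnames(dosage))
        else S4Vectors::DataFrame(subjects, row.names = subjects$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("SnpGenotypes", se)
}

#' QcReport: result of the SNP quality-control chain
#'
#' Per-SNP call statistics and verdicts from [applyQcChain()]. Verdicts
#' partition the panel into `pass`, `fail_missing`, `fail_maf` and
#' `fail_hwe`; `retained` preserves the input SNP order.
#'
#' @slot table `data.frame` with columns `snp_id`, `n_called`,
#'   `missing_rate`, `maf`, `hwe_p`, `verdict`.
#' @slot retained character vector of passing SNP ids, in input order.
#' @slot excluded character vector of failing SNP ids, in input order.
#' @slot thresholds named numeric vector (`maf_min`, `hwe_p_min`,
#'   `missing_max`).
#' @export
setClass("QcReport", representation(
  table = "data.frame",
  retained = "character",
  excluded = "character",
  thresholds = "numeric"
))

setValidity("QcReport", function(object) {
  tab <- object@table
  need <- c("snp_id", "n_called", "missing_rate", "maf", "hwe_p", "verdict")
  if (!all(need %in% names(tab))) return("QC table missing required columns")
  if (!all(tab$verdict %in% c("pass", "fail_missing", "fail_maf", "fail_hwe")))
    return("unknown verdict")
  if (!setequal(object@retained, tab$snp_id[tab$verdict == "pass"]))
    return("retained set must equal the pass set")
  ok <- !is.na(tab$maf)
  if (any(tab$maf[ok] > 0.5 + 1e-12)) return("maf must be <= 0.5")
  TRUE
})

#' TestResult: a single statistical test outcome
#'
#' Uniform container returned by the inference-layer functions
#' ([spearmanTest()], [wilcoxonRankSum()], [kruskalWallis()],
#' [dunnTest()], [trendTest()], [rankInteraction()], [chiSquareTable()]).
#'
#' @slot method test name.
#' @slot statistic named numeric statistic (e.g. `rs`, `H`, `z`, `chisq`).
#' @slot parameter named numeric nuisance parameters (df, n, ...).
#' @slot p.value two-sided p-value in \[0, 1\].
#' @slot estimate named numeric estimates (e.g. the correlation).
#' @slot groups `data.frame` of group summaries (n, median, P25, P75),
#'   possibly empty.
#' @slot adjusted logical; `TRUE` when `p.value` is multiplicity-adjusted.
#' @slot label free-text comparison label (e.g. `"low vs high"`).
#' @export
setClass("TestResult", representation(
  method = "character",
  statistic = "numeric",
  parameter = "numeric",
  p.value = "numeric",
  estimate = "numeric",
  groups = "data.frame",
  adjusted = "logical",
  label = "character"
))

setValidity("TestResult", function(object) {
  p <- object@p.value
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1 + 1e-12)
    return("p.value must be a single number in [0, 1]")
  TRUE
})

.TestResult <- function(method, statistic, p, parameter = numeric(),
                        estimate = numeric(), groups = data.frame(),
                        adjusted = FALSE, label = NA_character_) {
  new("TestResult", method = method, statistic = statistic,
      parameter = parameter, p.value = min(1, max(0, p)),
      estimate = estimate, groups = groups, adjusted = adjusted,
      label = label)
}

#' RunReport: the full pipeline output
#'
#' Returned by [runAnalysis()]. Bundles the inclusion flowchart, the QC
#' report, the analysis-ready subject table (scores, risk groups, zBMI,
#' vitamin D status) and the result tables.
#'
#' @slot flow named integer vector of inclusion-flowchart counts.
#' @slot qc a [QcReport-class].
#' @slot data analysis `data.frame`, one row per analyzed subject.
#' @slot tables named list of result tables (descriptives, correlations,
#'   group comparisons, subgroup comparisons), each holding
#'   [TestResult-class] objects and/or summary `data.frame`s.
#' @slot config named list: the [analysisConfig()] used.
#' @slot seed integer seed recorded for provenance.
#' @export
setClass("RunReport", representation(
  flow = "integer",
  qc = "QcReport",
  data = "data.frame",
  tables = "list",
  config = "list",
  seed = "integer"
))
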