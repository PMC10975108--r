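#' Accessors for SnpGenotypes, QcReport, TestResult and RunReport
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x the object.
#' @name accessors
NULL

#' @describeIn accessors the SNPs-by-subjects dosage matrix (0/1/2/NA).
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @export
setMethod("dosageMatrix", "SnpGenotypes", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn accessors the SNP panel as a plain `data.frame`
#'   (`snp_id` plus `rowData` columns).
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setMethod("snpInfo", "SnpGenotypes", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(data.frame(snp_id = rownames(x), stringsAsFactors = FALSE),
        rd, row.names = NULL)
})

#' @describeIn accessors subject identifiers.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @export
setMethod("subjectIds", "SnpGenotypes", function(x) colnames(x))

#' @describeIn accessors per-SNP QC table.
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @export
setMethod("qcTable", "QcReport", function(x) x@table)

#' @describeIn accessors ids retained by QC, in input order.
#' @export
setGeneric("retainedSnps", function(x) standardGeneric("retainedSnps"))

#' @export
setMethod("retainedSnps", "QcReport", function(x) x@retained)

#' @describeIn accessors ids excluded by QC, in input order.
#' @export
setGeneric("excludedSnps", function(x) standardGeneric("excludedSnps"))

#' @export
setMethod("excludedSnps", "QcReport", function(x) x@excluded)

#' @describeIn accessors the p-value of a test.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setMethod("pValue", "TestResult", function(x) x@p.value)

#' @describeIn accessors the named test statistic.
#' @export
setGeneric("statValue", function(x) standardGeneric("statValue"))

#' @export
setMethod("statValue", "TestResult", function(x) x@statistic)

#' @describeIn accessors group summaries attached to a test.
#' @export
setGeneric("groupSummaries", function(x) standardGeneric("groupSummaries"))

#' @export
setMethod("groupSummaries", "TestResult", function(x) x@groups)

#' @describeIn accessors result tables of a pipeline run.
#' @export
setGeneric("resultTables", function(x) standardGeneric("resultTables"))

#' @export
setMethod("resultTables", "RunReport", function(x) x@tables)

#' @describeIn accessors analysis-ready subject table of a pipeline run.
#' @export
setGeneric("analysisData", function(x) standardGeneric("analysisData"))

#' @export
setMethod("analysisData", "RunReport", function(x) x@data)

#' @describeIn accessors inclusion-flowchart counts of a pipeline run.
#' @export
setGeneric("flowCounts", function(x) standardGeneric("flowCounts"))

#' @export
setMethod("flowCounts", "RunReport", function(x) x@flow)

#' Flatten a TestResult to a one-row data.frame
#'
#' Used by the TSV/JSON serializers; stable column set across methods.
#'
#' @param x a [TestResult-class].
#' @return one-row `data.frame` with columns `method`, `label`,
#'   `statistic_name`, `statistic`, `df`, `p_value`, `estimate`, `adjusted`.
#' @export
testResultRow <- function(x) {
  stopifnot(is(x, "TestResult"))
  df <- if ("df" %in% names(x@parameter)) unname(x@parameter["df"]) else NA_real_
  data.frame(
    method = x@method,
    label = x@label,
    statistic_name = if (length(x@statistic)) names(x@statistic)[1] else NA_character_,
    statistic = if (length(x@statistic)) unname(x@statistic[1]) else NA_real_,
    df = df,
    p_value = x@p.value,
    estimate = if (length(x@estimate)) unname(x@estimate[1]) else NA_real_,
    adjusted = x@adjusted,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "SnpGenotypes", function(object) {
  cat("SnpGenotypes:", nrow(object), "SNPs x", ncol(object), "subjects\n")
  d <- dosageMatrix(object)
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
  if ("beta" %in% names(SummarizedExperiment::rowData(object)))
    cat("  panel with effect sizes attached\n")
})

setMethod("show", "QcReport", function(object) {
  tab <- object@table
  cat("QcReport:", nrow(tab), "SNPs;",
      length(object@retained), "retained,",
      length(object@excluded), "excluded\n")
  print(table(factor(tab$verdict,
                     c("pass", "fail_missing", "fail_maf", "fail_hwe"))))
})

setMethod("show", "TestResult", function(object) {
  cat(object@method)
  if (!is.na(object@label)) cat(" [", object@label, "]", sep = "")
  cat(":")
  if (length(object@statistic))
    cat(sprintf(" %s = %.4f,", names(object@statistic)[1],
                object@statistic[1]))
  cat(sprintf(" p = %.4g", object@p.value))
  if (object@adjusted) cat(" (adjusted)")
  cat("\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed", object@seed, ")\n")
  cat("Inclusion flow:\n")
  for (nm in names(object@flow))
    cat(sprintf("  %-28s %d\n", nm, object@flow[[nm]]))
  cat("Tables:", paste(names(object@tables), collapse = ", "), "\n")
})
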