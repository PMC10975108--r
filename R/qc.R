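# SNP-level quality control: missing rate, minor allele frequency and
# Hardy-Weinberg filters, applied in a fixed order.

#' Minor allele frequency of one SNP column
#'
#' Computed from called genotypes only (complete-case): the effect-allele
#' frequency is the dosage sum over twice the number of calls, and the MAF
#' folds it onto \[0, 0.5\].
#'
#' @param dosages numeric vector of 0/1/2/NA dosages.
#' @return MAF in \[0, 0.5\].
#' @examples
#' computeMaf(c(0, 0, 1, 2))  # 0.375
#' @export
computeMaf <- function(dosages) {
  called <- dosages[!is.na(dosages)]
  if (length(called) == 0)
    stop("MAF undefined: all genotypes missing", call. = FALSE)
  f <- sum(called) / (2 * length(called))
  min(f, 1 - f)
}

#' Missing-call rate of one SNP column
#'
#' @param dosages numeric vector of 0/1/2/NA dosages.
#' @return fraction missing in \[0, 1\].
#' @export
missingRate <- function(dosages) {
  if (length(dosages) == 0) stop("empty dosage column", call. = FALSE)
  mean(is.na(dosages))
}

#' Apply the SNP quality-control chain
#'
#' Filters SNPs in a fixed order — missing rate first, then MAF, then the
#' Hardy-Weinberg exact test — so that unavailable SNPs never contaminate
#' frequency estimates. Each SNP receives exactly one verdict (the first
#' failing rule wins); the retained list preserves input order.
#'
#' @param genotypes a [SnpGenotypes-class] (or bare dosage matrix with SNP
#'   rownames, SNPs in rows).
#' @param mafMin exclude SNPs with MAF strictly below this (default 0.01).
#' @param hwePMin exclude SNPs with HWE p strictly below this
#'   (default 1e-6).
#' @param missingMax exclude SNPs with missing rate strictly above this
#'   (default 0.05); a SNP with zero calls always fails here.
#' @param hweMethod `"exact"` (default) or `"chisq"`, see [hweExactTest()].
#' @return a [QcReport-class].
#' @examples
#' sim <- makePreset("qc_stress", seed = 1)
#' rep <- applyQcChain(sim$genotypes)
#' length(retainedSnps(rep))  # 55
#' @export
applyQcChain <- function(genotypes, mafMin = 0.01, hwePMin = 1e-6,
                         missingMax = 0.05, hweMethod = c("exact", "chisq")) {
  hweMethod <- match.arg(hweMethod)
  d <- if (is(genotypes, "SnpGenotypes")) dosageMatrix(genotypes)
       else as.matrix(genotypes)
  if (nrow(d) == 0 || ncol(d) == 0) stop("empty genotype matrix", call. = FALSE)
  stopifnot(mafMin >= 0, mafMin <= 0.5, hwePMin >= 0, hwePMin <= 1,
            missingMax >= 0, missingMax <= 1)
  m <- nrow(d)
  tab <- data.frame(
    snp_id = rownames(d), n_called = NA_integer_, missing_rate = NA_real_,
    maf = NA_real_, hwe_p = NA_real_, verdict = NA_character_,
    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    col <- d[j, ]
    miss <- missingRate(col)
    nCalled <- sum(!is.na(col))
    tab$n_called[j] <- nCalled
    tab$missing_rate[j] <- miss
    if (miss > missingMax || nCalled == 0) {
      tab$verdict[j] <- "fail_missing"
      next
    }
    maf <- computeMaf(col)
    tab$maf[j] <- maf
    if (maf < mafMin) {
      tab$verdict[j] <- "fail_maf"
      next
    }
    called <- col[!is.na(col)]
    p <- hweExactTest(sum(called == 2), sum(called == 1), sum(called == 0),
                      method = hweMethod)
    tab$hwe_p[j] <- p
    tab$verdict[j] <- if (p < hwePMin) "fail_hwe" else "pass"
  }
  new("QcReport",
      table = tab,
      retained = tab$snp_id[tab$verdict == "pass"],
      excluded = tab$snp_id[tab$verdict != "pass"],
      thresholds = c(maf_min = mafMin, hwe_p_min = hwePMin,
                     missing_max = missingMax))
}

#' Subset a SnpGenotypes object to the SNPs retained by QC
#'
#' @param genotypes a [SnpGenotypes-class].
#' @param report the matching [QcReport-class].
#' @return the retained-SNP submatrix, input order preserved.
#' @export
keepRetained <- function(genotypes, report) {
  stopifnot(is(genotypes, "SnpGenotypes"), is(report, "QcReport"))
  genotypes[rownames(genotypes) %in% retainedSnps(report), ]
}
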