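# Plain-text readers/writers for the pipeline's interchange formats:
# panel TSV, wide genotype CSV, subject CSV, LMS reference CSV, QC report
# TSV + JSON, PRS TSV, and a minimal VCF route for genotype ingestion.

#' Read / write a SNP weight panel (TSV)
#'
#' Tab-separated with header columns `snp_id`, `effect_allele`,
#' `other_allele`, `beta` (optional `source_maf`).
#'
#' @param path file path.
#' @param panel panel `data.frame` (for the writer).
#' @return the panel `data.frame` (reader) / invisible path (writer).
#' @export
readSnpPanel <- function(path) {
  panel <- read.delim(path, stringsAsFactors = FALSE)
  validateSnpPanel(panel)
  panel
}

#' @rdname readSnpPanel
#' @export
writeSnpPanel <- function(panel, path) {
  validateSnpPanel(panel)
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write genotypes as a wide CSV
#'
#' One row per subject: `subject_id` then one column per SNP id holding
#' dosages 0/1/2 or empty for missing.
#'
#' @param path file path.
#' @param genotypes [SnpGenotypes-class] (for the writer).
#' @param panel optional panel attached to the object on read.
#' @return a [SnpGenotypes-class] (reader) / invisible path (writer).
#' @export
readGenotypeCsv <- function(path, panel = NULL) {
  wide <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("subject_id" %in% names(wide))
  ids <- as.character(wide$subject_id)
  d <- t(as.matrix(wide[setdiff(names(wide), "subject_id")]))
  storage.mode(d) <- "double"
  colnames(d) <- ids
  if (!is.null(panel)) {
    panel <- panel[match(rownames(d), panel$snp_id), , drop = FALSE]
    if (anyNA(panel$snp_id))
      stop("genotype file holds SNPs absent from the panel", call. = FALSE)
  }
  SnpGenotypes(d, panel = panel)
}

#' @rdname readGenotypeCsv
#' @export
writeGenotypeCsv <- function(genotypes, path) {
  d <- t(dosageMatrix(genotypes))
  wide <- data.frame(subject_id = rownames(d), d, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a subject table (CSV)
#'
#' @param path file path.
#' @param subjects subject `data.frame` (for the writer).
#' @return `data.frame` (reader) / invisible path (writer).
#' @export
readSubjects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("subject_id" %in% names(df))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @rdname readSubjects
#' @export
writeSubjects <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write an LMS reference (CSV)
#'
#' Header columns `sex`, `age_months`, `L`, `M`, `S`. Real WHO reference
#' tables exported to this schema are drop-in replacements for the bundled
#' synthetic one.
#'
#' @param path file path.
#' @param ref reference `data.frame` (for the writer).
#' @return validated `data.frame` (reader) / invisible path (writer).
#' @export
readLmsReference <- function(path) {
  ref <- read.csv(path, stringsAsFactors = FALSE)
  validateLmsReference(ref)
  ref
}

#' @rdname readLmsReference
#' @export
writeLmsReference <- function(ref, path) {
  validateLmsReference(ref)
  write.csv(ref, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a QC report
#'
#' Writes the per-SNP table as TSV and a JSON summary (thresholds, verdict
#' counts, retained/excluded id lists).
#'
#' @param report a [QcReport-class].
#' @param tsvPath,jsonPath output paths (`NULL` to skip either).
#' @return invisible list of the paths written.
#' @export
writeQcReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
  stopifnot(is(report, "QcReport"))
  if (!is.null(tsvPath))
    write.table(qcTable(report), tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(jsonPath)) {
    tab <- qcTable(report)
    summ <- list(
      thresholds = as.list(report@thresholds),
      n_snps = nrow(tab),
      verdict_counts = as.list(table(factor(tab$verdict,
        c("pass", "fail_missing", "fail_maf", "fail_hwe")))),
      retained = retainedSnps(report),
      excluded = excludedSnps(report))
    jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tsv = tsvPath, json = jsonPath))
}

#' Write PRS results (TSV)
#'
#' @param prs `data.frame` from [computePrs()]; if a `risk_group` column
#'   is absent it is added from [classifyRisk()] on the scorable subjects.
#' @param path output path.
#' @return invisible path.
#' @export
writePrsResults <- function(prs, path) {
  if (!"risk_group" %in% names(prs)) {
    prs$risk_group <- NA_character_
    ok <- !prs$unscorable
    prs$risk_group[ok] <- as.character(classifyRisk(prs$score[ok]))
  }
  write.table(prs[c("subject_id", "score", "n_available", "risk_group")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write test results as TSV rows
#'
#' @param results list of [TestResult-class] (possibly nested one level).
#' @param path output path.
#' @return invisible path.
#' @export
writeTestResults <- function(results, path) {
  flat <- list()
  walk <- function(x, prefix = "") {
    if (is(x, "TestResult")) {
      row <- testResultRow(x)
      row$key <- prefix
      flat[[length(flat) + 1]] <<- row
    } else if (is.list(x)) {
      for (nm in names(x))
        walk(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm)
    }
  }
  walk(results)
  tab <- do.call(rbind, flat)
  write.table(tab[c("key", setdiff(names(tab), "key"))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- VCF route -----------------------------------------------------------

#' Write genotypes as a minimal VCF 4.2
#'
#' GT-only, one sample column per subject, unphased; effect allele written
#' as ALT so that the ALT dosage equals the stored effect-allele dosage.
#' Intended for testing VCF ingestion, not as a general-purpose exporter.
#'
#' @param genotypes [SnpGenotypes-class] with allele columns in the panel.
#' @param path output path (`.vcf`, uncompressed).
#' @return invisible path.
#' @export
writeGenotypeVcf <- function(genotypes, path) {
  info <- snpInfo(genotypes)
  stopifnot(all(c("effect_allele", "other_allele") %in% names(info)))
  d <- dosageMatrix(genotypes)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(c("1", as.character(i * 100), rownames(d)[i],
            info$other_allele[i], info$effect_allele[i], ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file, matching a weight panel
#'
#' Parses a VCF (via Bioconductor's VariantAnnotation, if installed) and
#' derives effect-allele dosages by exact allele matching against the
#' panel: a record matches a panel SNP when its id matches and
#' (REF, ALT) equals (other, effect) — dosage is then the ALT count in GT
#' — or (effect, other) — dosage is the REF count. No strand flipping is
#' attempted; A/T and C/G palindromic panel SNPs trigger a warning.
#' Panel SNPs without a matching record become all-missing columns.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param panel SNP weight panel `data.frame`.
#' @return a [SnpGenotypes-class] with one row per panel SNP.
#' @export
readGenotypeVcf <- function(path, panel) {
  validateSnpPanel(panel)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF ingestion requires the VariantAnnotation package",
         call. = FALSE)
  pal <- (panel$effect_allele == "A" & panel$other_allele == "T") |
    (panel$effect_allele == "T" & panel$other_allele == "A") |
    (panel$effect_allele == "C" & panel$other_allele == "G") |
    (panel$effect_allele == "G" & panel$other_allele == "C")
  if (any(pal))
    warning(sum(pal), " palindromic (A/T or C/G) panel SNP(s): ",
            "strand ambiguity cannot be detected", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altList), function(i) {
    a <- as.character(altList[[i]])
    if (length(a) == 1) a else NA_character_
  }, character(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  nSamp <- ncol(gt)
  altCount <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) == 1)
  }
  d <- matrix(NA_real_, nrow(panel), nSamp,
              dimnames = list(panel$snp_id, colnames(gt)))
  unmatched <- character()
  for (k in seq_len(nrow(panel))) {
    i <- match(panel$snp_id[k], ids)
    if (is.na(i) || is.na(alt[i])) {
      unmatched <- c(unmatched, panel$snp_id[k])
      next
    }
    ac <- vapply(gt[i, ], altCount, numeric(1))
    if (ref[i] == panel$other_allele[k] && alt[i] == panel$effect_allele[k]) {
      d[k, ] <- ac
    } else if (ref[i] == panel$effect_allele[k] &&
               alt[i] == panel$other_allele[k]) {
      d[k, ] <- 2 - ac
    } else {
      unmatched <- c(unmatched, panel$snp_id[k])
    }
  }
  if (length(unmatched))
    warning(length(unmatched), " panel SNP(s) without an exact allele ",
            "match in the VCF become all-missing: ",
            paste(head(unmatched, 5), collapse = ", "), call. = FALSE)
  SnpGenotypes(d, panel = panel)
}
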