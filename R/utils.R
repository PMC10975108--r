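# Internal helpers shared across modules.

# Derive a stream-specific child seed from one user seed. Keeps every
# product below 2^53 so the arithmetic is exact in doubles, and the result
# below 2^31 so set.seed() accepts it.
.childSeed <- function(seed, stream) {
  s <- as.double(seed) %% 94906249
  as.integer((s * 48271 + as.double(stream) * 9973 + 17) %% 2147483629)
}

.assertScalarCount <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}

#' Validate a SNP panel table
#'
#' Checks the invariants of the weight panel: unique SNP ids, single-letter
#' A/C/G/T alleles with effect != other, finite `beta`, non-empty table.
#'
#' @param panel `data.frame` with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta` (and optionally `source_maf`).
#' @return the panel, invisibly, after validation.
#' @export
validateSnpPanel <- function(panel) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta")
  if (!is.data.frame(panel) || !all(need %in% names(panel)))
    stop("panel must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  if (anyDuplicated(panel$snp_id)) stop("duplicate snp_id", call. = FALSE)
  ok <- c("A", "C", "G", "T")
  if (!all(panel$effect_allele %in% ok) || !all(panel$other_allele %in% ok))
    stop("alleles must be one of A/C/G/T", call. = FALSE)
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect_allele must differ from other_allele", call. = FALSE)
  if (any(!is.finite(panel$beta))) stop("beta must be finite", call. = FALSE)
  if ("source_maf" %in% names(panel) &&
      any(panel$source_maf <= 0 | panel$source_maf > 0.5))
    stop("source_maf must lie in (0, 0.5]", call. = FALSE)
  invisible(panel)
}

# Quartile convention used everywhere a median (P25, P75) is reported:
# linear interpolation (R's default type 7), documented in the vignette.
.p50p25p75 <- function(x) {
  q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  c(median = q[1], p25 = q[2], p75 = q[3])
}

.groupSummaryTable <- function(values, labels) {
  labs <- if (is.factor(labels)) levels(droplevels(labels)) else unique(labels)
  rows <- lapply(labs, function(l) {
    v <- values[labels == l]
    q <- .p50p25p75(v)
    data.frame(group = l, n = length(v), median = q[1], p25 = q[2],
               p75 = q[3], stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
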