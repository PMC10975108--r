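# Hardy-Weinberg equilibrium tests on biallelic genotype counts.

# Unnormalized conditional distribution of the heterozygote count given the
# allele counts, by outward recurrence from the modal value (stable without
# logs; the classic exact-test recursion).
.hweHetDistribution <- function(nA, nTot) {
  nB <- 2 * nTot - nA
  hetMax <- min(nA, nB)
  hets <- seq(nA %% 2, hetMax, by = 2)
  if (length(hets) == 1) return(setNames(1, hets))
  probs <- setNames(numeric(length(hets)), hets)
  # modal het near nA*nB/(2n); snap to attainable parity
  mode <- round(nA * nB / (2 * nTot))
  if (mode %% 2 != nA %% 2) mode <- mode + 1
  mode <- min(max(mode, hets[1]), hets[length(hets)])
  i0 <- match(mode, hets)
  probs[i0] <- 1
  # ratio P(h+2)/P(h) = 4*nAA*nBB / ((h+2)*(h+1)) with nAA=(nA-h)/2 etc.
  if (i0 < length(probs)) for (i in i0:(length(probs) - 1)) {
    h <- hets[i]
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    probs[i + 1] <- probs[i] * 4 * nAA * nBB / ((h + 2) * (h + 1))
  }
  if (i0 > 1) for (i in i0:2) {
    h <- hets[i]
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (nAA + 1) * (nBB + 1))
  }
  probs / sum(probs)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts of a biallelic SNP: given the
#' allele counts, the two-sided p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count (ties in the probability ordering are included in
#' the rejection sum). The chi-square alternative (1 df, no continuity
#' correction) is available via `method`; the exact test is the default
#' because chi-square is unreliable at extreme significance levels for
#' rare alleles.
#'
#' @param n_hom_effect count of effect-allele homozygotes (dosage 2).
#' @param n_het heterozygote count (dosage 1).
#' @param n_hom_other other-allele homozygote count (dosage 0).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)  # 1/3
#' @export
hweExactTest <- function(n_hom_effect, n_het, n_hom_other,
                         method = c("exact", "chisq")) {
  method <- match.arg(method)
  cts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(is.na(cts)) || any(cts < 0) || any(cts != floor(cts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  nTot <- sum(cts)
  if (nTot < 1) stop("at least one genotyped subject required", call. = FALSE)
  if (method == "chisq") {
    p <- (2 * n_hom_effect + n_het) / (2 * nTot)
    if (p == 0 || p == 1) return(1)
    e <- nTot * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((cts - e)^2 / e)
    return(pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nA <- 2 * n_hom_effect + n_het
  probs <- .hweHetDistribution(nA, nTot)
  pObs <- probs[[as.character(n_het)]]
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}
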