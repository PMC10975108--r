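# Shared fixtures and independent oracles, all built in code.

toyPanel <- function(betas = c(0.5, -0.2), mafs = NULL) {
  m <- length(betas)
  data.frame(
    snp_id = sprintf("snp%02d", seq_len(m)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = m),
    other_allele = rep(c("G", "T", "A", "C"), length.out = m),
    beta = betas,
    source_maf = if (is.null(mafs)) rep(0.3, m) else mafs,
    stringsAsFactors = FALSE)
}

toyGenotypes <- function(dosage, betas = NULL) {
  dosage <- as.matrix(dosage)
  panel <- toyPanel(if (is.null(betas)) rep(0.1, nrow(dosage)) else betas)
  rownames(dosage) <- panel$snp_id
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  SnpGenotypes(dosage, panel = panel)
}

# Independent HWE oracle: direct log-factorial evaluation of the
# conditional heterozygote distribution (the package uses an outward
# recurrence instead).
hweOracleDistribution <- function(nA, nTot) {
  nB <- 2 * nTot - nA
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- vapply(hets, function(h) {
    nAA <- (nA - h) / 2
    nBB <- (nB - h) / 2
    lgamma(nTot + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * nTot + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  setNames(p / sum(p), hets)
}

hweOracleP <- function(nAA, nAB, nBB) {
  probs <- hweOracleDistribution(2 * nAA + nAB, nAA + nAB + nBB)
  pObs <- probs[[as.character(nAB)]]
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

# Independent brute-force partial Spearman: explicit projection matrix.
partialSpearmanOracle <- function(x, y, cv) {
  rx <- rank(x); ry <- rank(y)
  Q <- cbind(1, apply(as.matrix(cv), 2, rank))
  P <- diag(length(x)) - Q %*% solve(crossprod(Q)) %*% t(Q)
  as.numeric(cor(P %*% rx, P %*% ry))
}

# All distinct permutations of a label vector (for small exact-test
# oracles); recursion over positions, duplicates collapsed.
allLabelPermutations <- function(labels) {
  uniq <- unique(labels)
  recurse <- function(lab) {
    if (length(lab) <= 1) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      i <- match(u, lab)
      for (rest in recurse(lab[-i]))
        out[[length(out) + 1]] <- c(u, rest)
    }
    out
  }
  unique(recurse(labels))
}

# Jonckheere-Terpstra statistic recomputed naively from scratch.
jtOracle <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k))
    for (a in groups[[i]]) for (b in groups[[j]])
      s <- s + (b > a) + 0.5 * (b == a)
  s
}
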