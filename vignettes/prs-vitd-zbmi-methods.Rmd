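---
title: "Methods: polygenic risk, vitamin D status and child zBMI"
author: "prsgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, vitamin D status and child zBMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsgrowth)
```

# The scientific problem

Childhood obesity has both a polygenic component — many common variants,
each of small effect — and environmental correlates, among them vitamin D
status. A standard epidemiological design for studying their interplay in
preschool children measures three quantities per child: a weighted
polygenic risk score (PRS) built from BMI-associated SNPs, serum
25-hydroxyvitamin D (25(OH)D, ng/mL) as the vitamin D biomarker, and the
BMI-for-age z-score (zBMI) against a sex- and age-specific growth
reference. Inference is nonparametric throughout, because zBMI, 25(OH)D
and the PRS are all non-normal in such cohorts.

This package implements that full analysis — genotype quality control, PRS
construction, LMS-based zBMI, vitamin D classification and the rank-based
inference layer — together with a seeded synthetic-cohort generator, so
every stage is testable end to end without access to any individual-level
study data.

# Genotype quality control

SNPs are filtered in a fixed order:

1. **Missing rate** above 5% (or zero calls) — `fail_missing`. Running
   this first keeps unavailable assays from contaminating the frequency
   estimates used by the later filters.
2. **Minor allele frequency** below 1%, computed from called genotypes
   only — `fail_maf`.
3. **Hardy–Weinberg equilibrium** exact p below 1e-6 — `fail_hwe`.

Each SNP receives exactly one verdict (the first failing rule wins), so
the verdict counts always partition the panel; when the failure sets are
disjoint — as they are in the engineered stress preset — the counts are
order-independent.

The HWE test is the conditional exact test: given the allele counts, the
distribution of the heterozygote count is known in closed form, and the
two-sided p sums the probabilities of all heterozygote counts no more
probable than the observed one (probability ties are included in the
rejection sum). The exact test is the default because at thresholds as
extreme as 1e-6 the 1-df chi-square approximation is unreliable for rare
alleles; chi-square remains available as a method flag and serves as a
large-sample cross-check in the test suite. The implementation uses the
outward recurrence from the modal heterozygote count, which is stable
without logarithms; the test suite verifies it against an independent
log-factorial enumeration for every genotype table with up to 50 subjects.

# The polygenic risk score

For subject $i$ with available (non-missing) SNP set $A_i$ of size $n_i$:

$$\mathrm{PRS}_i \;=\; \Big(\sum_{j \in A_i} \beta_j \, g_{ij}\Big) \times
\frac{n_i}{\sum_{j \in A_i} \beta_j}$$

where $g_{ij} \in \{0,1,2\}$ counts effect-allele copies and $\beta_j$ is
the per-allele GWAS effect size. The rescaling factor compensates
subjects genotyped at fewer SNPs. Two consequences of this formula, which
divides by a *signed* sum of mixed-sign weights, matter in practice:

* the divisor can be arbitrarily close to zero for unlucky availability
  patterns, so subjects with $|\sum\beta| \le 10^{-10}$ (or no available
  SNPs at all) are flagged unscorable rather than silently scored;
* when the panel-wide $\sum\beta$ is negative, scores are sign-flipped
  relative to the raw weighted sums — `computePrs()` reports the sign and
  magnitude of the full-panel sum for this reason. We implement the
  formula as stated because it is the scale on which the downstream
  grouping and correlations are defined; a $\sum|\beta|$ normalization
  exists as an alternative in the literature but is deliberately not the
  default.

Risk groups use floor-rank deciles: with $k = \lfloor 0.1\,n \rfloor$,
the $k$ smallest scores are low-risk, the $k$ largest high-risk, the rest
intermediate. At $n = 1046$ with distinct scores this gives groups of
104/838/104 — the only boundary convention that reproduces that split,
which is why it is fixed here. Ties spanning a boundary are broken by
stable subject order with a warning.

# LMS z-scores

Against a reference row $(L, M, S)$ — Box–Cox power, median, coefficient
of variation — a measurement $X$ scores

$$z = \frac{(X/M)^L - 1}{L\,S} \quad (L \ne 0), \qquad
z = \frac{\ln(X/M)}{S} \quad (L = 0),$$

with the *restricted adjustment* of growth-standard software beyond
$|z|=3$: above 3, $z = 3 + (X - \mathrm{SD3^+})/(\mathrm{SD3^+} -
\mathrm{SD2^+})$ with $\mathrm{SD}k = M(1 + LSk)^{1/L}$, and symmetrically
below $-3$. This keeps extreme z-scores linear in the measurement, in
units of the local SD2–SD3 gap. `lmsInverse()` is the exact piecewise
inverse; the round trip is verified to 1e-9 over $z \in [-5, 5]$.

Reference lookup uses the completed-month convention: a child aged 60.4
months reads the month-60 row (largest knot $\le$ age + 0.5). The package
ships a *synthetic* LMS reference (36–84 months, both sexes, smooth in
age, labelled synthetic in its filename and documentation); any real WHO
table exported to the same CSV schema is a drop-in replacement. A single
table spanning the cohort's ages stands in for the under-5/over-5
software split used in field practice; nothing in the algorithm depends
on which table supplied the row.

zBMI values with $|z| > 5$ are flagged implausible but retained; subject
exclusion happens only in the pipeline's mean ± 4 SD outlier step, whose
moments are computed once on the pre-filter sample (single pass, no
iteration). The monitored variables default to zBMI and 25(OH)D and are
configurable.

# The inference layer

All tests are two-sided. Continuous summaries are median (P25, P75) with
linear-interpolation quartiles; categorical summaries are count (percent
to one decimal).

* **Spearman** — Pearson correlation of average ranks, t approximation
  with $n-2$ df.
* **Partial Spearman** — ranks of x, y and every covariate column;
  ranked x and y are residualized on the ranked covariate matrix by least
  squares with intercept, and the residuals correlated ($t$, $n-2-k$ df).
  Categorical covariates are indicator-coded with the first level as
  reference. This rank-residualization scheme is one reasonable reading
  of "covariate-adjusted Spearman"; the adjustment mechanics are rarely
  stated in applied reports, so the choice is documented here rather than
  claimed as a reproduction.
* **Wilcoxon rank-sum** — tie-corrected normal approximation; exact
  label-assignment enumeration for combined samples of 12 or fewer
  (deviation-from-mean two-sided rule, valid under ties).
* **Kruskal–Wallis** — tie-corrected H via `stats::kruskal.test`.
* **Dunn's test** — pairwise z on joint mean ranks with the pooled
  tie-corrected variance, valid for unequal group sizes; Bonferroni
  adjustment over all pairs by default (Holm optional). This is the
  standard post-hoc companion to Kruskal–Wallis for unequal n.
* **Trend across ordered groups** — Jonckheere–Terpstra, the standard
  ordered-alternative rank test (ties counted one half), tie-corrected
  normal approximation, exact enumeration for 10 or fewer observations.
  Applied-report trend tests are rarely named; JT is chosen as the one
  consistent with the fully nonparametric framing.
* **Rank interaction** — Scheirer–Ray–Hare: two-way ANOVA sums of squares
  on the joint ranks, interaction SS divided by the total mean square of
  the ranks, chi-square reference on $(a-1)(b-1)$ df. Chosen to stay
  inside the rank paradigm; it is an interpretation of "p for
  interaction" on ranks, not a unique definition.
* **Chi-square** — Pearson, no continuity correction, zero margins
  dropped with a warning, small expected counts flagged.
* **Rank R²** — R² of ranked-y-on-ranked-x least squares, identically
  the squared Spearman correlation; the scale on which a PRS "explains"
  a percentage of outcome variation under rank regression.

The test suite checks hand-derived values (e.g. H = 2.4 and Dunn
z = −1.549 on {1,2} vs {3,4}; exact rank-sum p = 1/3), equivalence with
independent oracles (base R's `cor.test`/`wilcox.test`, explicit
projection matrices, brute-force permutation enumeration), rank-transform
invariance, and type-I error calibration within ±0.01 of nominal 0.05 at
5000 null replicates per test.

# The synthetic cohort generator

The generator exists so the pipeline can be validated against known
truth; its defaults are the study conditions the package targets.

* **Panel**: 55 SNPs (85 in the QC stress preset), effect sizes
  $\beta \sim N(0, 0.02^2)$ — *symmetric about zero*, because a panel of
  all-positive weights could never produce the negative cohort-median
  scores that the signed rescaled PRS exhibits in practice; effect-allele
  frequency uniform on [0.05, 0.5].
* **Genotypes**: per SNP, genotype probabilities
  $p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq$ for effect-allele frequency $p$
  and inbreeding coefficient $F$ — HWE at $F = 0$, heterozygote deficit
  as $F \to 1$. Independent SNPs: no linkage disequilibrium, no
  population stratification, no genotyping-error model (deliberate
  non-goals).
* **Subjects**: sex Bernoulli(0.5); age uniform 44–80 months; 25(OH)D
  log-normal with median 33.63 ng/mL and sdlog 0.32 (right-skewed,
  positive support; the sdlog reproduces an IQR of roughly 27–41 at that
  median); covariates (birth size, delivery mode, breastfeeding,
  supplement use, caregiver education, SES, ...) drawn with realistic
  marginals, independently of genotype by default — a confounded variant
  is a switch, off by default, because the covariance structure among
  such covariates is essentially never published and independence is the
  honest default.
* **Phenotypes**: the latent zBMI is
  $z = a_P P + a_V V + \sigma \varepsilon$ where $P$ and $V$ are normal
  scores of the true PRS and of 25(OH)D, $\varepsilon$ is standard
  normal, and $\sigma$ scales the total variance to 1. The loadings use
  $a = 2\sin(\pi r/6)$ — the inverse of the bivariate-normal
  Spearman/Pearson relation — so the *realized rank correlation* matches
  the requested target $r$ (defaults +0.10 for the PRS and −0.11 for
  25(OH)D). Across 40 replicates at n = 1046 the mean realized
  correlation sits within 0.02 of target (tested). Weight and height are
  then set by inverting the LMS reference at $z$, so re-scoring the
  cohort recovers the planted z to numerical precision — a strong
  round-trip oracle for the anthropometry module.
* **Seeding**: one integer seed; every generator derives its own child
  seed through a small splitting function, so draws in different modules
  are independent streams and identical (config, seed) pairs give
  byte-identical outputs.

Two presets fix the study conditions: `study_cohort` (n = 1046, 55 clean
SNPs, planted effects +0.10/−0.11) and `qc_stress` (85 candidates: 8 with
population effect-allele frequency 0.002, 13 with F = 0.9, 9 fully
missing, 55 clean — engineered so the default QC chain retains exactly
the 55 clean SNPs with overwhelming probability at n = 1046).

What passing tests on synthetic cohorts do **not** show: robustness to
linkage disequilibrium between panel SNPs, to ancestry structure, to
differential genotyping error, or to confounding between covariates and
genotype. The generator emulates marginal structure and planted
monotone effects, nothing more.

# Problem sizes and numerical choices

The validation suite uses the sizes a desk check can afford: exact-test
oracle equivalence over all genotype tables with up to 50 subjects;
type-I calibration at 5000 null replicates per test (n = 200–960);
effect-recovery over 100 cohort replicates at n = 1046. Tolerances: 1e-10
against enumeration oracles, 1e-9 for the LMS round trip, ±0.01 around
nominal 0.05 for calibration.

Tie handling is explicit everywhere: average ranks, tie-corrected
variances, probability ties included in exact rejection sums, stable
order at risk-group boundaries. Degenerate inputs resolve to the
conservative answer (H = 0 and p = 1 for constant outcomes; unscorable
flags rather than zeros; zero-variance outlier filters exclude nobody,
with a warning).

# Worked example

```{r example, eval = FALSE}
sim <- makePreset("study_cohort", seed = 1)
report <- runAnalysis(sim$genotypes, sim$subjects, sim$lms, sim$panel)
report
corrs <- resultTables(report)$correlations
corrs[["score~zbmi"]]$model_III   # adjusted PRS ~ zBMI correlation
corrs[["vitd~zbmi"]]$model_III    # adjusted 25(OH)D ~ zBMI correlation
```

# Known limitations

* The adjusted-correlation scheme, the trend test and the interaction
  test are reasoned choices within the rank paradigm, documented above;
  applied reports using other schemes will differ numerically.
* The bundled LMS table is synthetic; absolute zBMI values against it are
  not comparable to WHO-referenced values (relative structure is).
* No imputation, LD pruning or sample-level QC (sex checks, relatedness);
  no PRS tuning across GWAS p-value thresholds.
* Cross-sectional design throughout: nothing here supports causal
  claims.
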