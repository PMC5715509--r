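---
title: "Methods: comparative two-tissue neonatal methylome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative two-tissue neonatal methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analytical problem

Neonatal epigenome-wide association studies (EWAS) measure DNA methylation
in surrogate tissues collected at birth — most commonly cord blood and
umbilical cord tissue — because the target tissues of interest are
inaccessible. Since methylomes are strongly tissue specific, the choice of
surrogate shapes every downstream conclusion: which CpGs vary between
individuals at all, how much of that variation genotype explains, and which
prenatal exposures leave detectable marks. `dualtissue` implements the full
comparative pipeline for a paired two-tissue cohort: variability mapping,
cis methylation-QTL scanning, multi-factor EWAS, cross-tissue overlap
accounting, and clustering of the surrogate methylomes against
sequencing-based reference tissues — together with a synthetic cohort
generator that makes every stage testable against a known ground truth.

# Measurement scales

Array methylation is expressed as a beta value, the fraction methylated in
$[0,1]$. Linear modelling and batch adjustment operate on the M-value scale,
$M = \log_2\!\big(\beta / (1-\beta)\big)$, which stabilises variance and
unbounds the response. Conversion clips $\beta$ into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before taking
the log ratio: deposited-style matrices contain values at or indistinguishable
from 0 and 1, and the clip keeps the transform total and strictly monotone
while round-tripping interior values to $10^{-12}$.

# Inter-individual variability

A CpG is called *variable* in a tissue when two clauses both hold strictly:

* the methylation **range excluding outliers** exceeds 0.10, and
* the **99th minus 1st percentile** spread exceeds 0.05.

"Outlier" is operationalised as the standard boxplot convention: values
outside the Tukey fences $(Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
1.5\,\mathrm{IQR})$. The range clause is computed on in-fence values only;
the percentile clause is computed on **all** values, since outlier exclusion
is stated only for the range. Both choices are switchable
(`percentile_excl_outliers`), and percentiles use linear interpolation
between order statistics (R's type-7 default) — one fixed convention is
needed for reproducibility. Outlier *truncation* (used before regression
fits, below) replaces each fence-crossing value with the most extreme
observed in-fence value, i.e. the "next possible" boundary value; this is
idempotent and order preserving.

The two tissues' calls partition the shared CpG universe into four
categories (variable in both, in either alone, in neither), and the
cumulative distribution of per-CpG IQRs gives the exceedance curve used to
compare overall tissue variability.

# Preprocessing

**Cell composition.** Each sample's panel-CpG beta profile is projected
onto reference cell-type profiles under nonnegativity and sum-to-one
constraints. The quadratic program is solved exactly by enumerating cell
type supports and solving the equality-constrained least-squares system on
each support; for realistic panel sizes (3–7 cell types) this is exact,
deterministic and fast, and it avoids any dependence on an iterative QP
solver. Cell proportions enter regressions through their principal
components — the smallest number retaining at least 90% of the variance,
capped at one less than the number of types (proportions live on a
simplex, so the final dimension is redundant) — together with
cell-PC × ethnicity interaction terms, because composition effects can be
ethnicity dependent.

**Design matrix.** Covariates follow the study design: child sex,
gestational age, ethnicity (dummy coded against the most frequent level),
hospital, bisulfite conversion batch, chip position, plus DNA extraction
batch for cord tissue and chip-set for cord blood. Rank-deficient columns
are dropped deterministically via pivoted QR and logged.

**Chip adjustment.** The dominant technical axis on methylation arrays is
the chip. Chips are harmonised on the M scale with the parametric
empirical-Bayes location/scale model: per-CpG batch effects are
standardised against a pooled variance, shrunk toward their across-CpG
batch means by the standard EB updates, and removed, while the covariate
fit is preserved. The implementation lives in this package so that the
degenerate case of a noiseless pure location shift — where the pooled
residual variance is exactly zero — reduces to exact batch-mean removal
rather than a division by zero; on noisy data it agrees with the reference
empirical-Bayes implementation to numerical tolerance (this agreement is a
test). Whether the adjustment should protect the full covariate design is
not prescribed; the default protects it, and the covariates argument is
configurable. A single batch level is a no-op.

**Surrogate variables.** As a sensitivity analysis, hidden structure is
estimated by residual-matrix PCA: the known design is projected out and the
top principal-component scores of the residual become additional
covariates. This simplified form (not the iteratively reweighted published
algorithm) preserves the testable contract — recovery of an implanted
hidden batch with $|r| > 0.9$ — and returns exactly zero scores when the
design explains the matrix.

# Association scans

**cis-mQTL scan.** Every variable CpG is regressed on each SNP of the same
chromosome ("cis" is defined as same-chromosome, with no distance window)
under an additive dosage model, adjusted for the full design; methylation is
outlier-truncated before fitting. Each CpG keeps its most significant SNP
(min-p), with ties broken by larger $|t|$ then lexicographic SNP id, and is
called genotype-associated below the genome-wide Bonferroni threshold
$5\times10^{-8}$. Fits use Frisch–Waugh–Lovell residualisation: the design
is projected out of responses and dosages once per chromosome through a
shared QR, after which per-SNP effects, standard errors and t-tests come
from cross-products — algebraically identical to separate per-SNP OLS fits
(verified against a normal-equations oracle to $10^{-8}$) but fast enough
for a desk-scale scan in seconds. SNPs with missing dosages fall back to
pairwise complete-case fits. P values are floored at $10^{-300}$ so
rankings never underflow. Associations are fitted on the adjusted beta
scale by default, with the M scale as an option.

Genotypes first pass QC: SNP call rate ≥ 95%, minor allele frequency
≥ 10%, and Hardy–Weinberg equilibrium by a 1-df chi-square goodness-of-fit
test with $P \ge 10^{-6}$ (no specific test or cutoff is prescribed;
the chi-square with a conventional GWAS-style cutoff is used, and
monomorphic SNPs return $P = 1$); then samples with call rate < 99% are
dropped. SNP filters run before sample filters, in one iteration.

**Prenatal-factor EWAS.** Each variable CpG is regressed on each of the 45
prenatal factors separately (the factor list is configuration — a typed
schema file — not code). Continuous factors are outlier-truncated and
tested by the coefficient t-test; categorical factors are dummy-coded and
tested by the block F-test, reporting the largest-magnitude level
coefficient as the effect (a single-coefficient report would be undefined
for multi-level factors). Min-p aggregation across the 45 factors with the
Bonferroni threshold $10^{-3}$ yields the factor-associated call, exactly
as specified — with no additional CpG-dimension correction. Per-factor
fits are complete-case; factors missing in more than half the samples are
skipped.

**Overlap accounting.** Over CpGs variable in at least one tissue, each
CpG receives a tri-state status per tissue (associated / variable but not
associated / not variable). The $3\times3$ cross-classification minus the
impossible (not-variable, not-variable) cell gives the eight-category
table; the both-associated overlap is reported as a percentage of each
tissue's associated count, since both denominators are informative.
Cross-tissue effect concordance pairs each selected CpG's winning-factor
effect in one tissue with the same factor's effect in the other.

# Reference clustering

Cohort tissues are summarised by per-CpG medians and joined with
sequencing-based reference methylomes. A site is retained when it is
present in all cohort profiles, remains observed in at least 10 of 25
references (the default generalises as $\lceil 0.4\,n\rceil$) after
observations under 30× read coverage are masked missing, and has IQR
across references above 0.10. Coverage masking precedes missingness
counting, making the filter order well defined. Distances are
$1 - \rho_{\mathrm{Spearman}}$ (pairwise complete) with average linkage —
the distance metric and linkage are declared package defaults, both
configurable, since rank correlations are the natural companion to the
reported sample–reference Spearman matrix and are invariant to the
monotone distortions that separate array and sequencing scales.

# The synthetic cohort generator

The generator draws a paired-tissue cohort with the statistical structure
the analysis assumes, plus a manifest of every implant, so that recall,
bias, calibration and specificity are all measurable. Its defaults define
the package's study conditions: 200 samples, 20,000 CpGs, 5,000 SNPs on 4
chromosomes.

* **Baseline landscape** — non-variable CpGs sit near 0 or 1 (M baselines
  at $\pm4 \pm 0.7$), variable CpGs at intermediate betas (0.25–0.75),
  reproducing the bimodal beta distribution of array data.
* **Variability** — designated variable CpGs get person-level normal
  variance on the M scale (SD 0.6; 0.35 at effect-carrying CpGs), sized so
  the variability filter detects them while leaving non-variable CpGs
  (measurement noise SD 0.1) below threshold. The default category split —
  20.0% variable in both tissues, 17.5% cord tissue only, 3.3% cord blood
  only — mirrors the published two-tissue accounting.
* **Effects** — mQTL CpGs receive additive per-allele M-scale shifts
  (default 0.6) from a random same-chromosome SNP; factor CpGs receive
  linear effects (default 0.25 per factor SD). Half of each implant set is
  shared between tissues with the identical effect, supporting
  concordance tests. Effects are implanted on the M scale and transformed
  to beta, keeping values bounded without truncation artifacts.
* **Genotypes** — independent SNPs, allele frequencies uniform on
  [0.15, 0.5] (headroom above the 10% MAF QC filter), dosages
  binomial(2, p); Hardy–Weinberg holds by construction.
* **Batch** — each chip applies a location shift (SD 0.3 M) and a
  multiplicative scale on deviations (log-SD 0.06) — large enough to
  corrupt raw variability calls, which is what makes the chip-adjustment
  stage observable end to end.
* **Cell mixing** — a set of cell-discriminating CpGs is generated as
  proportion-weighted mixtures of cell-specific profiles (one
  high-methylation cell type per panel CpG), with symmetric
  Dirichlet-distributed proportions (concentration 10 per type; no
  composition distribution is prescribed, so a symmetric concentration is
  the neutral choice) and beta-scale mixing noise (SD 0.02). The same
  profiles serve as the deconvolution reference panel.
* **Prenatal factors** — 40 continuous standard-normal variables in
  correlated blocks of 5 ($\rho = 0.3$, a placeholder magnitude, not a
  calibration) plus 5 three-level categorical variables.
* **Reference methylomes** — lineages share a profile (between-lineage SD
  1.5 M) with smaller tissue deviations (ratio 5:1 by default), Poisson
  coverage around 40× (so a tail falls under any 30× threshold), and 5%
  injected missingness.

What the generator does **not** emulate: probe chemistry and type effects,
detection-P artifacts, linkage disequilibrium (SNPs are independent),
realistic factor distributions or their true correlation structure, and
cell-type-specific effect heterogeneity. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the assumed model, not that real-data artifacts outside that model are
handled.

# Numerical and design choices

* Quantiles: type-7 linear interpolation everywhere.
* Zero residual variance (exact fits): $t = \pm\infty$, P floored at
  $10^{-300}$; zero effect with zero variance reports $t = 0$, $P = 1$.
* Pooled variance below $10^{-12}$ in the chip adjustment triggers the
  exact location path.
* Deterministic orderings: scan output sorted by CpG id; min-p ties by
  $|t|$ then predictor id; clustering ties by label order.
* One master seed expands to per-stage seeds by a fixed affine derivation,
  so stages can be rerun in isolation.
* Missing methylation is rejected on input rather than imputed; missing
  genotypes are handled per-SNP complete-case; missing factor values
  per-factor complete-case.

# Problem sizes

The test suite exercises the pipeline at reduced scale (cohorts of 60–150
samples, 800–2,500 CpGs) and the acceptance checks at the full default
conditions (200 × 20,000 × 5,000, with ≥ 100,000 null fits for
calibration); both complete in well under the time a desk run should take.

# Limitations

The variability thresholds, QC cutoffs and Bonferroni levels are faithful
to their published values but remain configuration; nothing in the package
re-derives them. The percentile-clause dialect (all values vs
outlier-excluded) is decided but switchable, because the original
definition leaves it ambiguous — on deposited-scale data the two dialects
can be compared directly. Reference clustering assumes per-site methylation
fractions with coverage are already produced by upstream sequencing
pipelines; strand combining and other read-level processing are out of
scope. The surrogate-variable stage is the simplified residual-PCA form and
is intended for sensitivity analysis, not as a replacement for dedicated
latent-factor estimation.
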