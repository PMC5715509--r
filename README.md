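# dualtissue

Comparative two-tissue neonatal methylome analysis: inter-individual
variability mapping, cis-mQTL scanning, multi-factor EWAS, cross-tissue
overlap accounting, and surrogate-vs-reference tissue clustering — with a
seeded synthetic cohort simulator that makes every stage verifiable.

## Who this is for

Epigenetic epidemiologists running neonatal EWAS on paired surrogate
tissues (cord tissue and cord blood profiled on methylation arrays) who
need to know, per tissue: which CpGs show inter-individual variation, how
much of that variation genotype explains, which prenatal factors associate
with it, how the two tissues' answers overlap, and which primary tissues
each surrogate can proxy for. The package also serves as a reproducible
test bed: its cohort simulator implants known variability, cis-genetic and
prenatal-factor effects, batch structure and cell-composition mixing, so
recall, bias, calibration and specificity of the whole pipeline are
measurable against a ground-truth manifest.

## The statistics at the core

* **Variability call** — a CpG is variable when range(β) excluding Tukey
  outliers > 0.10 **and** (P99 − P1)(β) > 0.05 (both strict); tissues are
  compared by a four-category partition and IQR exceedance curves.
* **cis-mQTL scan** — per variable CpG, OLS of adjusted methylation on
  each same-chromosome SNP dosage (additive model) given the covariate
  design; the min-p SNP is kept and the CpG is genotype-associated when
  min-p < 5×10⁻⁸. Fits are residualised once per chromosome
  (Frisch–Waugh–Lovell), exactly equivalent to per-SNP OLS.
* **Prenatal-factor EWAS** — per variable CpG, OLS on each of 45 typed
  factors (t-test for continuous, dummy-block F-test for categorical);
  factor-associated when min-p < 10⁻³ (Bonferroni for 45 factors).
* **Eight-category overlap** — over CpGs variable in ≥ 1 tissue, the
  tri-state status (associated / variable-not-associated / not-variable)
  per tissue, with both-denominator overlap percentages.
* **Preprocessing** — M-value conversion (M = log₂ β/(1−β), ε = 10⁻⁶
  clip), parametric empirical-Bayes chip adjustment on M-values,
  reference-based cell deconvolution by exact simplex-constrained least
  squares, residual-PCA surrogate variables, and a design matrix with
  cell-PC × ethnicity interactions.
* **Reference clustering** — cohort median profiles harmonised with
  RRBS-style reference methylomes (30× coverage mask, ≥ 10-of-25
  presence, IQR > 0.10), clustered on 1 − Spearman with average linkage.
* **Genotype QC** — SNP call rate ≥ 95%, MAF ≥ 10%, HWE χ² P ≥ 10⁻⁶;
  sample call rate ≥ 99%.

## Worked example

```r
library(dualtissue)

cfg <- simulation_config(n_samples = 150, n_cpgs = 5000, n_snps = 1000,
                         seed = 42, n_mqtl_cpgs = 80, n_factor_cpgs = 40,
                         n_panel_cpgs = 80)
report <- run_pipeline(pipeline_config(simulation = cfg, seed = 42))
print(report)
#> run_report: 5000 CpGs x 150 samples; 1000 of 1000 SNPs pass QC
#>        tissue pct_variable pct_snp_associated pct_pf_associated
#> 1 cord_tissue         39.1           4.092072          5.677749
#> 2  cord_blood         24.9           6.506024          6.666667

report$categories$summary
#>           category count proportion
#> 1    both_variable  1001     0.2002
#> 2 cord_tissue_only   954     0.1908
#> 3  cord_blood_only   244     0.0488
#> 4          neither  2801     0.5602

report$mqtl_overlap$overlap
#>   both_associated pct_of_a pct_of_b n_associated_a n_associated_b universe
#> 1              41    51.25 50.61728             80             81     2199
```

Reading the output: 39.1% of CpGs pass the variability filter in cord
tissue versus 24.9% in cord blood — the four-way split (20.0% variable in
both, 19.1% cord-tissue-only, 4.9% cord-blood-only, 56.0% neither) follows
the simulator's implanted design. Of the variable CpGs, 4.1%/6.5% are
genotype-associated at 5×10⁻⁸ (80 and 81 CpGs; 41 in both tissues, i.e. an
overlap of ~51% on either denominator), and 5.7%/6.7% associate with at
least one of the 45 prenatal factors at 10⁻³.

Individual stages are exported (`variability_stats`, `cis_scan`,
`ewas_scan`, `combat_adjust`, `estimate_cell_proportions`, `harmonize`,
`cluster_panel`, ...) and a thin command-line wrapper ships in
`inst/scripts/dualtissue.R` (`simulate`, `run`, `sensitivity`
subcommands).

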