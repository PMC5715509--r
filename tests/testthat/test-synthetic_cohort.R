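test_that("cohort simulation is deterministic and bookkeeping is exact", {
  cfg <- simulation_config(n_samples = 60L, n_cpgs = 800L, n_snps = 200L,
                           seed = 4L, n_mqtl_cpgs = 50L, n_factor_cpgs = 20L,
                           n_panel_cpgs = 30L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  for (t in names(s1$truth$manifest)) {
    man <- s1$truth$manifest[[t]]
    expect_equal(sum(man$driver == "mqtl"), 50L)
    expect_equal(sum(man$driver == "factor"), 20L)
    # every implanted mQTL references a SNP on the CpG's own chromosome
    mq <- man[man$driver == "mqtl", ]
    map <- s1$beta[[t]]$cpg_map
    smap <- s1$genotypes$snp_map
    expect_identical(map$chrom[match(mq$cpg_id, map$cpg_id)],
                     smap$chrom[match(mq$mqtl_snp_id, smap$snp_id)])
  }
  # emitted values respect their domains
  expect_true(all(s1$beta$cord_tissue$values >= 0 &
                  s1$beta$cord_tissue$values <= 1))
  expect_true(all(s1$genotypes$dosages %in% c(0, 1, 2)))
  # cell proportions lie on the simplex
  w <- s1$truth$cell_proportions$cord_blood
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-8)
  expect_true(all(w >= 0))
})

test_that("infeasible implant counts are rejected", {
  expect_error(simulation_config(n_samples = 50L, n_cpgs = 100L,
                                 n_snps = 50L, seed = 1L,
                                 n_mqtl_cpgs = 90L, n_factor_cpgs = 90L),
               "infeasible")
  expect_error(simulation_config(n_samples = 10L, n_cpgs = 100L, n_snps = 10L),
               "seed")
})

test_that("noise-free mQTL CpGs order their dosage-group means additively", {
  cfg <- simulation_config(n_samples = 150L, n_cpgs = 400L, n_snps = 100L,
                           seed = 8L, n_mqtl_cpgs = 30L, n_factor_cpgs = 0L,
                           n_panel_cpgs = 10L, noise_sd = 0,
                           chip_shift_scale = 0, qtl_residual_sd = 0,
                           variable_sd = 0.5)
  sim <- simulate_cohort(cfg)
  man <- sim$truth$manifest$cord_tissue
  mq <- man[man$driver == "mqtl", ]
  B <- sim$beta$cord_tissue$values
  G <- sim$genotypes$dosages
  for (i in seq_len(nrow(mq))) {
    g <- G[mq$mqtl_snp_id[i], ]
    if (length(unique(g)) < 3L) next
    mu <- tapply(B[mq$cpg_id[i], ], g, mean)[c("0", "1", "2")]
    if (mq$mqtl_effect[i] > 0) expect_true(all(diff(mu) > 0))
    else expect_true(all(diff(mu) < 0))
  }
})

test_that("with effects, noise and batch shifts zeroed, betas equal baselines", {
  cfg <- simulation_config(n_samples = 50L, n_cpgs = 300L, n_snps = 50L,
                           seed = 15L, n_mqtl_cpgs = 0L, n_factor_cpgs = 0L,
                           n_panel_cpgs = 10L, chip_shift_scale = 0,
                           noise_sd = 0)
  sim <- simulate_cohort(cfg)
  man <- sim$truth$manifest$cord_tissue
  plain <- man$driver == "none"
  B <- sim$beta$cord_tissue$values[plain, ]
  expect_equal(unname(rowMeans(B)), m_to_beta(man$baseline_m[plain]),
               tolerance = 1e-12)
  # with measurement noise, sample means stay within 3 SE of the baseline
  cfg2 <- cfg; cfg2$noise_sd <- 0.05; cfg2$n_samples <- 400L
  sim2 <- simulate_cohort(cfg2)
  man2 <- sim2$truth$manifest$cord_tissue
  plain2 <- man2$driver == "none"
  B2 <- sim2$beta$cord_tissue$values[plain2, ]
  se <- apply(B2, 1, sd) / sqrt(ncol(B2))
  dev <- abs(rowMeans(B2) - m_to_beta(man2$baseline_m[plain2]))
  expect_gt(mean(dev <= 3 * se), 0.95)
})

test_that("reference-set simulation separates lineages and injects low coverage", {
  rs1 <- simulate_reference_set(c(blood = 3L, brain = 3L), seed = 5L)
  rs2 <- simulate_reference_set(c(blood = 3L, brain = 3L), seed = 5L)
  expect_identical(rs1, rs2)
  # between-lineage beta distance exceeds within-lineage distance
  M <- sapply(rs1$references, function(r) r$sites$meth)
  d <- as.matrix(dist(t(M)))
  lin <- rs1$truth$lineage
  within <- d[outer(lin, lin, "==") & upper.tri(d)]
  between <- d[outer(lin, lin, "!=") & upper.tri(d)]
  expect_gt(mean(between), mean(within))
  # Poisson tail: some sites below 30x at mean 40
  cov <- rs1$references[[1]]$sites$coverage
  frac_low <- mean(cov < 30, na.rm = TRUE)
  expect_gt(frac_low, 0)
  expect_lt(frac_low, 0.2)
})

test_that("a simulated cohort round-trips through its on-disk formats", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_samples = 30L, n_cpgs = 200L, n_snps = 60L,
                           seed = 2L, n_mqtl_cpgs = 10L, n_factor_cpgs = 5L,
                           n_panel_cpgs = 10L)
  sim <- simulate_cohort(cfg)
  write_cohort(sim, dir)
  paths <- list(beta_a = file.path(dir, "beta_cord_tissue.tsv"),
                beta_b = file.path(dir, "beta_cord_blood.tsv"),
                cpg_map = file.path(dir, "cpg_map.tsv"),
                dosages = file.path(dir, "dosages.tsv"),
                snp_map = file.path(dir, "snp_map.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                factors = file.path(dir, "factors.tsv"),
                factor_schema = file.path(dir, "factor_schema.tsv"),
                panel_a = file.path(dir, "panel_cord_tissue.tsv"),
                panel_b = file.path(dir, "panel_cord_blood.tsv"))
  back <- dualtissue:::read_cohort(paths)
  expect_equal(back$beta$cord_tissue$values, sim$beta$cord_tissue$values,
               tolerance = 1e-6)
  expect_equal(back$genotypes$dosages, sim$genotypes$dosages)
  expect_identical(back$metadata$sample_id, sim$metadata$sample_id)
})
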