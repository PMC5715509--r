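test_that("HWE chi-square matches closed-form hand computation", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)           # exact HWE proportions
  # (50, 0, 50): p = 0.5, expected (25, 50, 25), chi-square = 100 = n
  expect_equal(hwe_test(c(50, 0, 50)),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(50, 0, 50)), 1e-20)
  expect_equal(hwe_test(c(100, 0, 0)), 1)            # monomorphic convention
  # generic hand oracle
  cnt <- c(30, 40, 30)
  p <- (2 * 30 + 40) / 200
  e <- 100 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(hwe_test(cnt),
               pchisq(sum((cnt - e)^2 / e), 1, lower.tail = FALSE))
  expect_error(hwe_test(c(-1, 2, 3)), "negative")
})

test_that("SNP and sample QC apply the call-rate/MAF/HWE rules", {
  n <- 100
  d <- rbind(
    rs_maf = c(rep(0, 90), rep(1, 9), 2),            # maf 0.055: fail
    rs_cr = c(rep(NA, 6), rep(c(0, 1, 2), length.out = 94)),  # call rate 0.94
    rs_ok = rep(c(0, 1, 1, 2), 25))
  colnames(d) <- paste0("s", seq_len(n))
  map <- data.frame(snp_id = rownames(d), chrom = "1",
                    pos = c(1L, 2L, 3L), ref = "A", alt = "G")
  qc <- snp_qc(genotype_data(d, map))
  rep_ <- qc$snp
  expect_equal(rep_$maf[rep_$snp_id == "rs_maf"], 0.055)
  expect_false(rep_$pass[rep_$snp_id == "rs_maf"])
  expect_equal(rep_$call_rate[rep_$snp_id == "rs_cr"], 0.94)
  expect_false(rep_$pass[rep_$snp_id == "rs_cr"])
  expect_true(rep_$pass[rep_$snp_id == "rs_ok"])
  expect_identical(rownames(qc$filtered$dosages), "rs_ok")
  # all-pass fixture leaves the set untouched
  d2 <- d["rs_ok", , drop = FALSE]
  qc2 <- snp_qc(genotype_data(d2, map[3, ]))
  expect_true(all(qc2$snp$pass), all(qc2$sample$pass))
  expect_identical(dim(qc2$filtered$dosages), dim(d2))
})

test_that("min-p OLS scan agrees with the normal-equations oracle", {
  set.seed(60)
  n <- 30
  d <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, sprintf("p%02d", 1:10)))
  y <- rnorm(n) + 0.4 * X[, 7]
  rec <- ols_scan(y, X, d)
  oracle <- lapply(seq_len(ncol(X)), function(j) ne_oracle(y, X[, j], d))
  ps <- vapply(oracle, `[[`, numeric(1), "p")
  j <- which.min(ps)
  expect_identical(rec$best_predictor_id, colnames(X)[j])
  expect_equal(rec$p_value, oracle[[j]]$p, tolerance = 1e-8)
  expect_equal(rec$effect, unname(oracle[[j]]$effect), tolerance = 1e-8)
  expect_equal(rec$se, oracle[[j]]$se, tolerance = 1e-8)
  expect_lte(rec$p_value, min(ps) * (1 + 1e-12))   # min-p <= all per-predictor p
})

test_that("exact linear response drives the P value to the floor", {
  x <- rnorm(10)
  rec <- ols_scan(0.5 * x, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                  NULL)
  expect_equal(rec$effect, 0.5, tolerance = 1e-10)
  expect_equal(rec$p_value, 1e-300)
})

test_that("scan handles missing genotypes by pairwise complete case", {
  set.seed(61)
  n <- 50
  x <- rbinom(n, 2, 0.4); x[c(3, 9)] <- NA
  y <- rnorm(n) + 0.5 * ifelse(is.na(x), 0, x)
  X <- cbind(snp1 = x)
  rec <- ols_scan(y, X, NULL)
  keep <- !is.na(x)
  o <- ne_oracle(y[keep], x[keep], matrix(1, sum(keep), 1))
  expect_equal(rec$effect, unname(o$effect), tolerance = 1e-10)
  expect_equal(rec$n_used, sum(keep))
})

test_that("cis scan restricts to same-chromosome SNPs and recovers implants", {
  sim <- tiny_cohort()
  prep <- tiny_prep("cord_tissue")
  qc <- snp_qc(sim$genotypes)
  calls <- prep$calls
  sc <- cis_scan(prep$m_adj, qc$filtered, prep$design,
                 variable_cpgs = calls$cpg_id[calls$is_variable])
  # winners are always cis
  map <- sim$beta$cord_tissue$cpg_map
  cpg_chr <- map$chrom[match(sc$cpg_id, map$cpg_id)]
  snp_chr <- qc$filtered$snp_map$chrom[match(sc$best_predictor_id,
                                             qc$filtered$snp_map$snp_id)]
  expect_identical(cpg_chr, snp_chr)
  # implanted mQTLs are recalled with the right SNP and sign
  man <- sim$truth$manifest$cord_tissue
  mq <- man[man$driver == "mqtl", ]
  idx <- match(mq$cpg_id, sc$cpg_id)
  expect_true(all(!is.na(idx)))
  expect_gte(mean(sc$is_significant[idx]), 0.9)
  hit <- sc$best_predictor_id[idx] == mq$mqtl_snp_id
  expect_gte(mean(hit), 0.9)
  expect_true(all(sign(sc$effect[idx][hit]) == sign(mq$mqtl_effect[hit])))
  expect_identical(sc$cpg_id, sort(sc$cpg_id))   # deterministic ordering
})

test_that("cis scan on a single-SNP chromosome equals the single fit", {
  set.seed(62)
  n <- 40
  vals <- matrix(runif(2 * n, 0.3, 0.7), 2, n,
                 dimnames = list(c("cg1", "cg2"), paste0("s", 1:n)))
  map <- data.frame(cpg_id = c("cg1", "cg2"), chrom = c("1", "2"),
                    pos = c(5L, 6L))
  bm <- beta_matrix(vals, map)
  dos <- matrix(rbinom(n, 2, 0.4), 1, n,
                dimnames = list("rsX", paste0("s", 1:n)))
  g <- genotype_data(dos, data.frame(snp_id = "rsX", chrom = "1", pos = 9L,
                                     ref = "A", alt = "G"))
  sc <- cis_scan(bm, g, NULL, variable_cpgs = c("cg1", "cg2"),
                 truncate = FALSE)
  expect_identical(sc$cpg_id, "cg1")              # cg2's chromosome has no SNPs
  expect_identical(attr(sc, "skipped"), "cg2")
  o <- ne_oracle(vals["cg1", ], dos[1, ], matrix(1, n, 1))
  expect_equal(sc$p_value, o$p, tolerance = 1e-10)
})

test_that("doubling the implanted effect never lowers recall", {
  base_cfg <- function(es) simulation_config(
    n_samples = 100L, n_cpgs = 1200L, n_snps = 300L, seed = 33L,
    n_mqtl_cpgs = 60L, n_factor_cpgs = 0L, n_panel_cpgs = 30L,
    mqtl_effect_size = es, noise_sd = 0.3, qtl_residual_sd = 0.6)
  recall <- sapply(c(0.25, 0.5), function(es) {
    sim <- simulate_cohort(base_cfg(es))
    b <- sim$beta$cord_tissue
    calls <- variability_stats(b)
    qc <- snp_qc(sim$genotypes)
    sc <- cis_scan(b, qc$filtered, NULL,
                   variable_cpgs = calls$cpg_id[calls$is_variable])
    man <- sim$truth$manifest$cord_tissue
    mq <- man$cpg_id[man$driver == "mqtl"]
    mean(sc$is_significant[match(mq, sc$cpg_id)], na.rm = TRUE)
  })
  expect_gte(recall[2], recall[1])
})

test_that("eight-category overlap accounts for every CpG exactly once", {
  mkcalls <- function(ids, var) data.frame(cpg_id = ids, is_variable = var)
  mkrec <- function(ids, sig) data.frame(cpg_id = ids, is_significant = sig)
  ids <- paste0("c", 1:4)
  calls_a <- mkcalls(ids, c(TRUE, TRUE, TRUE, FALSE))
  calls_b <- mkcalls(ids, c(FALSE, TRUE, FALSE, TRUE))
  rec_a <- mkrec(c("c1", "c2"), c(TRUE, TRUE))
  rec_b <- mkrec("c2", TRUE)
  ov <- overlap_eight(rec_a, rec_b, calls_a, calls_b)
  expect_equal(ov$overlap$both_associated, 1L)
  expect_equal(ov$overlap$universe, 4L)           # c1..c4 all variable somewhere
  expect_equal(sum(ov$categories$count), ov$overlap$universe)
  expect_equal(nrow(ov$categories), 8L)
  expect_equal(ov$overlap$pct_of_a, 50)
  expect_equal(ov$overlap$pct_of_b, 100)

  # identical tissues: no asymmetric categories
  ov2 <- overlap_eight(rec_a, rec_a, calls_a, calls_a)
  tab <- ov2$categories
  asym <- tab$count[tab$status_A != tab$status_B]
  expect_true(all(asym == 0))

  # impossible state: associated but not variable
  bad <- mkrec("c4", TRUE)
  expect_error(overlap_eight(bad, rec_b, calls_a, calls_b), "impossible|not variable")

  # partition property on random inputs
  set.seed(9)
  for (i in 1:5) {
    ids <- paste0("c", 1:60)
    va <- runif(60) > 0.4; vb <- runif(60) > 0.4
    sa <- va & runif(60) > 0.5; sb <- vb & runif(60) > 0.5
    ov3 <- overlap_eight(mkrec(ids[sa], rep(TRUE, sum(sa))),
                         mkrec(ids[sb], rep(TRUE, sum(sb))),
                         mkcalls(ids, va), mkcalls(ids, vb))
    expect_equal(sum(ov3$categories$count), ov3$overlap$universe)
  }
})
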