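test_that("outlier truncation replaces fence-crossers with boundary values", {
  x <- c(0.50, 0.51, 0.52, 0.53, 0.99)
  # type-7 quartiles: Q1 = 0.51, Q3 = 0.53, fences (0.48, 0.56)
  expect_equal(truncate_outliers(x), c(0.50, 0.51, 0.52, 0.53, 0.53))
  set.seed(2)
  y <- rnorm(200)
  expect_equal(truncate_outliers(truncate_outliers(y)), truncate_outliers(y))
  z <- c(0.4, 0.45, 0.5, 0.55, 0.6)
  expect_identical(truncate_outliers(z), z)      # fixed point, no outliers
  # range containment and rank preservation
  ty <- truncate_outliers(y)
  expect_true(all(ty >= min(y) & ty <= max(y)))
  inner <- y > quantile(y, 0.25) & y < quantile(y, 0.75)
  expect_identical(order(ty[inner]), order(y[inner]))
  expect_error(truncate_outliers(c(1, 2, 3)), "4 non-missing")
  # missing values pass through
  w <- c(NA, 0.5, 0.51, 0.52, 0.53, NA)
  expect_identical(is.na(truncate_outliers(w)), is.na(w))
})

test_that("PCA recovers rank structure with orthogonal scores", {
  set.seed(10)
  u <- rnorm(30)
  rank1 <- outer(rnorm(50), u)
  dimnames(rank1) <- list(paste0("cg", 1:50), paste0("s", 1:30))
  p <- run_pca(rank1, 5)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-10)
  full <- run_pca(matrix(rnorm(50 * 30), 50, 30,
                         dimnames = dimnames(rank1)), 10)
  g <- crossprod(full$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(full$variance_explained) <= 1e-12))
  expect_error(run_pca(matrix(1, 5, 5, dimnames = list(1:5, 1:5))), "constant")
})

test_that("PC-technical-variable association flags perfect confounding", {
  set.seed(11)
  n <- 60
  batch <- rep(c("a", "b"), each = n / 2)
  scores <- cbind(PC1 = ifelse(batch == "a", 1, -1) + rnorm(n, 0, 1e-6),
                  PC2 = rnorm(n))
  # a perfect fit makes the F-test warn; the near-zero P is the point here
  d <- suppressWarnings(associate_pcs(scores, data.frame(batch = batch,
                                                         single = "x")))
  expect_lt(d$p_value[d$pc == "PC1" & d$variable == "batch"], 1e-10)
  expect_identical(attr(d, "skipped"), "single")
  const <- cbind(PC1 = rep(0, n))
  d2 <- associate_pcs(const, data.frame(batch = batch))
  expect_equal(d2$p_value, 1)
})

test_that("PC association P values are calibrated under a permuted null", {
  set.seed(12)
  n <- 80
  batch <- rep(c("a", "b", "c", "d"), each = n / 4)
  p <- replicate(1000, {
    pc <- cbind(PC1 = rnorm(n))
    associate_pcs(pc, data.frame(batch = sample(batch)))$p_value
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("EB chip adjustment equalizes noiseless shifts and is a no-op for one batch", {
  set.seed(20)
  m <- 40; n <- 24
  batch <- rep(c("b1", "b2", "b3"), each = 8)
  base <- rnorm(m)
  shift <- c(b1 = 1.0, b2 = -0.5, b3 = 0.25)[batch]
  X <- matrix(base, m, n) + matrix(shift, m, n, byrow = TRUE)
  dimnames(X) <- list(paste0("cg", 1:m), paste0("s", 1:n))
  adj <- combat_adjust(X, batch)
  bmeans <- sapply(split(seq_len(n), batch), function(ix) rowMeans(adj[, ix]))
  expect_lt(max(apply(bmeans, 1, function(r) diff(range(r)))), 1e-6)

  expect_identical(combat_adjust(X, rep("one", n)), X)
  expect_error(combat_adjust(X, c("a", rep("b", n - 1))), "singleton")
})

test_that("EB chip adjustment agrees with the reference implementation on noisy data", {
  skip_if_not_installed("sva")
  set.seed(21)
  m <- 200; n <- 45
  batch <- rep(c("b1", "b2", "b3"), each = 15)
  X <- matrix(rnorm(m), m, n) + matrix(rnorm(m * n, 0, 0.6), m, n) +
    matrix(c(b1 = 0.7, b2 = -0.4, b3 = 0)[batch], m, n, byrow = TRUE)
  dimnames(X) <- list(paste0("cg", 1:m), paste0("s", 1:n))
  cov <- cbind(1, rnorm(n))
  mine <- combat_adjust(X, batch, cov)
  theirs <- suppressMessages(sva::ComBat(X, batch = batch, mod = cov,
                                         par.prior = TRUE))
  expect_lt(max(abs(mine - theirs)), 1e-4)
})

test_that("EB chip adjustment reduces batch F statistics and preserves effects", {
  set.seed(22)
  m <- 150; n <- 60
  batch <- rep(c("b1", "b2", "b3"), each = 20)
  g <- rbinom(n, 2, 0.3)
  X <- matrix(rnorm(m, 0, 1.5), m, n) + matrix(rnorm(m * n, 0, 0.7), m, n) +
    matrix(c(b1 = 0.8, b2 = -0.5, b3 = 0)[batch], m, n, byrow = TRUE)
  X[1:40, ] <- X[1:40, ] + 0.8 * matrix(g, 40, n, byrow = TRUE)
  dimnames(X) <- list(paste0("cg", 1:m), paste0("s", 1:n))
  adj <- combat_adjust(X, batch)
  fstat <- function(M) apply(M, 1, function(r)
    summary(stats::aov(r ~ factor(batch)))[[1]][["F value"]][1])
  expect_true(all(fstat(adj) < fstat(X)))
  # implanted effect orthogonal to batch survives the adjustment
  e_before <- sapply(1:40, function(i)
    coef(lm(X[i, ] ~ g + factor(batch)))["g"])
  e_after <- sapply(1:40, function(i) coef(lm(adj[i, ] ~ g))["g"])
  expect_lt(mean(abs(e_after - e_before) / abs(e_before)), 0.05)
})

test_that("constrained deconvolution recovers exact and noisy mixtures", {
  set.seed(30)
  k <- 3
  prof <- matrix(runif(60 * k, 0.05, 0.95), 60, k,
                 dimnames = list(paste0("cg", 1:60), c("t1", "t2", "t3")))
  panel <- cell_reference_panel(prof)
  mix <- cbind(prof %*% c(0.3, 0.7, 0), prof[, 1])
  dimnames(mix) <- list(rownames(prof), c("sA", "sB"))
  bm <- beta_matrix(pmin(pmax(mix, 0), 1))
  est <- estimate_cell_proportions(bm, panel)
  expect_equal(unname(est$proportions["sA", ]), c(0.3, 0.7, 0),
               tolerance = 1e-6)
  expect_equal(unname(est$proportions["sB", ]), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(unname(rowSums(est$proportions)), c(1, 1), tolerance = 1e-8)
  expect_true(all(est$proportions >= 0))

  # noisy recovery at mixing noise SD 0.02
  w <- matrix(rgamma(100 * k, 5), 100, k); w <- w / rowSums(w)
  noisy <- prof %*% t(w) + rnorm(60 * 100, 0, 0.02)
  noisy <- pmin(pmax(noisy, 0), 1)
  dimnames(noisy) <- list(rownames(prof), paste0("s", 1:100))
  est2 <- estimate_cell_proportions(beta_matrix(noisy), panel)
  rmse <- sqrt(colMeans((est2$proportions - w)^2))
  expect_true(all(rmse < 0.03))

  expect_error(estimate_cell_proportions(
    beta_matrix(matrix(0.5, 2, 4, dimnames = list(c("x1", "x2"),
                                                  paste0("s", 1:4)))), panel),
    "absent")
})

test_that("surrogate variables recover hidden structure and vanish without residual", {
  set.seed(40)
  m <- 300; n <- 50
  d <- cbind(1, rnorm(n))
  # pure design signal: zero surrogate scores
  signal <- matrix(rnorm(2 * m), m, 2) %*% t(d)
  dimnames(signal) <- list(paste0("cg", 1:m), paste0("s", 1:n))
  sv0 <- estimate_surrogate_variables(signal, d, 2)
  expect_lt(max(abs(sv0)), 1e-8)
  # hidden batch orthogonal to design
  hidden <- rep(c(-1, 1), length.out = n)
  X <- signal + outer(rnorm(m, 0, 1), hidden) + matrix(rnorm(m * n, 0, 0.5), m, n)
  sv <- estimate_surrogate_variables(X, d, 3)
  expect_gt(abs(cor(sv[, 1], hidden)), 0.9)
  g <- crossprod(sv)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_error(estimate_surrogate_variables(X, d, n), "too large")
})

test_that("design construction follows the covariate and interaction rules", {
  set.seed(50)
  n <- 90
  md <- data.frame(
    sample_id = paste0("s", 1:n),
    sex = sample(c("M", "F"), n, TRUE),
    gestational_age = rnorm(n, 38, 1),
    ethnicity = sample(c("chinese", "malay", "indian"), n, TRUE),
    hospital = sample(c("H1", "H2"), n, TRUE),
    bisulfite_batch = sample(c("B1", "B2"), n, TRUE),
    chip_position = sample(c("P1", "P2", "P3"), n, TRUE),
    dna_extraction_batch = sample(c("E1", "E2"), n, TRUE),
    chip_set = sample(c("set1", "set2"), n, TRUE))
  props <- matrix(rgamma(n * 3, 5), n, 3); props <- props / rowSums(props)
  colnames(props) <- c("fib", "b", "t")
  d_ct <- build_design(md, props, tissue = "cord_tissue")
  cn <- colnames(d_ct$matrix)
  # 3 cell types: at most 2 cell PCs; 3 ethnicities: 2 dummies; <= 4 interactions
  expect_lte(sum(grepl("^cellPC\\d+$", cn)), 2L)
  expect_lte(sum(grepl("^cellPC\\d+:", cn)), 4L)
  expect_true(any(grepl("dna_extraction_batch", cn)))
  expect_false(any(grepl("chip_set", cn)))
  d_cb <- build_design(md, props, tissue = "cord_blood")
  expect_true(any(grepl("chip_set", colnames(d_cb$matrix))))
  expect_false(any(grepl("dna_extraction_batch", colnames(d_cb$matrix))))
  expect_equal(d_ct$rank, ncol(d_ct$matrix))    # full column rank

  # degenerate: single ethnicity level drops dummies and interactions
  md1 <- md; md1$ethnicity <- "chinese"
  d1 <- build_design(md1, props, tissue = "cord_tissue")
  expect_false(any(grepl("ethnicity", colnames(d1$matrix))))
  expect_false(any(grepl(":", colnames(d1$matrix))))
  expect_true(any(grepl("single level", d1$dropped)))

  # deterministic
  expect_identical(d_ct$matrix, build_design(md, props, tissue = "cord_tissue")$matrix)
})
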