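#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square goodness-of-fit of observed genotype counts (hom-ref,
#' het, hom-alt) against the expected p^2, 2pq, q^2 proportions under the
#' estimated allele frequency. Monomorphic input returns P = 1 by
#' convention.
#'
#' @param genotype_counts integer vector of length 3: counts of dosage 0, 1
#'   and 2.
#' @return P value in \[0,1\].
#' @export
hwe_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L)
  if (any(genotype_counts < 0)) stop("negative genotype counts")
  n <- sum(genotype_counts)
  if (n == 0L) stop("total genotype count must be positive")
  p <- (2 * genotype_counts[1L] + genotype_counts[2L]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((genotype_counts - expected)^2 / expected)
  stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
}

#' SNP and sample quality control
#'
#' Per-SNP call rate, minor allele frequency and HWE P; a SNP passes with
#' call rate >= `snp_call_rate`, MAF >= `maf` and HWE P >= `hwe_p`. Sample
#' call rates are computed on the SNP-passing set, and a sample passes with
#' call rate >= `sample_call_rate` (SNP filters applied first, then sample
#' filters, in one iteration).
#'
#' @param genotypes a [genotype_data()].
#' @param snp_call_rate minimum SNP call rate (default 0.95).
#' @param maf minimum minor allele frequency (default 0.10).
#' @param hwe_p minimum HWE P value (default 1e-6).
#' @param sample_call_rate minimum sample call rate (default 0.99).
#' @return list with `snp` (per-SNP report), `sample` (per-sample report)
#'   and `filtered` (a [genotype_data()] restricted to passing SNPs and
#'   samples).
#' @export
snp_qc <- function(genotypes, snp_call_rate = 0.95, maf = 0.10,
                   hwe_p = 1e-6, sample_call_rate = 0.99) {
  d <- genotypes$dosages
  n <- ncol(d)
  called <- !is.na(d)
  cr <- rowSums(called) / n
  alt <- rowSums(d, na.rm = TRUE)
  af <- alt / (2 * rowSums(called))
  maf_v <- pmin(af, 1 - af)
  hwe <- apply(d, 1L, function(g) {
    g <- g[!is.na(g)]
    hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))
  })
  snp_pass <- cr >= snp_call_rate & maf_v >= maf & hwe >= hwe_p
  snp_report <- data.frame(snp_id = rownames(d), call_rate = cr, maf = maf_v,
                           hwe_p = hwe, pass = snp_pass,
                           row.names = NULL, stringsAsFactors = FALSE)
  d2 <- d[snp_pass, , drop = FALSE]
  s_cr <- if (nrow(d2)) colSums(!is.na(d2)) / nrow(d2) else rep(1, n)
  s_pass <- s_cr >= sample_call_rate
  sample_report <- data.frame(sample_id = colnames(d), call_rate = s_cr,
                              pass = s_pass, row.names = NULL,
                              stringsAsFactors = FALSE)
  filtered <- genotype_data(d2[, s_pass, drop = FALSE],
                            genotypes$snp_map[snp_pass, , drop = FALSE])
  list(snp = snp_report, sample = sample_report, filtered = filtered)
}

#' Min-p OLS scan of one response over a set of predictors
#'
#' Fits the response on \[design + predictor\] by ordinary least squares for
#' every predictor separately, takes the two-sided t-test P for the
#' predictor coefficient, and keeps the smallest-P predictor (ties broken by
#' larger |t|, then lexicographic predictor id). Samples with a missing
#' predictor value are dropped for that predictor's fit (pairwise complete
#' case); P values are floored at 1e-300.
#'
#' @param response complete numeric per-sample vector.
#' @param predictors numeric matrix (samples x predictors) with column
#'   names; may contain NA.
#' @param design a [build_design()] result or plain design matrix (with
#'   intercept); NULL means intercept only.
#' @param threshold significance threshold on the min-P (default 5e-8).
#' @return one-row data.frame: `best_predictor_id`, `effect`, `se`, `t`,
#'   `p_value`, `n_used`, `is_significant`.
#' @export
ols_scan <- function(response, predictors, design = NULL, threshold = 5e-8) {
  stopifnot(!anyNA(response))
  if (!is.matrix(predictors)) predictors <- as.matrix(predictors)
  d <- design_values(design)
  if (is.null(d)) d <- matrix(1, length(response), 1L)
  Y <- matrix(response, ncol = 1L)
  complete <- !anyNA(predictors)
  if (complete) {
    sc <- fwl_scan(Y, predictors, d)
    tab <- data.frame(effect = sc$effect[, 1L], se = sc$se[, 1L],
                      t = sc$t[, 1L], p = sc$p[, 1L],
                      n = sc$n, stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, lapply(seq_len(ncol(predictors)), function(j) {
      f <- fwl_fit_one(response, predictors[, j], d)
      data.frame(effect = f$effect, se = f$se, t = f$t, p = f$p, n = f$n)
    }))
  }
  tab$id <- colnames(predictors)
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  if (!nrow(tab)) stop("no fittable predictor (all rank-deficient or missing)")
  ord <- order(tab$p, -abs(tab$t), tab$id)
  w <- tab[ord[1L], ]
  data.frame(best_predictor_id = w$id, effect = w$effect, se = w$se,
             t = w$t, p_value = w$p, n_used = w$n,
             is_significant = w$p < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-CpG cis min-p methylation QTL scan
#'
#' For every variable CpG, scans all SNPs on the CpG's chromosome ("cis" is
#' same-chromosome, with no distance window), reporting the most significant
#' association under an additive genotype model adjusted for the design.
#' Methylation values are outlier-truncated per CpG before fitting. A CpG
#' is genotype-associated when its min-P is below the genome-wide Bonferroni
#' threshold.
#'
#' @param beta a [beta_matrix()] (or [m_matrix()] when fitting on the M
#'   scale) with a CpG map.
#' @param genotypes QC-passed [genotype_data()] with samples matching
#'   `beta`'s columns.
#' @param design a [build_design()] result or plain design matrix.
#' @param variable_cpgs character vector of CpG ids to scan.
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @param truncate truncate methylation outliers before fitting (default
#'   TRUE).
#' @return data.frame with one row per scanned CpG: `cpg_id`,
#'   `best_predictor_id`, `effect`, `se`, `t`, `p_value`, `n_used`,
#'   `is_significant`, ordered by `cpg_id`. CpGs on chromosomes absent from
#'   the genotype map are skipped (recorded in the `skipped` attribute).
#' @export
cis_scan <- function(beta, genotypes, design = NULL, variable_cpgs,
                     threshold = 5e-8, truncate = TRUE) {
  if (is.null(beta$cpg_map)) stop("beta matrix has no CpG map; cis scan needs chromosomes")
  stopifnot(length(variable_cpgs) > 0L)
  samples <- colnames(beta$values)
  if (!identical(samples, colnames(genotypes$dosages))) {
    if (!setequal(samples, colnames(genotypes$dosages)))
      stop("beta and genotype samples differ")
    genotypes$dosages <- genotypes$dosages[, samples, drop = FALSE]
  }
  d <- design_values(design)
  if (is.null(d)) d <- matrix(1, length(samples), 1L)
  map <- beta$cpg_map
  keep <- variable_cpgs[variable_cpgs %in% map$cpg_id]
  chrom <- map$chrom[match(keep, map$cpg_id)]
  snp_chrom <- genotypes$snp_map$chrom
  skipped <- keep[!(chrom %in% snp_chrom)]
  out <- list()
  for (ch in intersect(unique(chrom), unique(snp_chrom))) {
    cp <- keep[chrom == ch]
    snps <- genotypes$snp_map$snp_id[snp_chrom == ch]
    Y <- t(beta$values[cp, , drop = FALSE])          # samples x CpGs
    if (truncate) Y <- t(truncate_outliers_rows(t(Y)))
    X <- t(genotypes$dosages[snps, , drop = FALSE])  # samples x SNPs
    miss <- anyNA(X)
    if (!miss) {
      sc <- fwl_scan(Y, X, d)
      res <- summarize_minp(sc, snps, cp, threshold)
    } else {
      complete_snps <- !apply(X, 2L, anyNA)
      res_fast <- if (any(complete_snps)) {
        sc <- fwl_scan(Y, X[, complete_snps, drop = FALSE], d)
        minp_table(sc, snps[complete_snps], cp)
      } else NULL
      res_slow <- if (any(!complete_snps)) {
        do.call(rbind, lapply(which(!complete_snps), function(j) {
          do.call(rbind, lapply(seq_along(cp), function(i) {
            f <- fwl_fit_one(Y[, i], X[, j], d)
            data.frame(cpg_id = cp[i], best_predictor_id = snps[j],
                       effect = f$effect, se = f$se, t = f$t, p_value = f$p,
                       n_used = f$n, stringsAsFactors = FALSE)
          }))
        }))
      } else NULL
      all_fits <- rbind(res_fast, res_slow)
      all_fits <- all_fits[!is.na(all_fits$p_value), ]
      ord <- order(all_fits$cpg_id, all_fits$p_value, -abs(all_fits$t),
                   all_fits$best_predictor_id)
      all_fits <- all_fits[ord, ]
      res <- all_fits[!duplicated(all_fits$cpg_id), ]
      res$is_significant <- res$p_value < threshold
    }
    out[[ch]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cpg_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "threshold") <- threshold
  res
}

# Reduce a fwl_scan result (q SNPs x m CpGs) to per-CpG min-p records with
# deterministic tie-breaking (smallest p, then largest |t|, then id order).
summarize_minp <- function(sc, snp_ids, cpg_ids, threshold) {
  ordix <- order(snp_ids)
  p <- sc$p[ordix, , drop = FALSE]
  tt <- sc$t[ordix, , drop = FALSE]
  ids <- snp_ids[ordix]
  m <- ncol(p)
  win <- integer(m)
  for (i in seq_len(m)) {
    pc <- p[, i]
    j <- which(pc == min(pc, na.rm = TRUE))
    if (length(j) > 1L) j <- j[order(-abs(tt[j, i]))][1L] else j <- j[1L]
    win[i] <- j
  }
  eff <- sc$effect[ordix, , drop = FALSE]
  se <- sc$se[ordix, , drop = FALSE]
  pick <- cbind(win, seq_len(m))
  data.frame(cpg_id = cpg_ids, best_predictor_id = ids[win],
             effect = eff[pick], se = se[pick], t = tt[pick],
             p_value = p[pick], n_used = sc$n,
             is_significant = p[pick] < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

minp_table <- function(sc, snp_ids, cpg_ids) {
  r <- summarize_minp(sc, snp_ids, cpg_ids, threshold = 1)
  r$is_significant <- NULL
  r
}

#' Eight-category cross-tissue overlap accounting
#'
#' Over the universe of CpGs variable in at least one tissue, assigns each
#' CpG a tri-state status per tissue (associated / variable but not
#' associated / not variable) and counts the eight joint categories; also
#' reports the both-tissue overlap as a percentage of each tissue's
#' associated count (the two-denominator accounting).
#'
#' @param records_a,records_b scan result tables (from [cis_scan()] or
#'   [ewas_scan()]) for the two tissues.
#' @param calls_a,calls_b variability call tables from
#'   [variability_stats()]; CpG universes must agree.
#' @param label_a,label_b tissue labels.
#' @return list with `per_cpg` (cpg_id, status per tissue), `categories`
#'   (8-row count table), and `overlap` (both-associated count and the two
#'   percentages).
#' @export
overlap_eight <- function(records_a, records_b, calls_a, calls_b,
                          label_a = "A", label_b = "B") {
  if (!setequal(calls_a$cpg_id, calls_b$cpg_id))
    stop("variability call universes differ")
  univ <- calls_a$cpg_id[calls_a$is_variable |
                         calls_b$is_variable[match(calls_a$cpg_id, calls_b$cpg_id)]]
  status <- function(records, calls) {
    variable <- calls$is_variable[match(univ, calls$cpg_id)]
    assoc <- univ %in% records$cpg_id[records$is_significant]
    if (any(assoc & !variable))
      stop("CpG associated but not variable in the same tissue: ",
           paste(utils::head(univ[assoc & !variable], 5L), collapse = ", "))
    ifelse(assoc, "associated",
           ifelse(variable, "variable_not_associated", "not_variable"))
  }
  sa <- status(records_a, calls_a)
  sb <- status(records_b, calls_b)
  lev <- c("associated", "variable_not_associated", "not_variable")
  tab <- as.data.frame(table(factor(sa, lev), factor(sb, lev)))
  names(tab) <- c(paste0("status_", label_a), paste0("status_", label_b), "count")
  # drop the (not_variable, not_variable) cell: impossible in this universe
  keep <- !(tab[[1L]] == "not_variable" & tab[[2L]] == "not_variable")
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  n_a <- sum(sa == "associated")
  n_b <- sum(sb == "associated")
  both <- sum(sa == "associated" & sb == "associated")
  list(per_cpg = stats::setNames(
         data.frame(univ, sa, sb, stringsAsFactors = FALSE),
         c("cpg_id", paste0("status_", label_a), paste0("status_", label_b))),
       categories = tab,
       overlap = data.frame(
         both_associated = both,
         pct_of_a = if (n_a) 100 * both / n_a else NA_real_,
         pct_of_b = if (n_b) 100 * both / n_b else NA_real_,
         n_associated_a = n_a, n_associated_b = n_b,
         universe = length(univ)))
}
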