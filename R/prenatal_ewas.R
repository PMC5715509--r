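#' Construct a typed prenatal-factor table
#'
#' The factor panel is configuration, not code: a schema names each factor
#' and types it continuous or categorical, so the scan generalizes beyond
#' any specific variable list.
#'
#' @param data data.frame of per-sample factor values (one row per sample).
#' @param schema data.frame with columns `name` and `type`
#'   ("continuous"/"categorical") covering exactly the factor columns of
#'   `data`.
#' @return object of class `prenatal_factors`.
#' @export
prenatal_factor_table <- function(data, schema) {
  stopifnot(all(c("name", "type") %in% names(schema)),
            all(schema$type %in% c("continuous", "categorical")))
  miss <- setdiff(schema$name, names(data))
  if (length(miss)) stop("schema names missing from data: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(setdiff(names(data), "sample_id"), schema$name)
  if (length(extra)) stop("unschema'd columns: ", paste(extra, collapse = ", "))
  structure(list(data = data, schema = schema), class = "prenatal_factors")
}

#' Pairwise absolute Spearman correlation between prenatal factors
#'
#' Pairwise-complete absolute Spearman correlation; categorical factors are
#' rank-coded by their level index after sorting the level labels. Constant
#' factors have undefined correlation, recorded as NA.
#'
#' @param factors a [prenatal_factor_table()].
#' @return symmetric matrix in \[0,1\] with unit diagonal (NA rows/columns
#'   for constant factors).
#' @export
factor_correlations <- function(factors) {
  sch <- factors$schema
  x <- sapply(sch$name, function(nm) {
    v <- factors$data[[nm]]
    if (sch$type[sch$name == nm] == "categorical")
      v <- as.integer(factor(as.character(v), levels = sort(unique(stats::na.omit(as.character(v))))))
    as.numeric(v)
  })
  const <- apply(x, 2L, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                                    sum(!is.na(v)) < 3L)
  r <- abs(suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")))
  diag(r) <- 1
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  dimnames(r) <- list(sch$name, sch$name)
  r
}

#' Multi-factor EWAS with min-p aggregation
#'
#' Fits, for each variable CpG and each factor, an OLS model of
#' outlier-truncated methylation on \[design + factor\]. Continuous factors
#' are outlier-truncated first and tested by the coefficient t-test;
#' categorical factors are dummy-coded and tested by the overall F-test for
#' the dummy block, with the largest-magnitude level coefficient reported as
#' the effect. Per-factor fits are complete-case in that factor. Each CpG's
#' scan is summarized by its smallest P value; the CpG is called
#' factor-associated when min-P falls below the Bonferroni-style threshold.
#'
#' @param beta a [beta_matrix()] (or [m_matrix()]).
#' @param factors a [prenatal_factor_table()]; rows aligned with samples.
#' @param design a [build_design()] result or plain design matrix.
#' @param variable_cpgs CpG ids to scan.
#' @param threshold min-P call threshold (default 1e-3, the Bonferroni level
#'   for a 45-factor panel at family-wise 0.05).
#' @param max_missing skip factors missing in more than this fraction of
#'   samples (default 0.5).
#' @param truncate truncate methylation outliers before fitting (default
#'   TRUE).
#' @return list with `minp` (per-CpG table: `cpg_id`, `winning_factor`,
#'   `effect`, `se`, `p_value`, `is_significant`), `p_matrix`,
#'   `effect_matrix`, `se_matrix` (CpG x factor), and `skipped_factors`.
#' @export
ewas_scan <- function(beta, factors, design = NULL, variable_cpgs,
                      threshold = 1e-3, max_missing = 0.5, truncate = TRUE) {
  v <- beta$values
  stopifnot(length(variable_cpgs) > 0L)
  cp <- intersect(variable_cpgs, rownames(v))
  Y <- t(v[cp, , drop = FALSE])                    # samples x CpGs
  if (truncate) Y <- t(truncate_outliers_rows(t(Y)))
  d <- design_values(design)
  n <- nrow(Y)
  if (is.null(d)) d <- matrix(1, n, 1L)
  sch <- factors$schema
  m <- length(cp)
  P <- E <- SE <- matrix(NA_real_, m, nrow(sch),
                         dimnames = list(cp, sch$name))
  skipped <- character(0)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    x <- factors$data[[nm]]
    if (mean(is.na(x)) > max_missing) { skipped <- c(skipped, nm); next }
    keep <- !is.na(x)
    Yk <- Y[keep, , drop = FALSE]
    dk <- d[keep, , drop = FALSE]
    if (sch$type[i] == "continuous") {
      xt <- truncate_outliers(as.numeric(x[keep]))
      sc <- fwl_scan(Yk, matrix(xt, ncol = 1L), dk)
      P[, i] <- sc$p[1L, ]; E[, i] <- sc$effect[1L, ]; SE[, i] <- sc$se[1L, ]
    } else {
      f <- droplevels(factor(x[keep]))
      if (nlevels(f) < 2L) { skipped <- c(skipped, nm); next }
      B <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      k <- ncol(B)
      X1 <- cbind(dk, B)
      q0 <- qr(dk); q1 <- qr(X1)
      df1 <- nrow(Yk) - q1$rank
      if (df1 < 2L || q1$rank < q0$rank + k) { skipped <- c(skipped, nm); next }
      rss0 <- colSums(qr.resid(q0, Yk)^2)
      rss1 <- colSums(qr.resid(q1, Yk)^2)
      Fst <- ((rss0 - rss1) / k) / (rss1 / df1)
      Fst[Fst < 0] <- 0
      P[, i] <- pmax(stats::pf(Fst, k, df1, lower.tail = FALSE), 1e-300)
      cf <- qr.coef(q1, Yk)
      bl <- cf[(ncol(dk) + 1L):(ncol(dk) + k), , drop = FALSE]
      pick <- apply(abs(bl), 2L, which.max)
      E[, i] <- bl[cbind(pick, seq_len(m))]
      SE[, i] <- NA_real_
    }
  }
  minp <- apply(P, 1L, min, na.rm = TRUE)
  win <- colnames(P)[apply(P, 1L, which.min)]
  pick <- cbind(seq_len(m), match(win, colnames(P)))
  minp_tab <- data.frame(cpg_id = cp, winning_factor = win,
                         effect = E[pick], se = SE[pick], p_value = minp,
                         is_significant = minp < threshold,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(minp = minp_tab, p_matrix = P, effect_matrix = E, se_matrix = SE,
       skipped_factors = unique(skipped), threshold = threshold)
}

#' Cross-tissue overlap of factor-associated CpGs
#'
#' The same eight-category accounting as [overlap_eight()], applied to
#' factor-scan calls.
#'
#' @param results_a,results_b [ewas_scan()] results.
#' @param calls_a,calls_b variability call tables.
#' @param label_a,label_b tissue labels.
#' @return see [overlap_eight()].
#' @export
pf_overlap <- function(results_a, results_b, calls_a, calls_b,
                       label_a = "A", label_b = "B") {
  overlap_eight(results_a$minp, results_b$minp, calls_a, calls_b,
                label_a, label_b)
}

#' Cross-tissue effect concordance for shared factor associations
#'
#' For each selected CpG, pairs the effect in tissue A for A's winning
#' factor with the effect in tissue B for that same factor, and summarizes
#' sign agreement and the effect-size ratio.
#'
#' @param results_a,results_b [ewas_scan()] results.
#' @param select CpG ids to compare (present in both scans).
#' @return list with `pairs` (cpg_id, factor, effect_a, effect_b),
#'   `sign_agreement` (fraction of pairs with matching effect signs) and
#'   `median_abs_ratio` (median of |effect_b/effect_a|).
#' @export
effect_concordance <- function(results_a, results_b, select) {
  stopifnot(all(select %in% results_a$minp$cpg_id))
  a <- results_a$minp[match(select, results_a$minp$cpg_id), ]
  rows <- list()
  for (i in seq_along(select)) {
    fac <- a$winning_factor[i]
    cpg <- select[i]
    if (!(cpg %in% rownames(results_b$effect_matrix)) ||
        !(fac %in% colnames(results_b$effect_matrix))) next
    eb <- results_b$effect_matrix[cpg, fac]
    if (is.na(eb) || is.na(a$effect[i])) next
    rows[[length(rows) + 1L]] <- data.frame(cpg_id = cpg, factor = fac,
                                            effect_a = a$effect[i],
                                            effect_b = eb,
                                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs))
    return(list(pairs = pairs, sign_agreement = NA_real_,
                median_abs_ratio = NA_real_))
  nz <- pairs$effect_a != 0 & pairs$effect_b != 0
  list(pairs = pairs,
       sign_agreement = mean(sign(pairs$effect_a[nz]) == sign(pairs$effect_b[nz])),
       median_abs_ratio = stats::median(abs(pairs$effect_b / pairs$effect_a),
                                        na.rm = TRUE))
}
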