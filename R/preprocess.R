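#' Truncate outliers to the nearest in-fence observed value
#'
#' Values outside the Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) are replaced
#' by the most extreme observed value inside the fences ("boundary, next
#' possible value"); all other values -- and the output order -- are
#' unchanged. Idempotent, never produces values outside the observed data
#' range, and never changes the rank order of non-outlier values. Missing
#' values are passed through.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @return numeric vector of the same length.
#' @export
truncate_outliers <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[2L] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  v <- pmin(pmax(v, min(inside)), max(inside))
  values[ok] <- v
  values
}

#' Principal component analysis of a methylation matrix
#'
#' Exact SVD of the CpG-wise centered matrix with samples as observations.
#'
#' @param matrix an [m_matrix()] / [beta_matrix()] or plain numeric matrix
#'   (CpGs x samples), complete.
#' @param n_components number of components to return (<= min(samples, CpGs)).
#' @return list with `scores` (samples x components, orthogonal columns) and
#'   `variance_explained` (non-increasing, sums to <= 1).
#' @export
run_pca <- function(matrix, n_components = 10L) {
  v <- if (is.list(matrix)) matrix$values else matrix
  stopifnot(is.matrix(v), !anyNA(v))
  n_components <- min(n_components, ncol(v), nrow(v))
  x <- t(v - rowMeans(v))              # samples x CpGs, CpG-centered
  if (all(abs(x) < 1e-12)) stop("matrix is constant; PCA undefined")
  sv <- svd(x, nu = n_components, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- colnames(v)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  tot <- sum(sv$d^2)
  list(scores = scores,
       variance_explained = sv$d[seq_len(n_components)]^2 / tot)
}

#' Associate principal components with technical variables
#'
#' For each PC x variable pair, a one-way linear-model F-test P value
#' (categorical variables) or simple-regression P value (continuous).
#' Constant PCs give P = 1 by convention; variables with a single level are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param scores PC score matrix from [run_pca()] (samples x components).
#' @param metadata data.frame of per-sample variables, rows aligned with
#'   `scores`.
#' @param variance_explained optional vector aligned with the PC columns.
#' @return data.frame with columns `pc`, `variable`, `p_value`,
#'   `variance_explained`.
#' @export
associate_pcs <- function(scores, metadata, variance_explained = NULL) {
  stopifnot(nrow(scores) == nrow(metadata))
  skipped <- character(0)
  rows <- list()
  for (v in names(metadata)) {
    x <- metadata[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x) && nlevels(droplevels(x)) < 2L) { skipped <- c(skipped, v); next }
    if (!is.factor(x) && stats::var(x, na.rm = TRUE) == 0) { skipped <- c(skipped, v); next }
    for (j in seq_len(ncol(scores))) {
      pc <- scores[, j]
      if (stats::var(pc) < 1e-24) { p <- 1 } else {
        fit <- stats::lm(pc ~ x)
        a <- stats::anova(fit)
        p <- a[["Pr(>F)"]][1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pc = colnames(scores)[j], variable = v, p_value = p,
        variance_explained = if (is.null(variance_explained)) NA_real_
                             else variance_explained[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Empirical-Bayes batch (chip) adjustment on M-values
#'
#' Parametric empirical-Bayes location/scale harmonization: per-CpG batch
#' effects are standardized, shrunk toward their across-CpG batch means via
#' the standard EB updates, and removed; covariate signal is preserved by
#' fitting the covariates alongside the batch design and restoring that fit.
#' CpGs with zero pooled residual variance are harmonized by exact batch-mean
#' removal, so noiseless pure-shift fixtures come out with exactly equal
#' batch means. A single batch level is a no-op.
#'
#' @param matrix an [m_matrix()] or plain numeric matrix (CpGs x samples).
#' @param batch factor/character of batch labels per sample; every batch
#'   needs >= 2 samples.
#' @param covariates optional design (a [build_design()] result or plain
#'   matrix) of covariates to protect; must not encode the batch variable.
#' @return adjusted matrix of the same class and shape.
#' @export
combat_adjust <- function(matrix, batch, covariates = NULL) {
  is_obj <- is.list(matrix) && !is.null(matrix$values)
  dat <- if (is_obj) matrix$values else matrix
  stopifnot(is.matrix(dat), !anyNA(dat))
  batch <- factor(batch)
  if (length(batch) != ncol(dat)) stop("batch length must match sample count")
  if (nlevels(batch) == 1L) return(matrix)
  tab <- table(batch)
  if (any(tab < 2L)) stop("singleton batch: ", names(tab)[tab < 2L][1L])
  n <- ncol(dat)
  nb <- nlevels(batch)
  B <- stats::model.matrix(~ 0 + batch)           # n x nb one-hot
  cov <- design_values(covariates)
  if (!is.null(cov)) {
    # drop intercept/constant columns; batch one-hot spans the intercept
    keep <- apply(cov, 2L, function(x) stats::var(x) > 0)
    cov <- cov[, keep, drop = FALSE]
    if (ncol(cov)) {
      q <- qr(cbind(B, cov))
      if (q$rank < nb + ncol(cov)) {
        drop_idx <- q$pivot[-seq_len(q$rank)]
        drop_idx <- drop_idx[drop_idx > nb] - nb
        if (length(drop_idx)) cov <- cov[, -drop_idx, drop = FALSE]
      }
    }
    if (!ncol(cov)) cov <- NULL
  }
  design <- if (is.null(cov)) B else cbind(B, cov)
  # per-CpG least squares; coefficients (design cols) x CpGs
  bhat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand <- crossprod(as.numeric(tab) / n, bhat[seq_len(nb), , drop = FALSE])
  stand_mean <- t(matrix(grand, n, nrow(dat), byrow = TRUE))  # CpG x samples
  if (!is.null(cov))
    stand_mean <- stand_mean +
      t(cov %*% bhat[-seq_len(nb), , drop = FALSE])
  resid_full <- dat - t(design %*% bhat)
  var_pooled <- rowSums(resid_full^2) / n
  noiseless <- var_pooled < 1e-12
  out <- dat
  batch_idx <- split(seq_len(n), batch)
  if (any(!noiseless)) {
    g <- which(!noiseless)
    sd_g <- sqrt(var_pooled[g])
    s_data <- (dat[g, , drop = FALSE] - stand_mean[g, , drop = FALSE]) / sd_g
    adj <- s_data
    for (bi in seq_len(nb)) {
      cols <- batch_idx[[bi]]
      nbk <- length(cols)
      sb <- s_data[, cols, drop = FALSE]
      gamma_hat <- rowMeans(sb)
      delta_hat <- rowSums((sb - gamma_hat)^2) / (nbk - 1L)
      gamma_bar <- mean(gamma_hat)
      t2 <- stats::var(gamma_hat)
      m_d <- mean(delta_hat); v_d <- stats::var(delta_hat)
      aprior <- (2 * v_d + m_d^2) / v_d
      bprior <- (m_d * v_d + m_d^3) / v_d
      if (!is.finite(aprior) || !is.finite(bprior) || v_d <= 0) {
        # flat prior fallback: no shrinkage across CpGs
        gamma_star <- gamma_hat
        delta_star <- pmax(delta_hat, 1e-12)
      } else {
        gamma_star <- gamma_hat
        delta_star <- delta_hat
        sum2 <- rowSums(sb^2)
        for (it in seq_len(100L)) {
          g_new <- (nbk * t2 * gamma_hat + delta_star * gamma_bar) /
                   (nbk * t2 + delta_star)
          ss <- sum2 - 2 * g_new * nbk * gamma_hat + nbk * g_new^2
          d_new <- (0.5 * ss + bprior) / (nbk / 2 + aprior - 1)
          if (max(abs(g_new - gamma_star), abs(d_new - delta_star)) < 1e-8) {
            gamma_star <- g_new; delta_star <- d_new; break
          }
          gamma_star <- g_new; delta_star <- d_new
        }
      }
      adj[, cols] <- (sb - gamma_star) / sqrt(delta_star)
    }
    out[g, ] <- adj * sd_g + stand_mean[g, , drop = FALSE]
  }
  if (any(noiseless)) {
    g <- which(noiseless)
    for (bi in seq_len(nb)) {
      cols <- batch_idx[[bi]]
      sub <- dat[g, cols, drop = FALSE] - stand_mean[g, cols, drop = FALSE]
      out[g, cols] <- dat[g, cols, drop = FALSE] - rowMeans(sub)
    }
  }
  dimnames(out) <- dimnames(dat)
  if (is_obj) { matrix$values <- out; matrix } else out
}

#' Reference-based cell-type deconvolution
#'
#' Per sample, solves the constrained least-squares projection of the
#' sample's panel-CpG betas onto the reference profiles subject to
#' nonnegativity and sum-to-one. The quadratic program is solved exactly by
#' enumerating active sets (supports) of cell types, which is fast for the
#' panel sizes used in practice (<= ~10 types).
#'
#' @param matrix a [beta_matrix()].
#' @param panel a [cell_reference_panel()]; all panel CpGs must be present
#'   in `matrix`.
#' @return list with `proportions` (samples x cell types, rows on the
#'   probability simplex) and `residual_norm` per sample.
#' @export
estimate_cell_proportions <- function(matrix, panel) {
  A <- panel$profiles
  missing <- setdiff(rownames(A), rownames(matrix$values))
  if (length(missing))
    stop("panel CpGs absent from matrix: ", paste(missing, collapse = ", "))
  if (nrow(A) < ncol(A))
    stop("need at least as many panel CpGs as cell types")
  Y <- matrix$values[rownames(A), , drop = FALSE]
  k <- ncol(A)
  supports <- lapply(seq_len(2^k - 1L), function(mask) which(bitwAnd(mask, 2^(0:(k - 1L))) > 0))
  res <- apply(Y, 2L, function(y) simplex_ls(A, y, supports))
  props <- t(vapply(res, `[[`, numeric(k), "w"))
  colnames(props) <- colnames(A)
  rownames(props) <- colnames(Y)
  list(proportions = props,
       residual_norm = vapply(res, `[[`, numeric(1L), "resid"))
}

# Exact simplex-constrained least squares by support enumeration.
simplex_ls <- function(A, y, supports) {
  k <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (S in supports) {
    m <- length(S)
    As <- A[, S, drop = FALSE]
    K <- rbind(cbind(crossprod(As), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(crossprod(As, y), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_len(m)]
    if (any(w < -1e-9)) next
    obj <- sum((As %*% w - y)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- S; bw <- w
    }
  }
  w_full <- numeric(k)
  w_full[best] <- pmax(bw, 0)
  w_full <- w_full / sum(w_full)
  list(w = w_full, resid = sqrt(best_obj))
}

#' Surrogate variables by residual-matrix PCA
#'
#' Projects the known design out of the M-value matrix and returns the top
#' principal-component scores of the residual matrix as surrogate variables
#' capturing unmodeled structure (hidden batch, composition). Columns are
#' mutually orthogonal; a residual-free matrix yields all-zero scores.
#'
#' @param matrix an [m_matrix()] or plain matrix (CpGs x samples).
#' @param design a [build_design()] result or plain design matrix.
#' @param n_sv number of surrogate variables; must be < n_samples -
#'   rank(design).
#' @return samples x n_sv score matrix.
#' @export
estimate_surrogate_variables <- function(matrix, design, n_sv = 5L) {
  v <- if (is.list(matrix)) matrix$values else matrix
  d <- design_values(design)
  if (is.null(d)) d <- stats::model.matrix(~ 1, data.frame(x = seq_len(ncol(v))))
  qrd <- qr(d)
  if (n_sv >= ncol(v) - qrd$rank) stop("n_sv too large for the residual rank")
  if (n_sv < 1L) return(matrix(numeric(0), ncol(v), 0L))
  R <- t(qr.resid(qrd, t(v)))          # CpGs x samples residual
  sv <- svd(t(R), nu = n_sv, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(n_sv)], n_sv)
  rownames(scores) <- colnames(v)
  colnames(scores) <- paste0("SV", seq_len(n_sv))
  scores
}

#' Build the regression design matrix
#'
#' Encodes the covariates used by every association model: child sex,
#' gestational age, ethnicity (dummy-coded, most frequent level as
#' reference), hospital, bisulfite batch, chip position, and the
#' tissue-specific covariate (DNA extraction batch for cord tissue, chip-set
#' for cord blood); cell proportions enter as their principal components
#' (smallest number retaining >= 90% variance, capped at n_types - 1), with
#' cell-PC x ethnicity-dummy interaction columns appended. Rank-deficient
#' columns are dropped deterministically (QR with pivoting) and logged.
#'
#' @param metadata per-sample data.frame; factor-like columns are
#'   dummy-coded with the most frequent level as reference.
#' @param proportions cell-proportion matrix (samples x types) from
#'   [estimate_cell_proportions()], or NULL to omit cell terms.
#' @param tissue "cord_tissue" (adds `dna_extraction_batch`) or
#'   "cord_blood" (adds `chip_set`); any other label adds neither.
#' @param covariates metadata columns to encode; defaults to the standard
#'   set, intersected with available columns.
#' @param surrogate optional surrogate-variable score matrix to append.
#' @param cell_pc_var variance fraction the cell PCs must retain (default
#'   0.90).
#' @return object of class `design_matrix`: list with `matrix` (full column
#'   rank, rows in sample order), `dropped` (log of dropped columns), and
#'   `rank`.
#' @export
build_design <- function(metadata, proportions = NULL,
                         tissue = c("cord_tissue", "cord_blood", "generic"),
                         covariates = NULL, surrogate = NULL,
                         cell_pc_var = 0.90) {
  tissue <- match.arg(tissue)
  n <- nrow(metadata)
  if (!is.null(proportions) && nrow(proportions) != n)
    stop("metadata and proportions sample counts differ")
  if (is.null(covariates)) {
    covariates <- c("sex", "gestational_age", "ethnicity", "hospital",
                    "bisulfite_batch", "chip_position")
    covariates <- c(covariates,
                    switch(tissue, cord_tissue = "dna_extraction_batch",
                           cord_blood = "chip_set", NULL))
  }
  covariates <- intersect(covariates, names(metadata))
  cols <- list(`(Intercept)` = rep(1, n))
  dropped <- character(0)
  eth_dummies <- NULL
  for (v in covariates) {
    x <- metadata[[v]]
    if (is.numeric(x)) { cols[[v]] <- x; next }
    x <- droplevels(factor(x))
    if (nlevels(x) < 2L) { dropped <- c(dropped, paste0(v, " (single level)")); next }
    ref <- names(sort(table(x), decreasing = TRUE))[1L]
    x <- stats::relevel(x, ref = ref)
    mm <- stats::model.matrix(~ x)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(v, sub("^x", "_", colnames(mm)))
    for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    if (v == "ethnicity") eth_dummies <- mm
  }
  cell_pcs <- NULL
  if (!is.null(proportions) && ncol(proportions) >= 2L) {
    pc <- stats::prcomp(proportions, center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    kmax <- ncol(proportions) - 1L
    k <- min(which(cumsum(ve) >= cell_pc_var), kmax)
    cell_pcs <- pc$x[, seq_len(k), drop = FALSE]
    colnames(cell_pcs) <- paste0("cellPC", seq_len(k))
    for (j in seq_len(k)) cols[[colnames(cell_pcs)[j]]] <- cell_pcs[, j]
    if (!is.null(eth_dummies)) {
      for (j in seq_len(k)) for (e in seq_len(ncol(eth_dummies))) {
        nm <- paste0(colnames(cell_pcs)[j], ":", colnames(eth_dummies)[e])
        cols[[nm]] <- cell_pcs[, j] * eth_dummies[, e]
      }
    }
  }
  if (!is.null(surrogate))
    for (j in seq_len(ncol(surrogate)))
      cols[[colnames(surrogate)[j] %||% paste0("SV", j)]] <- surrogate[, j]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_idx <- sort(q$pivot[-seq_len(q$rank)])
    dropped <- c(dropped, paste0(colnames(X)[drop_idx], " (rank deficient)"))
    X <- X[, -drop_idx, drop = FALSE]
  }
  rownames(X) <- rownames(metadata)
  structure(list(matrix = X, dropped = dropped, rank = qr(X)$rank),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a design_matrix object, a plain matrix, or NULL.
design_values <- function(design) {
  if (is.null(design)) return(NULL)
  if (inherits(design, "design_matrix")) return(design$matrix)
  stopifnot(is.matrix(design))
  design
}

#' @exportS3Method base::print
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d samples x %d columns (rank %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$rank))
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = "; "), "\n")
  invisible(x)
}
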