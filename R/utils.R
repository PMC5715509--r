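# Internal numerical helpers shared across modules.

# Row-wise quantiles with linear interpolation between order statistics
# (type-7), vectorised over the rows of a complete numeric matrix.
row_quantiles <- function(x, probs) {
  n <- ncol(x)
  s <- t(apply(x, 1L, sort.int, method = "quick"))
  if (n == 1L) s <- matrix(x, ncol = 1L)
  out <- matrix(NA_real_, nrow(x), length(probs))
  for (j in seq_along(probs)) {
    h <- (n - 1) * probs[j]
    lo <- floor(h)
    frac <- h - lo
    v <- s[, lo + 1L]
    if (frac > 0) v <- v + frac * (s[, lo + 2L] - v)
    out[, j] <- v
  }
  dimnames(out) <- list(rownames(x), NULL)
  out
}

# Tukey fences (Q1 - k*IQR, Q3 + k*IQR) per row; returns a list of matrices.
row_tukey_fences <- function(x, k = 1.5) {
  q <- row_quantiles(x, c(0.25, 0.75))
  iqr <- q[, 2L] - q[, 1L]
  list(lower = q[, 1L] - k * iqr, upper = q[, 2L] + k * iqr, iqr = iqr,
       q1 = q[, 1L], q3 = q[, 2L])
}

# Row-wise outlier truncation to the most extreme in-fence observed value.
# Each row needs >= 4 values; operates on a complete matrix.
truncate_outliers_rows <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 4L)
  f <- row_tukey_fences(x)
  s <- t(apply(x, 1L, sort.int, method = "quick"))
  n <- ncol(x)
  n_below <- rowSums(s < f$lower)
  n_above <- rowSums(s > f$upper)
  idx <- seq_len(nrow(x))
  min_in <- s[cbind(idx, pmin(n_below + 1L, n))]
  max_in <- s[cbind(idx, pmax(n - n_above, 1L))]
  out <- pmin(pmax(x, min_in), max_in)
  dimnames(out) <- dimnames(x)
  out
}

# Residualize the columns of y against a design matrix using a shared QR.
# Returns residuals; design must be complete and of full column rank after
# pivoting (rank handled by qr).
project_out <- function(y, design) {
  qrd <- qr(design)
  qr.resid(qrd, y)
}

# Frisch-Waugh-Lovell scan core: OLS of each column of Y on [design + x] for
# every column of X, returning effect, SE, t and two-sided P as q x m
# matrices (q predictors, m responses). Y and X are n x m and n x q complete
# matrices sharing the sample dimension. Equivalent to separate per-predictor
# OLS fits; p-values floored at 1e-300.
fwl_scan <- function(Y, X, design) {
  stopifnot(nrow(Y) == nrow(X), nrow(Y) == nrow(design))
  qrd <- qr(design)
  rk <- qrd$rank
  n <- nrow(Y)
  df <- n - rk - 1L
  if (df < 2L) stop("residual degrees of freedom < 2")
  Yr <- qr.resid(qrd, Y)
  Xr <- qr.resid(qrd, X)
  sxx <- colSums(Xr^2)
  syy <- colSums(Yr^2)
  sxy <- crossprod(Xr, Yr)              # q x m
  ok <- sxx > .Machine$double.eps * n   # constant-within-design predictors
  b <- sxy / sxx
  rss <- sweep(-b * sxy, 2L, syy, "+")  # syy - b*sxy
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  se <- sqrt(sweep(sigma2, 1L, sxx, "/"))
  tt <- b / se
  tt[is.nan(tt)] <- 0        # 0/0: no effect, no evidence
  p <- 2 * stats::pt(-abs(tt), df)
  p <- pmax(p, 1e-300)
  if (any(!ok)) { b[!ok, ] <- NA_real_; se[!ok, ] <- NA_real_
                  tt[!ok, ] <- NA_real_; p[!ok, ] <- NA_real_ }
  list(effect = b, se = se, t = tt, p = p, df = df, n = n)
}

# Single-response, single-predictor OLS with complete-case handling; used as
# the slow path when predictors have missing values.
fwl_fit_one <- function(y, x, design) {
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]; d <- design[keep, , drop = FALSE]
  qrd <- qr(d)
  df <- length(y) - qrd$rank - 1L
  if (df < 2L) return(list(effect = NA_real_, se = NA_real_, t = NA_real_,
                           p = NA_real_, n = sum(keep)))
  yr <- qr.resid(qrd, y)
  xr <- qr.resid(qrd, x)
  sxx <- sum(xr^2)
  if (sxx <= .Machine$double.eps * length(y))
    return(list(effect = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, n = sum(keep)))
  b <- sum(xr * yr) / sxx
  rss <- max(sum(yr^2) - b * sum(xr * yr), 0)
  se <- sqrt(rss / df / sxx)
  tt <- if (se > 0) b / se else if (b == 0) 0 else sign(b) * Inf
  list(effect = b, se = se, t = tt,
       p = max(2 * stats::pt(-abs(tt), df), 1e-300), n = sum(keep))
}

# Deterministic seed derivation for sub-stages from one master seed; keeps
# the result inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(offset)) %% 2147483647)
}
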