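#' Per-CpG inter-individual variability statistics
#'
#' For each CpG, computes the methylation range excluding outliers
#' (maximum minus minimum over values inside the Tukey fences at 1.5 x IQR),
#' the 99th minus 1st percentile over all values, and the interquartile
#' range, then calls the CpG variable when the outlier-excluded range
#' exceeds `range_threshold` AND the 99th-1st percentile spread exceeds
#' `tail_threshold` (both strict). Percentiles use linear interpolation
#' between order statistics and, by default, are computed on all values --
#' outlier exclusion applies only to the range clause. All statistics are
#' invariant to sample order.
#'
#' @param betas a [beta_matrix()], a numeric matrix (CpGs x samples), or a
#'   single per-sample numeric vector.
#' @param range_threshold variable call needs range (excluding outliers)
#'   strictly greater than this; default 0.10.
#' @param tail_threshold variable call needs p99 - p1 strictly greater than
#'   this; default 0.05.
#' @param percentile_excl_outliers compute the percentile clause on
#'   outlier-excluded values instead of all values (alternate dialect);
#'   default FALSE.
#' @return data.frame with columns `cpg_id`, `range_excl_outliers`,
#'   `p99_minus_p1`, `iqr`, `is_variable`.
#' @export
variability_stats <- function(betas, range_threshold = 0.10,
                              tail_threshold = 0.05,
                              percentile_excl_outliers = FALSE) {
  tissue <- ""
  if (inherits(betas, "beta_matrix")) { tissue <- betas$tissue; betas <- betas$values }
  if (!is.matrix(betas)) betas <- matrix(betas, nrow = 1L,
                                         dimnames = list("cpg", NULL))
  if (ncol(betas) < 4L) stop("need at least 4 samples per CpG")
  if (anyNA(betas)) stop("missing values are not accepted")
  n <- ncol(betas)
  m <- nrow(betas)
  s <- t(apply(betas, 1L, sort.int, method = "quick"))
  q <- sorted_row_quantiles(s, c(0.25, 0.75, 0.01, 0.99))
  iqr <- q[, 2L] - q[, 1L]
  lower <- q[, 1L] - 1.5 * iqr
  upper <- q[, 2L] + 1.5 * iqr
  n_below <- rowSums(s < lower)
  n_above <- rowSums(s > upper)
  idx <- seq_len(m)
  min_in <- s[cbind(idx, pmin(n_below + 1L, n))]
  max_in <- s[cbind(idx, pmax(n - n_above, 1L))]
  rng <- max_in - min_in
  if (percentile_excl_outliers) {
    p99p1 <- vapply(idx, function(i) {
      v <- s[i, (n_below[i] + 1L):(n - n_above[i])]
      unname(diff(stats::quantile(v, c(0.01, 0.99), names = FALSE)))
    }, numeric(1L))
  } else {
    p99p1 <- q[, 4L] - q[, 3L]
  }
  data.frame(cpg_id = rownames(betas),
             range_excl_outliers = rng,
             p99_minus_p1 = p99p1,
             iqr = iqr,
             is_variable = call_variable(rng, p99p1, range_threshold,
                                         tail_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Type-7 quantiles on an already row-sorted matrix.
sorted_row_quantiles <- function(s, probs) {
  n <- ncol(s)
  out <- matrix(NA_real_, nrow(s), length(probs))
  for (j in seq_along(probs)) {
    h <- (n - 1) * probs[j]
    lo <- floor(h); frac <- h - lo
    v <- s[, lo + 1L]
    if (frac > 0) v <- v + frac * (s[, lo + 2L] - v)
    out[, j] <- v
  }
  out
}

#' Variable-CpG decision rule
#'
#' Strict inequalities on both clauses: range (excluding outliers) greater
#' than 10% and 99th-1st percentile spread greater than 5%, by default.
#'
#' @param range_excl_outliers numeric vector.
#' @param p99_minus_p1 numeric vector.
#' @param range_threshold,tail_threshold thresholds (defaults 0.10, 0.05).
#' @return logical vector.
#' @export
call_variable <- function(range_excl_outliers, p99_minus_p1,
                          range_threshold = 0.10, tail_threshold = 0.05) {
  stopifnot(all(is.finite(range_excl_outliers)), all(is.finite(p99_minus_p1)))
  range_excl_outliers > range_threshold & p99_minus_p1 > tail_threshold
}

#' Four-category cross-tissue partition of CpGs
#'
#' Partitions the shared CpG universe into: variable in both tissues,
#' variable only in tissue A, variable only in tissue B, variable in
#' neither.
#'
#' @param calls_a,calls_b variability call tables from
#'   [variability_stats()] over identical CpG sets.
#' @param label_a,label_b tissue labels used in the category names.
#' @return list with `per_cpg` (cpg_id, category) and `summary`
#'   (category, count, proportion).
#' @export
categorize <- function(calls_a, calls_b, label_a = "A", label_b = "B") {
  if (!setequal(calls_a$cpg_id, calls_b$cpg_id)) {
    d <- union(setdiff(calls_a$cpg_id, calls_b$cpg_id),
               setdiff(calls_b$cpg_id, calls_a$cpg_id))
    stop("CpG sets differ; symmetric difference: ",
         paste(utils::head(d, 10L), collapse = ", "),
         if (length(d) > 10L) " ..." else "")
  }
  b <- calls_b[match(calls_a$cpg_id, calls_b$cpg_id), ]
  va <- calls_a$is_variable; vb <- b$is_variable
  lv <- c("both_variable", paste0(label_a, "_only"), paste0(label_b, "_only"),
          "neither")
  cat <- ifelse(va & vb, lv[1L],
                ifelse(va, lv[2L], ifelse(vb, lv[3L], lv[4L])))
  cat <- factor(cat, levels = lv)
  counts <- as.integer(table(cat))
  list(per_cpg = data.frame(cpg_id = calls_a$cpg_id, category = cat,
                            stringsAsFactors = FALSE),
       summary = data.frame(category = lv, count = counts,
                            proportion = counts / length(cat),
                            stringsAsFactors = FALSE))
}

#' IQR exceedance curve
#'
#' For each threshold on a grid, the proportion of CpGs whose methylation
#' IQR is greater than or equal to the threshold. Non-increasing in the
#' threshold; equals 1 at threshold 0.
#'
#' @param calls variability call table from [variability_stats()].
#' @param grid strictly increasing numeric thresholds.
#' @return data.frame with columns `threshold`, `proportion`.
#' @export
iqr_exceedance_curve <- function(calls, grid = seq(0, 0.5, by = 0.01)) {
  stopifnot(all(diff(grid) > 0))
  prop <- vapply(grid, function(th) mean(calls$iqr >= th), numeric(1L))
  data.frame(threshold = grid, proportion = prop)
}
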