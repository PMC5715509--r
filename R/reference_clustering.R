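#' Per-CpG median methylation profile
#'
#' The median value across all samples represents each CpG for a tissue
#' (linear interpolation for even sample counts).
#'
#' @param matrix a [beta_matrix()] or plain matrix (CpGs x samples).
#' @return named numeric vector of per-CpG medians.
#' @export
median_profile <- function(matrix) {
  v <- if (is.list(matrix)) matrix$values else matrix
  stopifnot(is.matrix(v), ncol(v) >= 1L)
  apply(v, 1L, stats::median)
}

#' Harmonize reference methylomes with cohort median profiles
#'
#' Builds the joint site panel used for clustering. A site is kept iff it
#' (i) is present in every cohort profile, (ii) after masking reference
#' observations with read coverage below `min_coverage` as missing, remains
#' non-missing in at least `min_present` references, and (iii) has
#' interquartile range across reference tissues strictly greater than
#' `min_iqr`. Coverage masking precedes missingness counting, so the filter
#' order is well-defined. Dropped sites carry a provenance label.
#'
#' @param references list of [reference_methylome()] objects (>= 2).
#' @param cohort_profiles named list of per-tissue median profiles (named
#'   numeric vectors keyed by site id), e.g. from [median_profile()].
#' @param min_coverage minimum read coverage (default 30).
#' @param min_present minimum number of references with an observation;
#'   default `ceiling(0.4 * n_references)`, preserving the 10-of-25 ratio.
#' @param min_iqr minimum IQR across references (default 0.10).
#' @return object of class `harmonized_panel`: list with `sites` (retained
#'   site ids), `reference` (sites x reference tissues methylation matrix,
#'   NA where masked/missing), `cohort` (sites x cohort tissues), and
#'   `dropped` (site id + provenance: not_in_cohort, too_missing, low_iqr).
#' @export
harmonize <- function(references, cohort_profiles, min_coverage = 30,
                      min_present = NULL, min_iqr = 0.10) {
  stopifnot(length(references) >= 2L)
  if (is.null(min_present)) min_present <- ceiling(0.4 * length(references))
  ref_names <- vapply(references, `[[`, character(1L), "tissue")
  all_sites <- sort(unique(unlist(lapply(references, function(r) r$sites$site_id))))
  R <- matrix(NA_real_, length(all_sites), length(references),
              dimnames = list(all_sites, ref_names))
  for (j in seq_along(references)) {
    s <- references[[j]]$sites
    meth <- ifelse(!is.na(s$coverage) & s$coverage >= min_coverage, s$meth,
                   NA_real_)
    R[match(s$site_id, all_sites), j] <- meth
  }
  if (is.null(names(cohort_profiles))) names(cohort_profiles) <-
    paste0("cohort_", seq_along(cohort_profiles))
  in_cohort <- Reduce(`&`, lapply(cohort_profiles,
                                  function(p) all_sites %in% names(p)))
  n_obs <- rowSums(!is.na(R))
  present <- n_obs >= min_present
  iqr <- apply(R, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))
  })
  keep <- in_cohort & present & iqr > min_iqr
  provenance <- ifelse(!in_cohort, "not_in_cohort",
                       ifelse(!present, "too_missing", "low_iqr"))
  if (!any(keep)) stop("no sites retained after harmonization")
  C <- vapply(cohort_profiles, function(p) unname(p[all_sites[keep]]),
              numeric(sum(keep)))
  C <- matrix(C, ncol = length(cohort_profiles),
              dimnames = list(all_sites[keep], names(cohort_profiles)))
  structure(list(sites = all_sites[keep],
                 reference = R[keep, , drop = FALSE],
                 cohort = C,
                 dropped = data.frame(site_id = all_sites[!keep],
                                      reason = provenance[!keep],
                                      stringsAsFactors = FALSE)),
            class = "harmonized_panel")
}

#' Hierarchical clustering of cohort and reference methylomes
#'
#' Joins the cohort median profiles with the reference profiles, computes
#' pairwise distances 1 - Spearman correlation over shared non-missing
#' sites, and agglomerates with average linkage (both configurable). Column
#' label order breaks ties deterministically.
#'
#' @param panel a [harmonize()] result.
#' @param method linkage method passed to [stats::hclust()] (default
#'   "average").
#' @param min_shared minimum shared non-missing sites required per pair
#'   (default 3).
#' @return object of class `cluster_result`: list with `hclust`, the
#'   distance matrix `dist`, the column `labels`, and the Spearman
#'   `correlations` between all columns.
#' @export
cluster_panel <- function(panel, method = "average", min_shared = 3L) {
  M <- cbind(panel$cohort, panel$reference)
  if (ncol(M) < 3L) stop("need at least 3 columns to cluster")
  shared <- crossprod(!is.na(M))
  if (any(shared < min_shared)) {
    w <- which(shared < min_shared, arr.ind = TRUE)[1L, ]
    stop(sprintf("columns '%s' and '%s' share fewer than %d non-missing sites",
                 colnames(M)[w[1L]], colnames(M)[w[2L]], min_shared))
  }
  rho <- suppressWarnings(
    stats::cor(M, method = "spearman", use = "pairwise.complete.obs"))
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = method)
  structure(list(hclust = hc, dist = d, labels = colnames(M),
                 correlations = rho),
            class = "cluster_result")
}

#' Spearman correlation of each cohort sample with each reference
#'
#' Pairwise-complete Spearman correlation between every cohort sample's
#' panel-site betas and every reference profile.
#'
#' @param cohort a [beta_matrix()].
#' @param panel a [harmonize()] result.
#' @param min_shared minimum number of shared sites (default 10).
#' @return samples x references correlation matrix.
#' @export
sample_reference_correlation <- function(cohort, panel, min_shared = 10L) {
  shared <- intersect(panel$sites, rownames(cohort$values))
  if (length(shared) < min_shared)
    stop("fewer than ", min_shared, " shared sites between cohort and panel")
  S <- cohort$values[shared, , drop = FALSE]
  R <- panel$reference[shared, , drop = FALSE]
  out <- suppressWarnings(
    stats::cor(S, R, method = "spearman", use = "pairwise.complete.obs"))
  out
}

#' Write a clustering dendrogram in Newick format
#'
#' @param result a [cluster_panel()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(result, path) {
  ape::write.tree(ape::as.phylo(result$hclust), file = path)
  invisible(path)
}
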