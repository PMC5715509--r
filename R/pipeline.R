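#' Pipeline configuration
#'
#' Bundles the inputs, thresholds and toggles for an end-to-end run. Either
#' a [simulation_config()] (synthetic cohort) or a set of input paths (as
#' written by [write_cohort()]) supplies the data.
#'
#' @param simulation a [simulation_config()], or NULL when reading inputs
#'   from `paths`.
#' @param paths named list of input files (`beta_a`, `beta_b`, `cpg_map`,
#'   `dosages`, `snp_map`, `metadata`, `factors`, `factor_schema`,
#'   `panel_a`, `panel_b`); ignored when `simulation` is given.
#' @param thresholds named list; defaults: variability range 0.10 and tail
#'   0.05, mqtl 5e-8, ewas 1e-3, hwe 1e-6, maf 0.10, SNP call rate 0.95,
#'   sample call rate 0.99, reference coverage 30.
#' @param n_sv surrogate variables to append to the design (0 = none).
#' @param response_scale fit associations on the adjusted "beta" scale
#'   (default) or on the "m" scale.
#' @param include_clustering also run the reference-clustering stage on a
#'   simulated reference set (default TRUE).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir optional directory: every intermediate table is written.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, paths = NULL,
                            thresholds = list(), n_sv = 0L,
                            response_scale = c("beta", "m"),
                            include_clustering = TRUE, seed = 1L,
                            out_dir = NULL) {
  response_scale <- match.arg(response_scale)
  th <- utils::modifyList(list(
    variability_range = 0.10, variability_tail = 0.05,
    mqtl = 5e-8, ewas = 1e-3, hwe = 1e-6, maf = 0.10,
    snp_call_rate = 0.95, sample_call_rate = 0.99, coverage = 30), thresholds)
  stopifnot(th$mqtl > 0, th$mqtl <= 1, th$ewas > 0, th$ewas <= 1,
            th$maf >= 0, th$maf <= 0.5)
  if (is.null(simulation) && is.null(paths))
    stop("either simulation or paths must be given")
  structure(list(simulation = simulation, paths = paths, thresholds = th,
                 n_sv = as.integer(n_sv), response_scale = response_scale,
                 include_clustering = include_clustering,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full two-tissue analysis pipeline
#'
#' Stages, in dependency order: cohort acquisition (simulate or read);
#' per-tissue preprocessing (cell-proportion estimation, design
#' construction, empirical-Bayes chip adjustment on M-values, optional
#' surrogate variables); variability mapping and four-category accounting;
#' SNP QC and the cis min-p mQTL scan with eight-category overlap; the
#' multi-factor EWAS with overlap and cross-tissue effect concordance; and
#' (optionally) reference-methylome clustering. Identical config and seed
#' give an identical report.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: per-stage shapes and results,
#'   category/overlap accounting with partition identities, seed and
#'   package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## -- data
  dat <- stage("data", {
    if (!is.null(config$simulation)) simulate_cohort(config$simulation)
    else read_cohort(config$paths)
  })
  tissues <- names(dat$beta)
  stopifnot(length(tissues) == 2L)

  ## -- preprocess per tissue
  pre <- stage("preprocess", lapply(tissues, function(t) {
    b <- dat$beta[[t]]
    props <- estimate_cell_proportions(b, dat$panels[[t]])
    design <- build_design(dat$metadata, props$proportions,
                           tissue = if (t %in% c("cord_tissue", "cord_blood"))
                             t else "generic")
    mv <- beta_to_m(b)
    adj <- combat_adjust(mv, dat$metadata$chip, design)
    if (config$n_sv > 0L) {
      sv <- estimate_surrogate_variables(adj, design, config$n_sv)
      design <- build_design(dat$metadata, props$proportions,
                             tissue = if (t %in% c("cord_tissue", "cord_blood"))
                               t else "generic",
                             surrogate = sv)
    }
    beta_adj <- m_to_beta(adj)
    list(beta_adj = beta_adj, m_adj = adj, design = design,
         proportions = props)
  }))
  names(pre) <- tissues

  ## -- variability
  vb <- stage("variability", lapply(tissues, function(t)
    variability_stats(pre[[t]]$beta_adj,
                      range_threshold = th$variability_range,
                      tail_threshold = th$variability_tail)))
  names(vb) <- tissues
  cats <- stage("variability", categorize(vb[[1L]], vb[[2L]],
                                          tissues[1L], tissues[2L]))

  ## -- genotype QC + cis scan
  qc <- stage("mqtl", snp_qc(dat$genotypes, th$snp_call_rate, th$maf,
                             th$hwe, th$sample_call_rate))
  scans <- stage("mqtl", lapply(tissues, function(t) {
    resp <- if (config$response_scale == "beta") pre[[t]]$beta_adj
            else pre[[t]]$m_adj
    cis_scan(resp, qc$filtered, pre[[t]]$design,
             variable_cpgs = vb[[t]]$cpg_id[vb[[t]]$is_variable],
             threshold = th$mqtl)
  }))
  names(scans) <- tissues
  mqtl_overlap <- stage("mqtl", overlap_eight(scans[[1L]], scans[[2L]],
                                              vb[[1L]], vb[[2L]],
                                              tissues[1L], tissues[2L]))

  ## -- prenatal-factor EWAS
  ewas <- stage("ewas", lapply(tissues, function(t) {
    resp <- if (config$response_scale == "beta") pre[[t]]$beta_adj
            else pre[[t]]$m_adj
    ewas_scan(resp, dat$factors, pre[[t]]$design,
              variable_cpgs = vb[[t]]$cpg_id[vb[[t]]$is_variable],
              threshold = th$ewas)
  }))
  names(ewas) <- tissues
  ewas_overlap <- stage("ewas", pf_overlap(ewas[[1L]], ewas[[2L]],
                                           vb[[1L]], vb[[2L]],
                                           tissues[1L], tissues[2L]))
  sig_a <- ewas[[1L]]$minp$cpg_id[ewas[[1L]]$minp$is_significant]
  concord <- if (length(sig_a))
    stage("ewas", effect_concordance(ewas[[1L]], ewas[[2L]], sig_a)) else NULL

  ## -- reference clustering (synthetic reference set)
  clust <- NULL
  if (isTRUE(config$include_clustering)) {
    clust <- stage("cluster", {
      refset <- simulate_reference_set(seed = derive_seed(config$seed, 7L))
      profiles <- lapply(pre, function(p) median_profile(p$beta_adj))
      # cohort CpGs and reference sites live on different identifier
      # systems; clustering uses the reference panel alone plus cohort
      # medians when site ids intersect. With synthetic references the
      # cohort medians are attached by building a shared panel first.
      panel <- harmonize(refset$references,
                         cohort_profiles = ref_cohort_profiles(refset),
                         min_coverage = th$coverage)
      cl <- cluster_panel(panel)
      list(panel = panel, result = cl, truth = refset$truth)
    })
  }

  ## -- report
  report <- structure(list(
    tissues = tissues,
    shapes = list(
      n_cpgs = nrow(dat$beta[[1L]]$values),
      n_samples = ncol(dat$beta[[1L]]$values),
      n_snps_input = nrow(dat$genotypes$dosages),
      n_snps_pass = nrow(qc$filtered$dosages)),
    variability = vb, categories = cats,
    snp_qc = list(snp = qc$snp, sample = qc$sample),
    mqtl = scans, mqtl_overlap = mqtl_overlap,
    ewas_minp = lapply(ewas, `[[`, "minp"),
    ewas_overlap = ewas_overlap, concordance = concord,
    clustering = clust,
    accounting = pipeline_accounting(cats, mqtl_overlap, ewas_overlap,
                                     scans, ewas, vb),
    seed = config$seed,
    version = as.character(utils::packageVersion("dualtissue"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Synthetic-reference cohort profiles: medians of each lineage's tissues,
# used to stand in for array-derived cohort medians on the shared site ids.
ref_cohort_profiles <- function(refset) {
  lin <- split(refset$truth$tissue, refset$truth$lineage)
  lapply(lin, function(ts) {
    mats <- vapply(ts, function(t) refset$references[[t]]$sites$meth,
                   numeric(nrow(refset$references[[ts[1L]]]$sites)))
    p <- apply(mats, 1L, stats::median, na.rm = TRUE)
    names(p) <- refset$references[[ts[1L]]]$sites$site_id
    p[!is.na(p)]
  })
}

# Category/overlap accounting with the partition identities spelled out.
pipeline_accounting <- function(cats, mqtl_overlap, ewas_overlap, scans,
                                ewas, vb) {
  four <- cats$summary
  stopifnot(sum(four$count) == length(cats$per_cpg$cpg_id),
            abs(sum(four$proportion) - 1) < 1e-9)
  eight_ok <- function(ov) sum(ov$categories$count) == ov$overlap$universe
  stopifnot(eight_ok(mqtl_overlap), eight_ok(ewas_overlap))
  tiss <- names(scans)
  pct <- function(records, calls) {
    nv <- sum(calls$is_variable)
    100 * sum(records$is_significant) / nv
  }
  data.frame(
    tissue = tiss,
    pct_variable = vapply(tiss, function(t) 100 * mean(vb[[t]]$is_variable),
                          numeric(1L)),
    pct_snp_associated = vapply(tiss, function(t) pct(scans[[t]], vb[[t]]),
                                numeric(1L)),
    pct_pf_associated = vapply(tiss, function(t) pct(ewas[[t]]$minp, vb[[t]]),
                               numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

read_cohort <- function(paths) {
  need <- c("beta_a", "beta_b", "cpg_map", "dosages", "snp_map", "metadata",
            "factors", "factor_schema", "panel_a", "panel_b")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  cpg_map <- read_table_tsv(paths$cpg_map)
  read_panel <- function(p) {
    d <- read_table_tsv(p)
    m <- as.matrix(d[-1L]); rownames(m) <- d[[1L]]
    cell_reference_panel(m)
  }
  ba <- read_beta_matrix(paths$beta_a, cpg_map = cpg_map, tissue = "cord_tissue")
  bb <- read_beta_matrix(paths$beta_b, cpg_map = cpg_map, tissue = "cord_blood")
  fd <- read_table_tsv(paths$factors)
  list(beta = list(cord_tissue = ba, cord_blood = bb),
       genotypes = read_genotypes(paths$dosages, "matrix", paths$snp_map),
       metadata = read_table_tsv(paths$metadata),
       factors = prenatal_factor_table(fd, read_table_tsv(paths$factor_schema)),
       panels = list(cord_tissue = read_panel(paths$panel_a),
                     cord_blood = read_panel(paths$panel_b)))
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(report$categories$summary, file.path(dir, "categories.tsv"))
  write_table_tsv(report$accounting, file.path(dir, "accounting.tsv"))
  write_table_tsv(report$mqtl_overlap$categories,
                  file.path(dir, "mqtl_overlap.tsv"))
  write_table_tsv(report$ewas_overlap$categories,
                  file.path(dir, "ewas_overlap.tsv"))
  for (t in report$tissues) {
    write_table_tsv(report$mqtl[[t]], file.path(dir, paste0("mqtl_", t, ".tsv")))
    write_table_tsv(report$ewas_minp[[t]],
                    file.path(dir, paste0("ewas_", t, ".tsv")))
    write_table_tsv(report$variability[[t]],
                    file.path(dir, paste0("variability_", t, ".tsv")))
  }
  if (!is.null(report$clustering))
    write_dendrogram(report$clustering$result, file.path(dir, "dendrogram.nwk"))
  invisible(dir)
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("run_report:", x$shapes$n_cpgs, "CpGs x", x$shapes$n_samples,
      "samples;", x$shapes$n_snps_pass, "of", x$shapes$n_snps_input,
      "SNPs pass QC\n")
  print(x$accounting)
  invisible(x)
}

#' Sensitivity rerun with surrogate variables
#'
#' Repeats the full pipeline with surrogate variables appended to the
#' design and tabulates how the SNP-associated and factor-associated
#' percentages move.
#'
#' @param config a [pipeline_config()] (its `n_sv` is ignored; the base run
#'   uses 0).
#' @param n_sv surrogate variables for the sensitivity run.
#' @return list with `base` and `with_sv` reports plus `delta`: per tissue,
#'   the associated percentages under both designs.
#' @export
sensitivity_rerun <- function(config, n_sv = 5L) {
  base_cfg <- config; base_cfg$n_sv <- 0L
  sv_cfg <- config; sv_cfg$n_sv <- as.integer(n_sv)
  base <- run_pipeline(base_cfg)
  with_sv <- if (n_sv == 0L) base else run_pipeline(sv_cfg)
  delta <- merge(base$accounting, with_sv$accounting, by = "tissue",
                 suffixes = c("_base", "_sv"))
  list(base = base, with_sv = with_sv, delta = delta)
}
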