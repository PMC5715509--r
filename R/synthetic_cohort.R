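#' Simulation configuration for a paired-tissue cohort
#'
#' Defines the generative conditions for a two-tissue neonatal methylation
#' cohort: a bimodal beta landscape with designated variable CpGs, additive
#' cis-SNP effects and prenatal-factor effects implanted on the M scale,
#' chip-level location/scale batch effects, and per-tissue cell-composition
#' mixing. Defaults give a desk-scale cohort (200 samples, 20,000 CpGs,
#' 5,000 SNPs on 4 chromosomes) whose variable-CpG category proportions
#' mirror a two-tissue neonatal cohort (about 20% variable in both tissues,
#' 17.5% in the first tissue only, 3.3% in the second only).
#'
#' @param n_samples number of individuals (default 200).
#' @param n_cpgs number of CpGs (default 20000).
#' @param n_snps number of SNPs (default 5000).
#' @param n_chromosomes chromosomes to lay CpGs and SNPs on (default 4).
#' @param fraction_variable_both fraction of CpGs variable in both tissues
#'   (default 0.200).
#' @param fraction_variable_a_only,fraction_variable_b_only tissue-specific
#'   variable fractions (defaults 0.175 and 0.033).
#' @param n_mqtl_cpgs mQTL-driven CpGs per tissue (default 200).
#' @param mqtl_effect_size per-allele effect, M-value units (default 0.6).
#' @param n_factor_cpgs factor-driven CpGs per tissue (default 100).
#' @param factor_effect_size effect per factor SD, M-value units (default
#'   0.25).
#' @param shared_fraction fraction of mQTL/factor implants shared (same CpG,
#'   same effect) between the tissues (default 0.5).
#' @param allele_frequency_range SNP allele frequency range (default
#'   c(0.15, 0.5)).
#' @param n_chips chips per tissue (default 10); `chip_shift_scale` is the
#'   SD of per-chip location shifts on the M scale (default 0.3), with log
#'   scale factors drawn at SD `chip_shift_scale / 5`.
#' @param chip_shift_scale see `n_chips`.
#' @param cell_types_a,cell_types_b cell types mixed per tissue (defaults:
#'   fibroblast/B-cell/T-cell; and a 7-type blood panel).
#' @param cell_concentration symmetric Dirichlet concentration per cell type
#'   (default 10; larger = less composition variation across samples).
#' @param n_panel_cpgs cell-type-discriminating CpGs per tissue (default
#'   150).
#' @param variable_sd person-level SD (M units) at plain variable CpGs
#'   (default 0.6).
#' @param qtl_residual_sd person-level residual SD (M units) at mQTL- and
#'   factor-driven CpGs (default 0.35).
#' @param noise_sd measurement noise SD, M units (default 0.1).
#' @param cell_mix_noise beta-scale noise at panel CpGs (default 0.02).
#' @param n_factors_continuous,n_factors_categorical prenatal factor counts
#'   (defaults 40 and 5, i.e. a 45-variable panel).
#' @param factor_block_size,factor_block_rho correlation-block structure of
#'   the continuous factors (defaults 5 and 0.3).
#' @param seed mandatory integer seed.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_samples = 200L, n_cpgs = 20000L,
                              n_snps = 5000L, n_chromosomes = 4L,
                              fraction_variable_both = 0.200,
                              fraction_variable_a_only = 0.175,
                              fraction_variable_b_only = 0.033,
                              n_mqtl_cpgs = 200L, mqtl_effect_size = 0.6,
                              n_factor_cpgs = 100L, factor_effect_size = 0.25,
                              shared_fraction = 0.5,
                              allele_frequency_range = c(0.15, 0.5),
                              n_chips = 10L, chip_shift_scale = 0.3,
                              cell_types_a = c("fibroblast", "B_cell", "T_cell"),
                              cell_types_b = c("nRBC", "granulocyte", "monocyte",
                                               "NK_cell", "B_cell", "CD4_T", "CD8_T"),
                              cell_concentration = 10,
                              n_panel_cpgs = 150L,
                              variable_sd = 0.6, qtl_residual_sd = 0.35,
                              noise_sd = 0.1, cell_mix_noise = 0.02,
                              n_factors_continuous = 40L,
                              n_factors_categorical = 5L,
                              factor_block_size = 5L, factor_block_rho = 0.3,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_samples > 0, n_cpgs > 0, n_snps > 0, n_chromosomes > 0,
              fraction_variable_both > 0, fraction_variable_both < 1,
              fraction_variable_both + fraction_variable_a_only +
                fraction_variable_b_only < 1,
              allele_frequency_range[1L] > 0, allele_frequency_range[2L] <= 0.5,
              n_chips >= 2L, cell_concentration > 0, shared_fraction >= 0,
              shared_fraction <= 1)
  })
  n_var_a <- round(n_cpgs * (fraction_variable_both + fraction_variable_a_only))
  n_var_b <- round(n_cpgs * (fraction_variable_both + fraction_variable_b_only))
  if (n_mqtl_cpgs + n_factor_cpgs > min(n_var_a, n_var_b))
    stop("infeasible config: more implants than variable CpGs")
  structure(cfg, class = "simulation_config")
}

#' Simulate a paired-tissue cohort with a ground-truth manifest
#'
#' Generates two tissue beta matrices over a shared CpG set, shared
#' genotypes, sample metadata, a prenatal-factor table, per-tissue cell
#' reference panels, and a manifest recording every implanted effect.
#' Baseline CpG means form a bimodal beta landscape (most CpGs near 0 or 1,
#' variable CpGs intermediate); designated variable CpGs receive
#' person-level variance; mQTL CpGs receive additive per-allele M-scale
#' shifts from a cis SNP on their own chromosome; factor CpGs receive linear
#' M-scale factor effects; chips perturb location and scale on the M scale;
#' panel CpGs are cell-proportion-weighted mixtures of cell-specific
#' profiles. Fully deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `beta` (named list of two [beta_matrix()] objects),
#'   `genotypes`, `metadata`, `factors`, `panels` (per-tissue
#'   [cell_reference_panel()]), and `truth` (per-tissue manifest, chip
#'   table, true cell proportions).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples; m <- cf$n_cpgs
  sample_ids <- sprintf("S%03d", seq_len(n))
  cpg_ids <- sprintf("cg%06d", seq_len(m))
  chrom_cpg <- as.character(rep_len(seq_len(cf$n_chromosomes), m))
  pos_vec <- integer(m)
  for (ch in unique(chrom_cpg)) {
    ix <- which(chrom_cpg == ch)
    pos_vec[ix] <- sort(sample.int(5e7, length(ix)))
  }
  cpg_map <- data.frame(cpg_id = cpg_ids, chrom = chrom_cpg, pos = pos_vec,
                        stringsAsFactors = FALSE)

  ## genotypes
  snp_ids <- sprintf("rs%06d", seq_len(cf$n_snps))
  chrom_snp <- as.character(rep_len(seq_len(cf$n_chromosomes), cf$n_snps))
  pos_snp <- integer(cf$n_snps)
  for (ch in unique(chrom_snp)) {
    ix <- which(chrom_snp == ch)
    pos_snp[ix] <- sort(sample.int(5e7, length(ix)))
  }
  af <- stats::runif(cf$n_snps, cf$allele_frequency_range[1L],
                     cf$allele_frequency_range[2L])
  dos <- matrix(stats::rbinom(cf$n_snps * n, 2L, rep(af, n)),
                nrow = cf$n_snps, ncol = n,
                dimnames = list(snp_ids, sample_ids))
  genotypes <- genotype_data(dos,
    data.frame(snp_id = snp_ids, chrom = chrom_snp, pos = pos_snp,
               ref = "A", alt = "G", stringsAsFactors = FALSE))

  ## metadata
  ethnicity <- sample(c("chinese", "malay", "indian"), n, replace = TRUE,
                      prob = c(0.49, 0.30, 0.21))
  chip <- sprintf("chip%02d", rep_len(seq_len(cf$n_chips), n)[sample.int(n)])
  metadata <- data.frame(
    sample_id = sample_ids,
    sex = sample(c("M", "F"), n, replace = TRUE),
    gestational_age = round(stats::rnorm(n, 38.5, 1.2), 1L),
    ethnicity = ethnicity,
    hospital = sample(c("H1", "H2"), n, replace = TRUE),
    bisulfite_batch = sprintf("B%d", rep_len(1:3, n)[sample.int(n)]),
    chip = chip,
    chip_set = ifelse(chip <= sprintf("chip%02d", cf$n_chips %/% 2L),
                      "set1", "set2"),
    chip_position = sprintf("P%02d", rep_len(1:12, n)[sample.int(n)]),
    dna_extraction_batch = sprintf("E%d", rep_len(1:4, n)[sample.int(n)]),
    stringsAsFactors = FALSE)

  ## prenatal factors: correlated continuous blocks + categorical
  nc <- cf$n_factors_continuous; nk <- cf$n_factors_categorical
  blocks <- split(seq_len(nc),
                  ceiling(seq_len(nc) / cf$factor_block_size))
  Fc <- matrix(NA_real_, n, nc)
  for (b in blocks) {
    shared <- stats::rnorm(n)
    for (j in b)
      Fc[, j] <- sqrt(cf$factor_block_rho) * shared +
                 sqrt(1 - cf$factor_block_rho) * stats::rnorm(n)
  }
  colnames(Fc) <- sprintf("pf_cont_%02d", seq_len(nc))
  Fk <- as.data.frame(replicate(nk, sample(c("low", "mid", "high"), n,
                                           replace = TRUE),
                                simplify = FALSE),
                      stringsAsFactors = FALSE)
  names(Fk) <- sprintf("pf_cat_%02d", seq_len(nk))
  factor_data <- cbind(data.frame(sample_id = sample_ids,
                                  stringsAsFactors = FALSE),
                       as.data.frame(Fc), Fk)
  schema <- data.frame(name = c(colnames(Fc), names(Fk)),
                       type = c(rep("continuous", nc), rep("categorical", nk)),
                       stringsAsFactors = FALSE)
  factors <- prenatal_factor_table(factor_data, schema)

  ## variable-CpG categories shared across tissues
  n_both <- round(m * cf$fraction_variable_both)
  n_a_only <- round(m * cf$fraction_variable_a_only)
  n_b_only <- round(m * cf$fraction_variable_b_only)
  perm <- sample.int(m)
  idx_both <- perm[seq_len(n_both)]
  idx_a_only <- perm[n_both + seq_len(n_a_only)]
  idx_b_only <- perm[n_both + n_a_only + seq_len(n_b_only)]
  var_a <- sort(c(idx_both, idx_a_only))
  var_b <- sort(c(idx_both, idx_b_only))

  ## baselines: bimodal for non-variable, intermediate for variable
  base_m <- ifelse(stats::runif(m) < 0.5, stats::rnorm(m, -4, 0.7),
                   stats::rnorm(m, 4, 0.7))
  inter <- sort(unique(c(var_a, var_b)))
  base_m[inter] <- beta_to_m(stats::runif(length(inter), 0.25, 0.75))

  ## implant bookkeeping (shared implants drawn from both-variable CpGs)
  n_shared_q <- round(cf$shared_fraction * cf$n_mqtl_cpgs)
  n_shared_f <- round(cf$shared_fraction * cf$n_factor_cpgs)
  pool_both <- sample(idx_both)
  need_both <- n_shared_q + n_shared_f
  stopifnot(need_both <= length(pool_both))
  shared_q <- sort(pool_both[seq_len(n_shared_q)])
  shared_f <- sort(pool_both[n_shared_q + seq_len(n_shared_f)])
  used <- c(shared_q, shared_f)
  pick_own <- function(pool, k) {
    avail <- setdiff(pool, used)
    picked <- sort(sample(avail, k))
    used <<- c(used, picked)
    picked
  }
  own_q_a <- pick_own(var_a, cf$n_mqtl_cpgs - n_shared_q)
  own_q_b <- pick_own(var_b, cf$n_mqtl_cpgs - n_shared_q)
  own_f_a <- pick_own(var_a, cf$n_factor_cpgs - n_shared_f)
  own_f_b <- pick_own(var_b, cf$n_factor_cpgs - n_shared_f)

  cont_names <- colnames(Fc)
  assign_mqtl <- function(cpg_idx) {
    snp_idx <- vapply(cpg_idx, function(i) {
      cand <- which(chrom_snp == chrom_cpg[i])
      cand[sample.int(length(cand), 1L)]
    }, integer(1L))
    data.frame(cpg = cpg_idx, snp = snp_idx,
               effect = cf$mqtl_effect_size *
                 sample(c(-1, 1), length(cpg_idx), replace = TRUE))
  }
  assign_factor <- function(cpg_idx) {
    data.frame(cpg = cpg_idx,
               factor = sample(cont_names, length(cpg_idx), replace = TRUE),
               effect = cf$factor_effect_size *
                 sample(c(-1, 1), length(cpg_idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  mq_shared <- assign_mqtl(shared_q)
  pf_shared <- assign_factor(shared_f)
  mq <- list(a = rbind(mq_shared, assign_mqtl(own_q_a)),
             b = rbind(mq_shared, assign_mqtl(own_q_b)))
  pf <- list(a = rbind(pf_shared, assign_factor(own_f_a)),
             b = rbind(pf_shared, assign_factor(own_f_b)))

  tissues <- c(a = "cord_tissue", b = "cord_blood")
  cell_types <- list(a = cf$cell_types_a, b = cf$cell_types_b)
  beta_out <- panels <- truth_manifest <- chips_out <- props_out <- list()

  for (tk in c("a", "b")) {
    var_idx <- if (tk == "a") var_a else var_b
    mqt <- mq[[tk]]; pft <- pf[[tk]]
    driver <- rep("none", m)
    driver[var_idx] <- "random"
    driver[mqt$cpg] <- "mqtl"
    driver[pft$cpg] <- "factor"

    M <- matrix(rep(base_m, n), m, n)
    person_sd <- numeric(m)
    person_sd[var_idx] <- cf$variable_sd
    person_sd[c(mqt$cpg, pft$cpg)] <- cf$qtl_residual_sd
    has_sd <- person_sd > 0
    M[has_sd, ] <- M[has_sd, ] +
      matrix(stats::rnorm(sum(has_sd) * n, 0, person_sd[has_sd]),
             sum(has_sd), n)
    M[mqt$cpg, ] <- M[mqt$cpg, ] + mqt$effect * dos[mqt$snp, , drop = FALSE]
    M[pft$cpg, ] <- M[pft$cpg, ] +
      pft$effect * t(Fc[, pft$factor, drop = FALSE])
    if (cf$noise_sd > 0) M <- M + stats::rnorm(m * n, 0, cf$noise_sd)

    ## chip location/scale on the M scale (deviations from baseline)
    shift <- stats::rnorm(cf$n_chips, 0, cf$chip_shift_scale)
    logscale <- stats::rnorm(cf$n_chips, 0, cf$chip_shift_scale / 5)
    chip_of <- match(metadata$chip, sprintf("chip%02d", seq_len(cf$n_chips)))
    if (cf$chip_shift_scale > 0) {
      dev <- M - base_m
      M <- base_m + t(t(dev) * exp(logscale[chip_of])) +
        matrix(shift[chip_of], m, n, byrow = TRUE)
    }
    B <- m_to_beta(M)

    ## cell composition: panel CpGs are mixtures of cell-specific profiles
    types <- cell_types[[tk]]
    k <- length(types)
    panel_pool <- setdiff(which(driver == "none"), inter)
    panel_idx <- sort(sample(panel_pool, cf$n_panel_cpgs))
    prof <- matrix(stats::runif(cf$n_panel_cpgs * k, 0.05, 0.20),
                   cf$n_panel_cpgs, k,
                   dimnames = list(cpg_ids[panel_idx], types))
    hi <- sample.int(k, cf$n_panel_cpgs, replace = TRUE)
    prof[cbind(seq_len(cf$n_panel_cpgs), hi)] <- stats::runif(cf$n_panel_cpgs,
                                                              0.80, 0.95)
    w <- matrix(stats::rgamma(n * k, shape = cf$cell_concentration), n, k)
    w <- w / rowSums(w)
    dimnames(w) <- list(sample_ids, types)
    mix <- prof %*% t(w)
    if (cf$cell_mix_noise > 0)
      mix <- mix + stats::rnorm(length(mix), 0, cf$cell_mix_noise)
    B[panel_idx, ] <- pmin(pmax(mix, 0), 1)
    driver[panel_idx] <- "cell"

    is_var <- driver %in% c("random", "mqtl", "factor", "cell")
    manifest <- data.frame(
      cpg_id = cpg_ids, is_variable = is_var, driver = driver,
      baseline_m = base_m,
      mqtl_snp_id = NA_character_, mqtl_effect = NA_real_,
      factor_name = NA_character_, factor_effect = NA_real_,
      stringsAsFactors = FALSE)
    manifest$mqtl_snp_id[mqt$cpg] <- snp_ids[mqt$snp]
    manifest$mqtl_effect[mqt$cpg] <- mqt$effect
    manifest$factor_name[pft$cpg] <- pft$factor
    manifest$factor_effect[pft$cpg] <- pft$effect

    dimnames(B) <- list(cpg_ids, sample_ids)
    beta_out[[tissues[[tk]]]] <- beta_matrix(B, cpg_map, tissues[[tk]])
    panels[[tissues[[tk]]]] <- cell_reference_panel(prof)
    truth_manifest[[tissues[[tk]]]] <- manifest
    chips_out[[tissues[[tk]]]] <- data.frame(
      chip = sprintf("chip%02d", seq_len(cf$n_chips)),
      shift = shift, scale = exp(logscale))
    props_out[[tissues[[tk]]]] <- w
  }

  list(beta = beta_out, genotypes = genotypes, metadata = metadata,
       factors = factors, panels = panels,
       truth = list(manifest = truth_manifest, chips = chips_out,
                    cell_proportions = props_out, config = cf))
}

#' Simulate sequencing-based reference methylomes with lineage structure
#'
#' Tissues within a lineage share a lineage-level methylation profile plus
#' small tissue-level deviations; between-lineage divergence exceeds
#' within-lineage divergence by the configured ratio. Per-site read coverage
#' is Poisson around `coverage_mean` (so some sites fall below any chosen
#' threshold), and a fraction of sites is injected as missing per tissue.
#'
#' @param lineage_structure named integer vector: tissues per lineage
#'   (>= 2 lineages of >= 2 tissues).
#' @param n_sites number of sites (default 2000).
#' @param coverage_mean mean read coverage (default 40).
#' @param divergence_ratio between- to within-lineage effect SD ratio
#'   (default 5).
#' @param lineage_sd between-lineage profile SD, M units (default 1.5).
#' @param missing_rate per-tissue missing-site injection rate (default
#'   0.05).
#' @param seed integer seed.
#' @return list with `references` (list of [reference_methylome()]),
#'   `truth` (tissue/lineage table), and `lineage_profiles` (sites x
#'   lineages beta matrix, for building cohort-like profiles).
#' @export
simulate_reference_set <- function(lineage_structure = c(blood = 3L, brain = 3L),
                                   n_sites = 2000L, coverage_mean = 40,
                                   divergence_ratio = 5, lineage_sd = 1.5,
                                   missing_rate = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(lineage_structure) >= 2L, all(lineage_structure >= 2L))
  set.seed(seed)
  site_ids <- sprintf("site%05d", seq_len(n_sites))
  chrom <- as.character(rep_len(1:2, n_sites))
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    pos[ix] <- sort(sample.int(5e7, length(ix)))
  }
  base_m <- ifelse(stats::runif(n_sites) < 0.5, stats::rnorm(n_sites, -2, 1),
                   stats::rnorm(n_sites, 2, 1))
  tissue_sd <- lineage_sd / divergence_ratio
  refs <- list(); truth <- list(); lin_beta <- list()
  for (ln in names(lineage_structure)) {
    lin_m <- base_m + stats::rnorm(n_sites, 0, lineage_sd)
    lin_beta[[ln]] <- m_to_beta(lin_m)
    for (t in seq_len(lineage_structure[[ln]])) {
      tname <- sprintf("%s_%d", ln, t)
      meth <- m_to_beta(lin_m + stats::rnorm(n_sites, 0, tissue_sd))
      coverage <- stats::rpois(n_sites, coverage_mean)
      drop <- stats::runif(n_sites) < missing_rate
      meth[drop] <- NA_real_
      coverage[drop] <- NA_integer_
      refs[[tname]] <- reference_methylome(
        data.frame(site_id = site_ids, chrom = chrom, pos = pos,
                   meth = meth, coverage = coverage,
                   stringsAsFactors = FALSE),
        tissue = tname, lineage = ln)
      truth[[tname]] <- data.frame(tissue = tname, lineage = ln,
                                   stringsAsFactors = FALSE)
    }
  }
  list(references = refs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       lineage_profiles = do.call(cbind, lin_beta))
}

#' Write a simulated cohort to a directory in the standard formats
#'
#' Emits per-tissue beta matrices and CpG map, genotype dosages and SNP map,
#' metadata, factor table and schema, per-tissue cell panels, and the
#' ground-truth manifests (`truth_<tissue>.tsv`).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(sim$beta)) {
    write_beta_matrix(sim$beta[[t]], file.path(dir, paste0("beta_", t, ".tsv")))
    write_table_tsv(sim$truth$manifest[[t]],
                    file.path(dir, paste0("truth_", t, ".tsv")))
    p <- sim$panels[[t]]$profiles
    write_table_tsv(cbind(data.frame(cpg_id = rownames(p)), as.data.frame(p)),
                    file.path(dir, paste0("panel_", t, ".tsv")))
  }
  write_table_tsv(sim$beta[[1L]]$cpg_map, file.path(dir, "cpg_map.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "dosages.tsv"),
                  file.path(dir, "snp_map.tsv"))
  write_table_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  write_table_tsv(sim$factors$data, file.path(dir, "factors.tsv"))
  write_table_tsv(sim$factors$schema, file.path(dir, "factor_schema.tsv"))
  invisible(dir)
}
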