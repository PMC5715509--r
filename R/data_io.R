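#' Construct a methylation beta matrix
#'
#' A beta matrix holds methylation fractions in \[0,1\] for CpGs (rows) by
#' samples (columns), together with an autosomal CpG map (chromosome,
#' 1-based position) and a free-text tissue label. This is the unit every
#' pipeline stage consumes.
#'
#' @param values numeric matrix, CpGs x samples, entries in \[0,1\]; rownames
#'   are CpG identifiers, colnames sample identifiers.
#' @param cpg_map optional data.frame with columns `cpg_id`, `chrom`
#'   (autosome labels "1".."22"; any "chr" prefix is stripped), `pos`
#'   (1-based). When omitted, positional annotation is absent and stages
#'   that need chromosomes (the cis scan) will refuse the object.
#' @param tissue free-text tissue label.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, cpg_map = NULL, tissue = "") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values)) || (nrow(values) > 0L && is.null(rownames(values))))
    stop("values must have CpG rownames and sample colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values))) stop("duplicate CpG ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("missing methylation values are not accepted")
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) stop("beta values outside [0,1] for CpG(s): ",
                      paste(unique(rownames(values)[bad[, 1L]]), collapse = ", "))
  if (!is.null(cpg_map)) {
    cpg_map <- normalize_cpg_map(cpg_map, rownames(values))
  }
  structure(list(values = values, cpg_map = cpg_map, tissue = tissue),
            class = "beta_matrix")
}

normalize_cpg_map <- function(map, ids) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(map)))
  map$chrom <- sub("^chr", "", as.character(map$chrom))
  if (!all(map$chrom %in% as.character(1:22)))
    stop("CpG map contains non-autosomal chromosome labels")
  map <- map[match(ids, map$cpg_id), , drop = FALSE]
  if (anyNA(map$cpg_id)) stop("CpG map does not cover all matrix CpGs")
  rownames(map) <- NULL
  map[c("cpg_id", "chrom", "pos")]
}

#' @exportS3Method base::print
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples%s%s\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$tissue)) paste0(", tissue=", x$tissue) else "",
              if (is.null(x$cpg_map)) ", unannotated" else ""))
  invisible(x)
}

#' Construct an M-value matrix
#'
#' Same axes as a [beta_matrix()], with values on the M scale
#' (log2 methylated/unmethylated ratio, real line).
#'
#' @param values numeric matrix, CpGs x samples, finite.
#' @inheritParams beta_matrix
#' @return An object of class `m_matrix`.
#' @export
m_matrix <- function(values, cpg_map = NULL, tissue = "") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have CpG rownames and sample colnames")
  if (anyNA(values) || any(!is.finite(values))) stop("M-values must be finite")
  if (!is.null(cpg_map)) cpg_map <- normalize_cpg_map(cpg_map, rownames(values))
  structure(list(values = values, cpg_map = cpg_map, tissue = tissue),
            class = "m_matrix")
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into
#' \[epsilon, 1 - epsilon\], so the transform is total and finite. Strictly
#' increasing in beta on the clipped domain.
#'
#' @param beta numeric vector/matrix of methylation fractions, or a
#'   [beta_matrix()].
#' @param epsilon clip tolerance in (0, 0.5); default 1e-6 (deposited-style
#'   matrices contain values at or near 0 and 1).
#' @return Numeric of the same shape, or an [m_matrix()] for a
#'   `beta_matrix` input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  if (inherits(beta, "beta_matrix"))
    return(m_matrix(beta_to_m(beta$values, epsilon), beta$cpg_map, beta$tissue))
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] on the clipped domain: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector/matrix of M-values, or an [m_matrix()].
#' @return Numeric of the same shape, or a [beta_matrix()] for an
#'   `m_matrix` input.
#' @export
m_to_beta <- function(m) {
  if (inherits(m, "m_matrix"))
    return(beta_matrix(m_to_beta(m$values), m$cpg_map, m$tissue))
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) dimnames(out) <- dimnames(m)
  out
}

#' Read a tab-delimited methylation matrix
#'
#' Expects the deposited-file dialect: an identifier column followed by one
#' numeric column per sample, tab-separated, with a header row of sample
#' identifiers.
#'
#' @param path file path.
#' @param id_col name of the identifier column; defaults to the first column
#'   whatever its header (the deposited files' exact header is configurable).
#' @param cpg_map optional CpG map (see [beta_matrix()]).
#' @param tissue tissue label to attach.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, id_col = NULL, cpg_map = NULL, tissue = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("malformed header: need an id column plus samples")
  if (!is.null(id_col)) {
    if (!id_col %in% names(dt)) stop("malformed header: no column '", id_col, "'")
    dt <- dt[c(id_col, setdiff(names(dt), id_col))]
  }
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicate CpG id in ", path, ": ",
                               ids[duplicated(ids)][1L])
  body <- dt[-1L]
  nonnum <- !vapply(body, is.numeric, logical(1L))
  if (any(nonnum)) {
    j <- which(nonnum)[1L]
    bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
    stop(sprintf("non-numeric cell at row %s, column '%s'",
                 ids[bad], names(body)[j]))
  }
  vals <- as.matrix(body)
  rownames(vals) <- ids
  if (anyNA(vals)) stop("missing methylation values are not accepted")
  beta_matrix(vals, cpg_map = cpg_map, tissue = tissue)
}

#' Write a methylation matrix as tab-delimited text
#'
#' CpG rows, sample columns, 6-decimal fixed formatting; byte-stable for
#' identical input.
#'
#' @param matrix a [beta_matrix()] or [m_matrix()].
#' @param path output path.
#' @param id_col header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(matrix, path, id_col = "cpg_id") {
  v <- matrix$values
  header <- paste(c(id_col, colnames(v)), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(v)) {
    body <- apply(v, 1L, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
    writeLines(paste(rownames(v), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Construct genotype data
#'
#' Additive dosages (count of alternate alleles, 0/1/2 or NA) for SNPs
#' (rows) by samples (columns), with a SNP map giving autosomal chromosome,
#' 1-based position and positive-strand ref/alt alleles.
#'
#' @param dosages integer-valued matrix in \{0,1,2,NA\}, SNP rownames and
#'   sample colnames.
#' @param snp_map data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, snp_map) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosages must have SNP rownames and sample colnames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate SNP ids")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be in {0,1,2} or missing")
  stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snp_map)))
  snp_map$chrom <- sub("^chr", "", as.character(snp_map$chrom))
  if (!all(snp_map$chrom %in% as.character(1:22)))
    stop("SNP map contains non-autosomal chromosome labels")
  snp_map <- snp_map[match(rownames(dosages), snp_map$snp_id), , drop = FALSE]
  if (anyNA(snp_map$snp_id)) stop("SNP map does not cover all SNPs")
  rownames(snp_map) <- NULL
  structure(list(dosages = dosages,
                 snp_map = snp_map[c("snp_id", "chrom", "pos", "ref", "alt")]),
            class = "genotype_data")
}

#' @exportS3Method base::print
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d SNPs x %d samples, %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_map$chrom))))
  invisible(x)
}

#' Read genotypes from VCF or a dosage-matrix file
#'
#' For VCF input, only biallelic autosomal records are retained (the count
#' of dropped multi-allelic records is reported via a message) and GT fields
#' are coded as the number of alternate alleles. For matrix input, a
#' companion tab-delimited SNP map (`snp_id`, `chrom`, `pos`, `ref`, `alt`)
#' is required and entries must be 0/1/2 or NA.
#'
#' @param path file path.
#' @param format "vcf" or "matrix"; "auto" guesses from the extension.
#' @param map_path SNP map path (matrix format only).
#' @return A [genotype_data()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    auto <- sub("^chr", "", fix$CHROM) %in% as.character(1:22)
    keep <- !multi & auto
    if (sum(multi)) message(sum(multi), " multi-allelic record(s) dropped")
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean == "0/0"] <- 0; dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean == "1/1"] <- 2
    fix <- fix[keep, , drop = FALSE]
    ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID)
    rownames(dos) <- ids
    map <- data.frame(snp_id = ids, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
    return(genotype_data(dos, map))
  }
  if (is.null(map_path)) stop("matrix format requires a companion SNP map")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  ids <- as.character(dt[[1L]])
  dos <- as.matrix(dt[-1L])
  bad <- !(is.na(dos) | dos %in% c(0, 1, 2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage entry '%s' at SNP %s, sample %s is not in {0,1,2}",
                 dos[bad][1L], ids[w[1L]], colnames(dos)[w[2L]]))
  }
  rownames(dos) <- ids
  map <- data.table::fread(map_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  genotype_data(dos, map)
}

#' Write genotype dosages and SNP map as tab-delimited text
#'
#' @param genotypes a [genotype_data()].
#' @param path dosage-matrix output path.
#' @param map_path SNP map output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, map_path) {
  d <- as.data.frame(genotypes$dosages)
  out <- cbind(snp_id = rownames(genotypes$dosages), d)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  data.table::fwrite(genotypes$snp_map, map_path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read or write a sample metadata / prenatal factor / generic table
#'
#' Thin tab-delimited table IO with a stable column order; the first column
#' is the sample identifier.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = list(character = 1L))
}

#' @rdname read_table_tsv
#' @param x data.frame to write.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a cell-type reference panel
#'
#' Reference beta profiles (CpGs x cell types) used for constrained
#' least-squares deconvolution.
#'
#' @param profiles numeric matrix in \[0,1\], rownames CpG ids, colnames cell
#'   type names.
#' @return An object of class `cell_reference_panel`.
#' @export
cell_reference_panel <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1L, ncol(profiles) >= 2L)
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop("profiles need CpG rownames and cell-type colnames")
  if (any(profiles < 0 | profiles > 1)) stop("reference profiles must be in [0,1]")
  structure(list(profiles = profiles, cell_types = colnames(profiles)),
            class = "cell_reference_panel")
}

#' Construct a reference methylome (sequencing-based, per-site coverage)
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`, `meth`
#'   (fraction in \[0,1\] or NA), `coverage` (integer >= 0 or NA).
#' @param tissue tissue name.
#' @param lineage lineage label (e.g. ectoderm, endoderm, HSC-mesoderm,
#'   MSC-mesoderm).
#' @return An object of class `reference_methylome`.
#' @export
reference_methylome <- function(sites, tissue, lineage = NA_character_) {
  stopifnot(all(c("site_id", "chrom", "pos", "meth", "coverage") %in% names(sites)))
  ok <- is.na(sites$meth) | (sites$meth >= 0 & sites$meth <= 1)
  if (!all(ok)) stop("methylation fractions must be in [0,1]")
  if (any(sites$coverage < 0, na.rm = TRUE)) stop("coverage must be nonnegative")
  structure(list(sites = sites, tissue = tissue, lineage = lineage),
            class = "reference_methylome")
}
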