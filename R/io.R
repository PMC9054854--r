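# File formats: phased VCF (GT only), an RFMix-msp-style TSV for
# per-haplotype ancestry, plain TSVs for matrices/tables, JSON for the
# simulation truth registry. Reading VCF goes through vcfR; everything
# tabular goes through data.table.

#' Write a haplotype panel as a phased VCF
#'
#' Minimal VCFv4.2 with GT-only FORMAT and `|`-separated phased alleles,
#' 1-based positions.
#'
#' @param panel a `haplotype_panel` with alleles.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(!is.null(panel$alleles))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixmeth",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$individuals),
                     collapse = "\t")), con)
  m <- nrow(panel$snps)
  gt <- matrix(paste(panel$alleles[, 1, ], panel$alleles[, 2, ], sep = "|"),
               nrow = dim(panel$alleles)[1])
  lines <- vapply(seq_len(m), function(j)
    paste(c(panel$snps$chrom[j], panel$snps$pos[j], panel$snps$snp_id[j],
            "A", "G", ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"),
    character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a phased VCF into alleles and a SNP table
#'
#' @param path VCF file (GT must be phased with `|`).
#' @return list with `alleles` (n x 2 x m array, NA for missing),
#'   `snps` data.frame (`snp_id`, `chrom`, `pos`, `ref`, `alt`) and
#'   `individuals`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  m <- nrow(gt); n <- ncol(gt)
  h1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)), m, n))
  h2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)), m, n))
  alleles <- array(NA_integer_, c(n, 2, m))
  alleles[, 1, ] <- t(h1)
  alleles[, 2, ] <- t(h2)
  list(alleles = alleles,
       snps = data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"]),
       individuals = colnames(gt))
}

#' Write per-haplotype local ancestry in an RFMix-msp-style TSV
#'
#' One row per SNP (each SNP is its own window), with the usual msp
#' layout: a subpopulation-code comment line, then
#' `#chm spos epos sgpos egpos n snps` followed by two columns per
#' individual (`<id>.0`, `<id>.1`) holding ancestry codes (0 = AFR,
#' 1 = EUR).
#'
#' @param panel a `haplotype_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msp <- function(panel, path) {
  ids <- panel$individuals
  writeLines(c("#Subpopulation order/codes: AFR=0\tEUR=1",
               paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                       paste(rep(ids, each = 2), c(0, 1), sep = ".")),
                     collapse = "\t")), path)
  # msp codes: AFR=0, EUR=1 (internal coding is 1=AFR)
  code <- function(h) ifelse(panel$ancestry[, h, ] == 1L, 0L, 1L)
  c1 <- code(1); c2 <- code(2)
  m <- nrow(panel$snps)
  # interleave hap0/hap1 columns per individual
  inter <- matrix(0L, m, 2 * length(ids))
  inter[, seq(1, 2 * length(ids), 2)] <- t(c1)
  inter[, seq(2, 2 * length(ids), 2)] <- t(c2)
  dt <- data.table::data.table(chm = panel$snps$chrom, spos = panel$snps$pos,
                               epos = panel$snps$pos,
                               sgpos = panel$snps$morgans * 100,
                               egpos = panel$snps$morgans * 100,
                               nsnps = 1L)
  dt <- cbind(dt, data.table::as.data.table(inter))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read an RFMix-msp-style local-ancestry TSV
#'
#' Accepts the dialect written by [write_msp()]: a code legend line, a
#' header line, then one window per row with two ancestry-code columns per
#' individual.
#'
#' @param path msp TSV file.
#' @return list with `ancestry` (n x 2 x m array, 1 = AFR, 0 = EUR),
#'   `snps` data.frame (`chrom`, `pos`) and `individuals`.
#' @export
read_msp <- function(path) {
  legend <- readLines(path, n = 2)
  if (!grepl("AFR=0", legend[1]))
    stop("unrecognized msp subpopulation legend: ", legend[1])
  hdr <- strsplit(sub("^#", "", legend[2]), "\t")[[1]]
  dt <- data.table::fread(path, skip = 2, header = FALSE, sep = "\t")
  samp_cols <- hdr[-(1:6)]
  ids <- unique(sub("\\.[01]$", "", samp_cols))
  m <- nrow(dt); n <- length(ids)
  codes <- as.matrix(dt[, -(1:6)])
  anc <- array(NA_integer_, c(n, 2, m))
  anc[, 1, ] <- t(codes[, seq(1, 2 * n, 2), drop = FALSE] == 0L)
  anc[, 2, ] <- t(codes[, seq(2, 2 * n, 2), drop = FALSE] == 0L)
  list(ancestry = anc,
       snps = data.frame(chrom = dt[[1]], pos = dt[[2]]),
       individuals = ids)
}

#' Write / read a numeric matrix as TSV (rows = features)
#'
#' @param x matrix with row and column names.
#' @param path file path.
#' @param row_label name of the first (row id) column.
#' @return `path` / the matrix.
#' @export
write_matrix_tsv <- function(x, path, row_label = "id") {
  dt <- data.table::data.table(rn = rownames(x))
  data.table::setnames(dt, "rn", row_label)
  data.table::fwrite(cbind(dt, data.table::as.data.table(x)), path,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write the simulation ground-truth registry as JSON
#'
#' The registry round-trips unchanged (up to double precision) through
#' [read_truth_json()], which parameter-recovery tests rely on.
#'
#' @param truth truth list from [simulate_methylation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$effect_spec <- as.data.frame(tr$effect_spec)
  tr
}

#' Write all cohort artifacts to a directory
#'
#' Phased VCF, msp-style local ancestry, methylation / control-probe /
#' covariate / CpG-manifest TSVs and the truth JSON.
#'
#' @param cohort an `admix_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             msp = file.path(dir, "local_ancestry.msp.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             control = file.path(dir, "control_probes.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             cpgs = file.path(dir, "cpg_manifest.tsv"),
             truth = file.path(dir, "truth.json"))
  write_phased_vcf(cohort$panel, paths["vcf"])
  write_msp(cohort$panel, paths["msp"])
  write_matrix_tsv(cohort$methylation, paths["methylation"], "cpg_id")
  write_matrix_tsv(cohort$control, paths["control"], "probe_id")
  data.table::fwrite(cohort$covariates, paths["covariates"], sep = "\t")
  data.table::fwrite(cohort$panel$cpgs, paths["cpgs"], sep = "\t")
  write_truth_json(cohort$truth, paths["truth"])
  invisible(paths)
}
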