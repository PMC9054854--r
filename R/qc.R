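#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact test: conditional on the observed allele counts,
#' the two-sided p-value sums the probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' count. Preferred over the chi-square approximation because the 1e-6
#' cutoff used for variant QC sits in the tail where the approximation is
#' unreliable for rare alleles.
#'
#' @param n_hom_ref,n_het,n_hom_alt nonnegative integer genotype counts.
#' @return exact two-sided p-value; 1 for a monomorphic site.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes")
  n_a <- 2 * n_hom_ref + n_het      # reference allele count
  n_b <- 2 * n_hom_alt + n_het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts share parity
  # log P(het = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_b - hets) / 2 + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Variant quality-control filter
#'
#' Retains biallelic SNPs passing minor-allele-frequency, call-rate,
#' imputation-quality and Hardy-Weinberg filters. A SNP is kept iff
#' MAF >= `maf_min`, call rate >= 1 - `missing_max`, imputation info >=
#' `info_min` (skipped when no info is supplied), HWE exact p >=
#' `hwe_alpha`, and (optionally) both alleles are single nucleotides.
#' Missing genotypes are excluded pairwise from the frequency and HWE
#' computations.
#'
#' @param dosage individuals x SNPs matrix of genotype dosages in
#'   {0,1,2}, `NA` for missing calls.
#' @param info optional per-SNP imputation r-squared.
#' @param alleles optional data.frame with `ref`, `alt` strings used to
#'   drop indels when `snps_only`.
#' @param maf_min,missing_max,info_min,hwe_alpha filter thresholds.
#' @param snps_only drop variants whose ref or alt allele is longer than
#'   one base.
#' @return list with `report` (per-SNP data.frame: maf, call_rate, info,
#'   hwe_p, pass, reasons) and `keep` (logical vector).
#' @export
filter_variants <- function(dosage, info = NULL, alleles = NULL,
                            maf_min = 0.01, missing_max = 0.05,
                            info_min = 0.8, hwe_alpha = 1e-6,
                            snps_only = TRUE) {
  m <- ncol(dosage)
  n_called <- colSums(!is.na(dosage))
  call_rate <- n_called / nrow(dosage)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[n_called == 0] <- NA
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- dosage[, j]; g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  reasons <- vector("list", m)
  add <- function(which, tag) for (j in which) reasons[[j]] <<- c(reasons[[j]], tag)
  add(which(is.na(maf) | maf < maf_min), "maf")
  add(which(call_rate < 1 - missing_max), "missing")
  if (!is.null(info)) add(which(info < info_min), "info")
  add(which(!is.na(hwe_p) & hwe_p < hwe_alpha), "hwe")
  if (snps_only && !is.null(alleles))
    add(which(nchar(alleles$ref) > 1 | nchar(alleles$alt) > 1), "indel")
  pass <- lengths(reasons) == 0
  report <- data.frame(
    snp = if (!is.null(colnames(dosage))) colnames(dosage) else seq_len(m),
    maf = maf, call_rate = call_rate,
    info = if (is.null(info)) NA_real_ else info,
    hwe_p = hwe_p, pass = pass,
    reasons = vapply(reasons, function(r)
      paste(r, collapse = ";"), character(1)))
  if (!any(pass)) warning("no variant passed QC")
  list(report = report, keep = pass)
}
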