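#' Local ancestry at a CpG site
#'
#' Summarizes per-SNP local-ancestry calls into the African proportion at a
#' CpG: a weighted average of African-haplotype dosages (scaled to [0,1])
#' over SNPs inside the flanking window, with weights inversely
#' proportional to the physical distance between SNP and CpG, normalized to
#' sum to one. SNPs closer to the CpG therefore weigh more.
#'
#' `window_bp` is the total span of the flanking region (the default 1 Mb
#' means +/- 500 kb around the CpG); the window is closed on both ends.
#' A SNP exactly at the CpG coordinate is given distance 1 bp so weights
#' stay finite.
#'
#' @param afr_dosage numeric vector (or individuals x SNPs matrix) of
#'   African-haplotype counts in {0,1,2} per SNP.
#' @param snp_pos 1-based physical positions of the SNPs (same chromosome
#'   as the CpG).
#' @param cpg_pos 1-based position of the CpG.
#' @param window_bp total flanking span in bp (default 1e6).
#' @return the local African proportion in [0,1]; `NA` when no SNP falls in
#'   the window. A matrix input returns one value per row.
#' @export
la_at_cpg <- function(afr_dosage, snp_pos, cpg_pos, window_bp = 1e6) {
  if (is.matrix(afr_dosage)) stopifnot(ncol(afr_dosage) == length(snp_pos))
  else stopifnot(length(afr_dosage) == length(snp_pos))
  d <- abs(snp_pos - cpg_pos)
  inside <- d <= window_bp / 2
  if (!any(inside)) {
    return(if (is.matrix(afr_dosage)) rep(NA_real_, nrow(afr_dosage))
           else NA_real_)
  }
  w <- 1 / pmax(d[inside], 1)
  w <- w / sum(w)
  if (is.matrix(afr_dosage)) {
    as.vector(afr_dosage[, inside, drop = FALSE] %*% w) / 2
  } else {
    sum(afr_dosage[inside] * w) / 2
  }
}

#' Local-ancestry matrix over all CpGs
#'
#' Applies [la_at_cpg()] across a CpG manifest, chromosome by chromosome.
#'
#' @param afr_dosage individuals x SNPs matrix of African-haplotype counts.
#' @param snps data.frame with `chrom`, `pos` per SNP (column order must
#'   match `afr_dosage`).
#' @param cpgs data.frame with `cpg_id`, `chrom`, `pos`.
#' @param window_bp total flanking span in bp.
#' @return individuals x CpGs matrix of local African proportions (NA where
#'   the window holds no SNP).
#' @export
la_matrix <- function(afr_dosage, snps, cpgs, window_bp = 1e6) {
  out <- matrix(NA_real_, nrow(afr_dosage), nrow(cpgs),
                dimnames = list(rownames(afr_dosage), cpgs$cpg_id))
  for (ch in unique(cpgs$chrom)) {
    scol <- which(snps$chrom == ch)
    for (j in which(cpgs$chrom == ch)) {
      out[, j] <- la_at_cpg(afr_dosage[, scol, drop = FALSE],
                            snps$pos[scol], cpgs$pos[j], window_bp)
    }
  }
  out
}

#' Global ancestry as the genome-wide average of local ancestry
#'
#' The unweighted mean African proportion across loci — either per-SNP
#' dosages or a CpG-anchored local-ancestry matrix. Individuals with no
#' non-missing locus get `NA`.
#'
#' @param x individuals x loci matrix: African dosages in {0,1,2} (set
#'   `scale = 2`) or proportions in [0,1] (`scale = 1`, the default).
#' @param scale divisor applied to entries before averaging.
#' @return numeric vector of per-individual global African proportions.
#' @export
global_from_local <- function(x, scale = 1) {
  g <- rowMeans(x / scale, na.rm = TRUE)
  g[rowSums(!is.na(x)) == 0] <- NA_real_
  g
}

#' Ancestry-decomposed allele dosage
#'
#' Splits the alternate-allele dosage of a phased genotype by the local
#' ancestry of the haplotype carrying each allele: `snp_afr` counts
#' alternate alleles on African-origin haplotypes, `snp_eur` on
#' European-origin ones. Their sum is always the ordinary genotype dosage.
#'
#' @param allele1,allele2 alleles (0/1) on haplotypes 1 and 2.
#' @param anc1,anc2 haplotype ancestries, 1 = AFR, 0 = EUR (or "AFR"/"EUR").
#' @return data.frame with `snp_afr`, `snp_eur`; `NA` propagates from
#'   missing phase or ancestry (such records are excluded from
#'   ancestry-model fits).
#' @export
decompose_dosage <- function(allele1, allele2, anc1, anc2) {
  to01 <- function(a) if (is.character(a) || is.factor(a))
    as.integer(as.character(a) == "AFR") else as.integer(a)
  a1 <- to01(anc1); a2 <- to01(anc2)
  snp_afr <- allele1 * (a1 == 1L) + allele2 * (a2 == 1L)
  snp_eur <- allele1 * (a1 == 0L) + allele2 * (a2 == 0L)
  data.frame(snp_afr = snp_afr, snp_eur = snp_eur)
}

#' Decompose every SNP of a haplotype panel
#'
#' @param panel a `haplotype_panel` with `alleles` and `ancestry`.
#' @return list of individuals x SNPs matrices `afr`, `eur`, `total`
#'   (total = afr + eur = genotype dosage).
#' @export
decompose_panel <- function(panel) {
  stopifnot(!is.null(panel$alleles))
  afr <- panel$alleles[, 1, ] * (panel$ancestry[, 1, ] == 1L) +
         panel$alleles[, 2, ] * (panel$ancestry[, 2, ] == 1L)
  eur <- panel$alleles[, 1, ] * (panel$ancestry[, 1, ] == 0L) +
         panel$alleles[, 2, ] * (panel$ancestry[, 2, ] == 0L)
  dimnames(afr) <- dimnames(eur) <-
    list(panel$individuals, panel$snps$snp_id)
  list(afr = afr, eur = eur, total = afr + eur)
}

#' Convert methylation beta-values to M-values, and back
#'
#' `M = log2(beta / (1 - beta))`; the M-value scale is approximately
#' homoscedastic and is the response used by all association models here.
#' Beta-values are clipped into `[eps, 1 - eps]` before the transform.
#'
#' @param beta beta-values in (0,1).
#' @param eps clipping epsilon (set 0 to forbid clipping).
#' @return numeric vector/matrix of M-values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  beta <- pmin(pmax(beta, eps), 1 - eps)
  if (any(beta <= 0 | beta >= 1))
    stop("beta-values must lie strictly in (0, 1) after clipping")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
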