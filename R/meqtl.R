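#' Fit the null, conventional, and ancestry meQTL models
#'
#' For one CpG-SNP pair: three nested least-squares fits sharing the
#' covariate block (which includes the CpG's local ancestry in all three
#' models, to control confounding by ancestry background):
#' \itemize{
#'   \item null: covariates + LA;
#'   \item conventional: + total allele dosage (one shared genetic
#'     effect, `b_SNP`);
#'   \item ancestry: + ancestry-decomposed dosages (`b_AFR` on
#'     African-origin, `b_EUR` on European-origin haplotypes).
#' }
#' The ancestry model is equivalently reparameterized as
#' `b_average * SNP + b_diff * (SNP_AFR - SNP_EUR)/2` with
#' `b_average = (b_AFR + b_EUR)/2` and `b_diff = b_AFR - b_EUR`; the
#' 1-df F test of ancestry vs conventional is the test of `b_diff = 0`.
#'
#' @param y methylation M-values.
#' @param X_base samples x covariates design including intercept and the
#'   CpG's local ancestry.
#' @param dosage total allele dosage (0/1/2).
#' @param snp_afr,snp_eur decomposed dosages (must sum to `dosage`).
#' @param min_carriers decomposed columns with fewer carriers than this
#'   are flagged low-confidence (not dropped).
#' @return list with fits `null`, `conventional`, `ancestry` (each
#'   `coef`, `se`, `rss`, `df`, `n`), the derived quantities and test
#'   p-values (`b_snp`, `b_afr`, `b_eur`, `b_average`, `b_diff`,
#'   `p_conv`, `p_anc`, `p_diff`, `p_afr`, `p_eur`), and flags
#'   `inestimable`, `low_confidence`.
#' @export
fit_three_models <- function(y, X_base, dosage, snp_afr, snp_eur,
                             min_carriers = 3) {
  stopifnot(max(abs(snp_afr + snp_eur - dosage), na.rm = TRUE) < 1e-12)
  ok <- stats::complete.cases(X_base, y, dosage, snp_afr, snp_eur)
  y <- y[ok]; X_base <- X_base[ok, , drop = FALSE]
  dosage <- dosage[ok]; snp_afr <- snp_afr[ok]; snp_eur <- snp_eur[ok]
  f_null <- ols_fit(X_base, y)
  f_conv <- ols_fit(cbind(X_base, snp = dosage), y)
  inestimable <- stats::var(snp_afr) == 0 || stats::var(snp_eur) == 0
  low_confidence <- sum(snp_afr > 0) < min_carriers ||
    sum(snp_eur > 0) < min_carriers
  p_conv <- nested_f_test(f_null, f_conv)$p
  if (inestimable) {
    return(list(null = f_null, conventional = f_conv, ancestry = NULL,
                n = f_null$n,
                b_snp = unname(f_conv$coef["snp"]),
                b_afr = NA_real_, b_eur = NA_real_,
                b_average = NA_real_, b_diff = NA_real_,
                p_conv = p_conv, p_anc = NA_real_, p_diff = NA_real_,
                p_afr = NA_real_, p_eur = NA_real_,
                inestimable = TRUE, low_confidence = low_confidence))
  }
  f_anc <- ols_fit(cbind(X_base, snp_afr = snp_afr, snp_eur = snp_eur), y)
  tp <- function(f, nm) {
    tv <- f$coef[nm] / f$se[nm]
    unname(2 * stats::pt(abs(tv), f$df, lower.tail = FALSE))
  }
  list(null = f_null, conventional = f_conv, ancestry = f_anc,
       n = f_anc$n,
       b_snp = unname(f_conv$coef["snp"]),
       b_afr = unname(f_anc$coef["snp_afr"]),
       b_eur = unname(f_anc$coef["snp_eur"]),
       b_average = unname((f_anc$coef["snp_afr"] + f_anc$coef["snp_eur"]) / 2),
       b_diff = unname(f_anc$coef["snp_afr"] - f_anc$coef["snp_eur"]),
       p_conv = p_conv,
       p_anc = nested_f_test(f_null, f_anc)$p,
       p_diff = nested_f_test(f_conv, f_anc)$p,
       p_afr = tp(f_anc, "snp_afr"), p_eur = tp(f_anc, "snp_eur"),
       inestimable = FALSE, low_confidence = low_confidence)
}

#' Nested F test between two least-squares fits
#'
#' `F = ((RSS_small - RSS_big)/ddf) / (RSS_big / df_big)` with the upper
#' tail of the F distribution. The conventional-vs-null and
#' ancestry-vs-conventional comparisons have 1 numerator df, the
#' ancestry-vs-null comparison has 2.
#'
#' @param small,big fits from [ols_fit()]-shaped lists (`rss`, `df`); the
#'   small model must be nested in the big one.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(small, big) {
  ddf <- small$df - big$df
  if (ddf <= 0) stop("models are not nested (no extra parameters)")
  if (small$rss < big$rss - 1e-8 * max(1, big$rss))
    stop("models are not nested (larger model fits worse)")
  Fv <- max(0, (small$rss - big$rss) / ddf) / (big$rss / big$df)
  list(F = Fv, df1 = ddf, df2 = big$df,
       p = stats::pf(Fv, ddf, big$df, lower.tail = FALSE))
}

#' Cis-meQTL scan over significant CpGs
#'
#' Tests every CpG-SNP pair with the SNP inside the CpG's flanking window
#' under the conventional and ancestry models. Significance thresholds are
#' count-derived: the meQTL threshold is `alpha` over the number of pairs
#' tested, and the ancestry-difference (`b_diff`) threshold is `alpha`
#' over the number of ancestry-model-significant meQTLs.
#'
#' @param M CpGs x samples matrix of M-values (rows limited to the CpGs to
#'   scan, typically the EWAS-significant set).
#' @param cpgs data.frame `cpg_id`, `chrom`, `pos` for rows of `M`.
#' @param snps data.frame `snp_id`, `chrom`, `pos` for columns of the
#'   dosage matrices.
#' @param dec list of matrices `afr`, `eur`, `total` as from
#'   [decompose_panel()].
#' @param la samples x CpGs matrix of local ancestry at each scanned CpG.
#' @param X samples x covariates design (intercept + covariates + PCs,
#'   without LA).
#' @param window_bp total flanking span (default 1 Mb = +/- 500 kb).
#' @param alpha family-wise alpha used for both derived thresholds.
#' @return list with `records` (one row per tested pair: coefficients,
#'   p-values, significance flags, pattern label), `n_pairs`,
#'   `meqtl_threshold`, `n_meqtl_anc`, `n_meqtl_conv`, `bdiff_threshold`.
#' @export
cis_scan <- function(M, cpgs, snps, dec, la, X, window_bp = 1e6,
                     alpha = 0.05) {
  stopifnot(nrow(M) == nrow(cpgs), ncol(la) == nrow(cpgs))
  half <- window_bp / 2
  rows <- vector("list", nrow(cpgs))
  skipped <- character(0)
  for (i in seq_len(nrow(cpgs))) {
    js <- which(snps$chrom == cpgs$chrom[i] &
                abs(snps$pos - cpgs$pos[i]) <= half)
    if (length(js) == 0) { skipped <- c(skipped, cpgs$cpg_id[i]); next }
    Xb <- cbind(X, la = la[, i])
    fits <- lapply(js, function(j)
      fit_three_models(M[i, ], Xb, dec$total[, j], dec$afr[, j],
                       dec$eur[, j]))
    rows[[i]] <- data.frame(
      cpg = cpgs$cpg_id[i], snp = snps$snp_id[js],
      chrom = cpgs$chrom[i], snp_pos = snps$pos[js],
      n = vapply(fits, `[[`, 0, "n"),
      b_snp = vapply(fits, `[[`, 0, "b_snp"),
      b_afr = vapply(fits, `[[`, 0, "b_afr"),
      b_eur = vapply(fits, `[[`, 0, "b_eur"),
      b_average = vapply(fits, `[[`, 0, "b_average"),
      b_diff = vapply(fits, `[[`, 0, "b_diff"),
      p_conv = vapply(fits, `[[`, 0, "p_conv"),
      p_anc = vapply(fits, `[[`, 0, "p_anc"),
      p_diff = vapply(fits, `[[`, 0, "p_diff"),
      p_afr = vapply(fits, `[[`, 0, "p_afr"),
      p_eur = vapply(fits, `[[`, 0, "p_eur"),
      inestimable = vapply(fits, `[[`, TRUE, "inestimable"),
      low_confidence = vapply(fits, `[[`, TRUE, "low_confidence"))
  }
  records <- do.call(rbind, rows)
  if (is.null(records))
    return(list(records = NULL, n_pairs = 0L, skipped_cpgs = skipped))
  n_pairs <- nrow(records)
  thr <- bonferroni_threshold(alpha, n_pairs)
  records$sig_conv <- !is.na(records$p_conv) & records$p_conv < thr
  records$sig_anc <- !is.na(records$p_anc) & records$p_anc < thr
  n_anc <- sum(records$sig_anc)
  bdiff_thr <- if (n_anc > 0) bonferroni_threshold(alpha, n_anc) else NA_real_
  records$sig_diff <- !is.na(records$p_diff) & !is.na(bdiff_thr) &
    records$p_diff < bdiff_thr
  records$pattern <- NA_character_
  anc_ok <- records$sig_anc & !records$inestimable
  records$pattern[anc_ok] <- classify_pattern(
    records$b_afr[anc_ok], records$b_eur[anc_ok],
    records$p_afr[anc_ok], records$p_eur[anc_ok],
    records$p_diff[anc_ok], p_diff_threshold = bdiff_thr)
  list(records = records, n_pairs = n_pairs, meqtl_threshold = thr,
       n_meqtl_conv = sum(records$sig_conv), n_meqtl_anc = n_anc,
       bdiff_threshold = bdiff_thr, skipped_cpgs = skipped)
}

#' Classify the ancestry-specific effect pattern of a meQTL
#'
#' Taxonomy of ancestry-specific genetic effects for
#' ancestry-model-significant meQTLs: when the African/European effect
#' difference is not significant the effects are `comparable`; otherwise
#' the per-ancestry coefficient t tests (at `alpha_coeff`) decide between
#' `opposite` (both significant, opposite signs),
#' `same_direction_diff_magnitude` (both significant, same sign),
#' `african_only` and `european_only`.
#'
#' @param b_afr,b_eur per-ancestry effect estimates.
#' @param p_afr,p_eur their coefficient t-test p-values.
#' @param p_diff the ancestry-vs-conventional F-test p-value.
#' @param alpha_coeff per-coefficient significance level (default 0.05).
#' @param p_diff_threshold significance threshold for the effect
#'   difference (count-derived Bonferroni in a scan).
#' @return character vector of pattern labels.
#' @export
classify_pattern <- function(b_afr, b_eur, p_afr, p_eur, p_diff,
                             alpha_coeff = 0.05, p_diff_threshold = 0.05) {
  out <- rep(NA_character_, length(b_afr))
  diff_sig <- !is.na(p_diff) & p_diff < p_diff_threshold
  afr_sig <- !is.na(p_afr) & p_afr < alpha_coeff
  eur_sig <- !is.na(p_eur) & p_eur < alpha_coeff
  out[!diff_sig] <- "comparable"
  both <- diff_sig & afr_sig & eur_sig
  out[both & sign(b_afr) != sign(b_eur)] <- "opposite"
  out[both & sign(b_afr) == sign(b_eur)] <- "same_direction_diff_magnitude"
  out[diff_sig & afr_sig & !eur_sig] <- "african_only"
  out[diff_sig & !afr_sig & eur_sig] <- "european_only"
  out[diff_sig & !afr_sig & !eur_sig] <- "comparable"
  out
}

#' Replication of lead meQTLs in an independent cohort
#'
#' Restricted (by the caller) to CpGs whose EWAS association replicated. A
#' lead meQTL replicates when its ancestry-vs-null p-value in the
#' replication cohort is below `alpha` over the number of leads tested;
#' the ancestry-difference test replicates when `p_diff` is below `alpha`
#' over the number of leads with a significant difference in discovery.
#'
#' @param leads data.frame of discovery lead meQTLs (`cpg`, `snp`,
#'   `sig_diff`).
#' @param replication data.frame of replication-cohort fits (`cpg`,
#'   `snp`, `p_anc`, `p_diff`).
#' @param alpha total replication alpha (default 0.05).
#' @return list with `flags` per lead (`testable`, `replicated`,
#'   `diff_replicated`) and `summary` (both thresholds and counts).
#' @export
replicate_meqtl <- function(leads, replication, alpha = 0.05) {
  m <- nrow(leads)
  if (m == 0) stop("no lead meQTLs to replicate")
  thr_anc <- bonferroni_threshold(alpha, m)
  m_diff <- sum(leads$sig_diff)
  thr_diff <- if (m_diff > 0) bonferroni_threshold(alpha, m_diff) else NA_real_
  key <- paste(replication$cpg, replication$snp)
  idx <- match(paste(leads$cpg, leads$snp), key)
  testable <- !is.na(idx) & !is.na(replication$p_anc[idx])
  p_anc <- replication$p_anc[idx]
  p_diff <- replication$p_diff[idx]
  replicated <- testable & p_anc < thr_anc
  diff_replicated <- leads$sig_diff & testable & !is.na(thr_diff) &
    !is.na(p_diff) & p_diff < thr_diff
  list(flags = data.frame(cpg = leads$cpg, snp = leads$snp,
                          testable = testable,
                          replicated = replicated %in% TRUE,
                          diff_replicated = diff_replicated %in% TRUE),
       summary = list(threshold_anc = thr_anc, threshold_diff = thr_diff,
                      n_leads = m, n_diff_leads = m_diff,
                      n_replicated = sum(replicated %in% TRUE),
                      pct_replicated = 100 * sum(replicated %in% TRUE) / m,
                      n_diff_replicated = sum(diff_replicated %in% TRUE)))
}
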