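#' Positional (annotation) enrichment of a significant CpG set
#'
#' For each annotation, the fold change is the annotation coverage among
#' significant CpGs divided by the coverage in the universe of tested
#' CpGs; values above 1 indicate enrichment and below 1 depletion. The
#' p-value is hypergeometric, taken in the tail matching the direction of
#' the fold change (upper for enrichment, lower for depletion), and
#' adjusted across annotations by Benjamini-Hochberg. Probes with a
#' missing value for an annotation are excluded from both numerator and
#' denominator for that annotation; probes carrying several annotations
#' count in each.
#'
#' @param significant character vector of significant CpG ids (must be a
#'   subset of the universe; must be non-empty).
#' @param universe character vector of all tested CpG ids.
#' @param annotations data.frame with a `cpg_id` column plus one
#'   logical column per annotation.
#' @param fdr_alpha significance level on the adjusted p-values.
#' @return data.frame with one row per annotation: coverage in the
#'   significant set and universe, `fold_change`, `p`, `fdr`,
#'   `significant`.
#' @export
annotation_enrichment <- function(significant, universe, annotations,
                                  fdr_alpha = 0.05) {
  if (length(significant) == 0) stop("empty significant set")
  if (!all(significant %in% universe))
    stop("significant CpGs must be a subset of the universe")
  ann_cols <- setdiff(names(annotations), "cpg_id")
  ann <- annotations[match(universe, annotations$cpg_id), ]
  in_sig <- universe %in% significant
  rows <- lapply(ann_cols, function(a) {
    v <- ann[[a]]
    usable <- !is.na(v)
    N <- sum(usable); K <- sum(v[usable])
    n <- sum(in_sig & usable); k <- sum(v[usable] & in_sig[usable])
    cov_sig <- if (n > 0) k / n else NA_real_
    cov_all <- if (N > 0) K / N else NA_real_
    fc <- if (!is.na(cov_all) && cov_all > 0) cov_sig / cov_all else NA_real_
    p <- if (is.na(fc)) NA_real_
    else if (fc >= 1)
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else stats::phyper(k, K, N - K, n)
    data.frame(annotation = a, n_significant = n, k_significant = k,
               coverage_significant = cov_sig, coverage_universe = cov_all,
               fold_change = fc, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_alpha
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]).
#'
#' @param p vector of p-values.
#' @return adjusted p-values, capped at 1.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Trait-overlap enrichment against a CpG catalog
#'
#' For every catalog trait sharing at least one CpG with the significant
#' set, tests the 2x2 overlap table (in/out of the significant set by
#' in/out of the trait's CpG set, over the universe) with Fisher's exact
#' test. The significance cutoff is `alpha` Bonferroni-corrected for the
#' number of traits with nonzero overlap.
#'
#' @param significant significant CpG ids.
#' @param catalog data.frame with columns `trait`, `cpg_id` (one row per
#'   association; supplied as a file, no remote lookup).
#' @param universe all tested CpG ids.
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame per overlapping trait: overlap count, odds ratio
#'   (conditional MLE; `Inf` possible), `p`, `bonferroni_threshold`,
#'   `significant`. Empty catalog gives an empty result.
#' @export
trait_enrichment <- function(significant, catalog, universe, alpha = 0.05) {
  if (is.null(catalog) || nrow(catalog) == 0)
    return(data.frame(trait = character(0), n_overlap = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      bonferroni_threshold = numeric(0),
                      significant = logical(0)))
  catalog <- catalog[catalog$cpg_id %in% universe, ]
  in_sig <- universe %in% significant
  sets <- split(catalog$cpg_id, catalog$trait)
  overlaps <- vapply(sets, function(s)
    length(intersect(s, significant)), integer(1))
  sets <- sets[overlaps >= 1]
  if (length(sets) == 0)
    return(trait_enrichment(significant, catalog[0, ], universe, alpha))
  thr <- bonferroni_threshold(alpha, length(sets))
  rows <- lapply(names(sets), function(tr) {
    in_trait <- universe %in% sets[[tr]]
    tab <- table(factor(in_sig, c(TRUE, FALSE)),
                 factor(in_trait, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    data.frame(trait = tr, n_overlap = tab[1, 1],
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_threshold <- thr
  out$significant <- out$p < thr
  out[order(out$p, out$trait), ]
}
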