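#' Pairwise LD as squared dosage correlation
#'
#' Composite-genotype LD: the squared Pearson correlation of unphased
#' allele dosages computed on shared complete cases.
#'
#' @param a,b dosage vectors (0/1/2, `NA` allowed).
#' @return r-squared in [0, 1]; a constant vector gives 0 with a warning.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    warning("LD undefined for a constant dosage vector; returning 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Clump correlated meQTL SNPs into loci
#'
#' PLINK-style greedy seeding followed by the merge rules used for short
#' African-American LD blocks: the lowest-p unassigned SNP seeds a clump
#' and captures every unassigned SNP correlated with it at
#' `r2 >= r2_independent`; once all SNPs are assigned, any clump with
#' fewer than `min_snps` members or lying within `merge_bp` of another
#' clump (boundary-to-boundary distance) is merged into its nearest clump,
#' iterated to a fixed point. The lead SNP of a clump is its lowest-p
#' member. Ties in "nearest" are broken by the smaller boundary gap, then
#' by the lower lead p.
#'
#' @param meqtls data.frame with `snp`, `pos`, `p` (significant meQTLs
#'   for one CpG; any extra columns are carried through).
#' @param G samples x SNPs dosage matrix, columns named by SNP id (used
#'   for r-squared).
#' @param r2_independent r-squared below which two SNPs count as
#'   independent (default 0.01).
#' @param min_snps minimum clump size before merging (default 10).
#' @param merge_bp merge clumps closer than this many bp (default 250 kb).
#' @return list with `membership` (input rows plus `clump`) and `clumps`
#'   (per clump: `clump`, `lead_snp`, `lead_p`, `n_members`, `start`,
#'   `end`, `span`).
#' @export
clump_meqtls <- function(meqtls, G, r2_independent = 0.01, min_snps = 10,
                         merge_bp = 250000) {
  if (is.null(meqtls) || nrow(meqtls) == 0)
    return(list(membership = meqtls, clumps = NULL))
  # deterministic order: p, then position, then id
  ord <- order(meqtls$p, meqtls$pos, meqtls$snp)
  meqtls <- meqtls[ord, ]
  cl <- rep(NA_integer_, nrow(meqtls))
  nxt <- 0L
  for (i in seq_len(nrow(meqtls))) {
    if (!is.na(cl[i])) next
    nxt <- nxt + 1L
    cl[i] <- nxt
    un <- which(is.na(cl))
    if (length(un)) {
      r2 <- vapply(un, function(j)
        suppressWarnings(ld_r2(G[, meqtls$snp[i]], G[, meqtls$snp[j]])),
        numeric(1))
      cl[un[r2 >= r2_independent]] <- nxt
    }
  }
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) <= 1) break
    info <- do.call(rbind, lapply(ids, function(k) {
      w <- cl == k
      data.frame(id = k, n = sum(w), start = min(meqtls$pos[w]),
                 end = max(meqtls$pos[w]), lead_p = min(meqtls$p[w]))
    }))
    gap <- function(a, b) max(0, max(info$start[a], info$start[b]) -
                                 min(info$end[a], info$end[b]))
    nearest <- function(a) {
      others <- setdiff(seq_len(nrow(info)), a)
      gaps <- vapply(others, function(b) gap(a, b), numeric(1))
      cand <- others[gaps == min(gaps)]
      cand[order(info$lead_p[cand])][1]
    }
    min_gap <- vapply(seq_len(nrow(info)), function(a)
      min(vapply(setdiff(seq_len(nrow(info)), a), function(b) gap(a, b),
                 numeric(1))), numeric(1))
    flagged <- which(info$n < min_snps | min_gap < merge_bp)
    if (length(flagged) == 0) break
    # merge the least significant flagged clump into its nearest neighbour
    a <- flagged[order(-info$lead_p[flagged], info$id[flagged])][1]
    cl[cl == info$id[a]] <- info$id[nearest(a)]
  }
  cl <- match(cl, sort(unique(cl)))
  meqtls$clump <- cl
  clumps <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    w <- which(cl == k)
    w <- w[order(meqtls$pos[w])]
    lead <- w[which.min(meqtls$p[w])]
    data.frame(clump = k, lead_snp = meqtls$snp[lead],
               lead_p = meqtls$p[lead], n_members = length(w),
               start = meqtls$pos[w[1]], end = meqtls$pos[w[length(w)]],
               span = meqtls$pos[w[length(w)]] - meqtls$pos[w[1]])
  }))
  membership <- meqtls[order(meqtls$clump, meqtls$pos, meqtls$snp), ]
  list(membership = membership, clumps = clumps)
}

#' Clump a full meQTL table per CpG
#'
#' Applies [clump_meqtls()] separately to the significant meQTLs of each
#' CpG (the default) or to the pooled table (`per_cpg = FALSE`).
#'
#' @param records meQTL records (needs `cpg`, `snp`, `snp_pos`, a p-value
#'   column `p_col`, and a significance flag column `sig_col`).
#' @param G samples x SNPs dosage matrix with named columns.
#' @param p_col,sig_col names of the p-value/flag columns to use
#'   (`p_anc`/`sig_anc` for the ancestry model, `p_conv`/`sig_conv` for
#'   the conventional one).
#' @param per_cpg clump within CpG (default) or globally.
#' @inheritParams clump_meqtls
#' @return data.frame of clumps with a `cpg` column (NA in global mode).
#' @export
clump_scan <- function(records, G, p_col = "p_anc", sig_col = "sig_anc",
                       per_cpg = TRUE, r2_independent = 0.01,
                       min_snps = 10, merge_bp = 250000) {
  sig <- records[records[[sig_col]] %in% TRUE, ]
  if (nrow(sig) == 0) return(NULL)
  one <- function(d, cpg) {
    cc <- clump_meqtls(data.frame(snp = d$snp, pos = d$snp_pos,
                                  p = d[[p_col]]),
                       G, r2_independent, min_snps, merge_bp)$clumps
    cbind(cpg = cpg, cc)
  }
  if (per_cpg) {
    do.call(rbind, lapply(split(sig, sig$cpg), function(d)
      one(d, d$cpg[1])))
  } else {
    one(sig[!duplicated(sig$snp), ], NA_character_)
  }
}
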