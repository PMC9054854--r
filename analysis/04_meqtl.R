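#!/usr/bin/env Rscript
# Cis-meQTL scan for the LA-associated CpGs: null, conventional, and
# ancestry-decomposed models per CpG-SNP pair in a 1 Mb window, nested F
# tests, count-derived thresholds, ancestry-specific effect patterns,
# LD clumping of significant meQTLs, and replication of lead meQTLs in
# the second cohort.

suppressMessages({library(admixmeth); library(data.table)})

cov_cols <- c("age", "smoker", "log10_peth", "adherence", "log10_vl",
              "wbc", "cd4", "cd8", "gran", "nk", "bcell", "mono")

scan_group <- function(grp, cpg_ids) {
  dir <- file.path("results", "data", grp)
  vcf <- read_phased_vcf(file.path(dir, "genotypes.vcf"))
  msp <- read_msp(file.path(dir, "local_ancestry.msp.tsv"))
  M <- read_matrix_tsv(file.path(dir, "methylation.tsv"))
  ctrl <- read_matrix_tsv(file.path(dir, "control_probes.tsv"))
  covs <- as.data.frame(fread(file.path(dir, "covariates.tsv")))
  la <- t(read_matrix_tsv(file.path(dir, "local_ancestry_cpg.tsv")))
  ga <- fread(file.path(dir, "global_ancestry.tsv"))$global_afr
  cpgs <- as.data.frame(fread(file.path(dir, "cpg_manifest.tsv")))
  keep <- fread(file.path(dir, "variant_qc.tsv"))$pass
  aa <- covs$race == 1
  idx <- match(cpg_ids, cpgs$cpg_id)
  anc1 <- msp$ancestry[aa, 1, keep]; anc2 <- msp$ancestry[aa, 2, keep]
  al1 <- vcf$alleles[aa, 1, keep]; al2 <- vcf$alleles[aa, 2, keep]
  dec <- list(afr = al1 * (anc1 == 1L) + al2 * (anc2 == 1L),
              eur = al1 * (anc1 == 0L) + al2 * (anc2 == 0L))
  dec$total <- dec$afr + dec$eur
  colnames(dec$total) <- vcf$snps$snp_id[keep]
  cpcs <- control_probe_pcs(ctrl, k = min(30, nrow(ctrl) - 1))
  X <- cbind(intercept = 1, as.matrix(covs[aa, cov_cols]),
             cpcs[aa, , drop = FALSE], ga = ga[aa])
  sc <- cis_scan(M[idx, aa, drop = FALSE], cpgs[idx, ],
                 vcf$snps[keep, ], dec, la[aa, idx, drop = FALSE], X,
                 window_bp = 1e6)
  sc$G <- dec$total
  sc
}

ewas_la <- fread("results/ewas/discovery_la.tsv")
sig_cpgs <- ewas_la$cpg[ewas_la$significant]
stopifnot(length(sig_cpgs) > 0)
message(length(sig_cpgs), " LA-associated CpGs enter the cis-meQTL scan")

disc <- scan_group("discovery", sig_cpgs)
dir.create("results/meqtl", showWarnings = FALSE, recursive = TRUE)
fwrite(disc$records, "results/meqtl/discovery_meqtl.tsv", sep = "\t")
message(sprintf(
  "%d pairs tested (threshold %.3g): %d conventional-model, %d ancestry-model meQTLs",
  disc$n_pairs, disc$meqtl_threshold, disc$n_meqtl_conv, disc$n_meqtl_anc))
if (!is.na(disc$bdiff_threshold))
  message(sprintf("ancestry-difference threshold %.3g: %d significant; patterns: %s",
                  disc$bdiff_threshold, sum(disc$records$sig_diff),
                  paste(names(table(disc$records$pattern)),
                        table(disc$records$pattern), collapse = ", ")))

clumps <- clump_scan(disc$records, disc$G)
if (!is.null(clumps)) {
  fwrite(clumps, "results/meqtl/discovery_clumps.tsv", sep = "\t")
  leads <- do.call(rbind, lapply(split(clumps, clumps$cpg), function(d) {
    recs <- disc$records
    lead <- recs[recs$cpg == d$cpg[1] & recs$snp %in% d$lead_snp, ]
    lead
  }))
  leads$sig_diff <- leads$sig_diff %in% TRUE
  message(nrow(clumps), " meQTL clumps; ", nrow(leads), " lead meQTLs")

  # replication restricted to CpGs replicated at the EWAS stage
  rep_flags <- fread("results/ewas/replication_la.tsv")
  rep_cpgs <- rep_flags$cpg[rep_flags$replicated]
  leads_rep <- leads[leads$cpg %in% rep_cpgs, ]
  if (nrow(leads_rep) > 0) {
    repl <- scan_group("replication", unique(leads_rep$cpg))
    out <- replicate_meqtl(leads_rep, repl$records)
    fwrite(out$flags, "results/meqtl/replication_leads.tsv", sep = "\t")
    message(sprintf(
      "lead meQTL replication: %d/%d (%.0f%%) at p < %.3g (ancestry vs null)",
      out$summary$n_replicated, out$summary$n_leads,
      out$summary$pct_replicated, out$summary$threshold_anc))
  } else {
    message("no lead meQTL lies on an EWAS-replicated CpG; replication skipped")
  }
}
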