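#!/usr/bin/env Rscript
# Variant QC and ancestry-feature construction for both cohorts: filter
# SNPs (MAF >= 1%, call rate >= 95%, exact HWE p >= 1e-6), then compute
# the distance-weighted local African proportion at every CpG (1 Mb
# window) and each individual's global ancestry as the genome-wide
# average of per-SNP local ancestry.

suppressMessages({library(admixmeth); library(data.table)})

for (grp in c("discovery", "replication")) {
  dir <- file.path("results", "data", grp)
  vcf <- read_phased_vcf(file.path(dir, "genotypes.vcf"))
  msp <- read_msp(file.path(dir, "local_ancestry.msp.tsv"))
  cpgs <- as.data.frame(fread(file.path(dir, "cpg_manifest.tsv")))

  dosage <- vcf$alleles[, 1, ] + vcf$alleles[, 2, ]
  colnames(dosage) <- vcf$snps$snp_id
  qc <- filter_variants(dosage, alleles = vcf$snps)
  fwrite(qc$report, file.path(dir, "variant_qc.tsv"), sep = "\t")

  afr <- msp$ancestry[, 1, ] + msp$ancestry[, 2, ]
  rownames(afr) <- msp$individuals
  la <- la_matrix(afr[, qc$keep, drop = FALSE], vcf$snps[qc$keep, ],
                  cpgs, window_bp = 1e6)
  ga <- global_from_local(afr, scale = 2)
  write_matrix_tsv(t(la), file.path(dir, "local_ancestry_cpg.tsv"), "cpg_id")
  fwrite(data.frame(id = msp$individuals, global_afr = ga),
         file.path(dir, "global_ancestry.tsv"), sep = "\t")

  truth <- read_truth_json(file.path(dir, "truth.json"))
  message(sprintf(
    "%s: %d/%d SNPs pass QC; GA vs true theta r = %.3f; LA defined at %d/%d CpGs",
    grp, sum(qc$keep), ncol(dosage), cor(ga, truth$theta),
    sum(colSums(!is.na(la)) > 0), ncol(la)))
}
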