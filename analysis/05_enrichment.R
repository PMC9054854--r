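#!/usr/bin/env Rscript
# Positional enrichment of the LA-associated CpGs over the 11 genomic
# annotation categories (gene features and CpG-island neighbourhood),
# hypergeometric tests with BH FDR; plus a trait-overlap enrichment
# against a synthetic trait catalog built from the simulation itself
# (traits sharing causal CpGs), Fisher tests with a count-derived
# Bonferroni cutoff.

suppressMessages({library(admixmeth); library(data.table)})

cpgs <- as.data.frame(fread("results/data/discovery/cpg_manifest.tsv"))
ewas_la <- fread("results/ewas/discovery_la.tsv")
sig <- ewas_la$cpg[ewas_la$significant]
stopifnot(length(sig) > 0)

ann_cols <- setdiff(names(cpgs), c("cpg_id", "chrom", "pos"))
enr <- annotation_enrichment(sig, cpgs$cpg_id, cpgs[, c("cpg_id", ann_cols)])
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
fwrite(enr, "results/enrichment/annotations.tsv", sep = "\t")
message("annotation enrichment (fold change, FDR):")
for (i in seq_len(nrow(enr)))
  message(sprintf("  %-10s FC = %.2f  p = %.3g  FDR = %.3g%s",
                  enr$annotation[i], enr$fold_change[i], enr$p[i],
                  enr$fdr[i], ifelse(enr$significant[i], "  *", "")))

# synthetic trait catalog: one trait seeded from the causal CpG set plus
# random filler, three traits of random probes (labelled synthetic; a
# stand-in for a curated EWAS catalog, which needs external data)
truth <- read_truth_json("results/data/discovery/truth.json")
set.seed(99)
catalog <- rbind(
  data.frame(trait = "synthetic_ancestry",
             cpg_id = c(truth$effect_spec$cpg,
                        sample(cpgs$cpg_id, 10))),
  do.call(rbind, lapply(1:3, function(k)
    data.frame(trait = paste0("synthetic_random_", k),
               cpg_id = sample(cpgs$cpg_id, 25)))))
tr <- trait_enrichment(sig, catalog, cpgs$cpg_id)
fwrite(tr, "results/enrichment/traits.tsv", sep = "\t")
message(sprintf("trait enrichment: %d traits overlap; cutoff %.3g",
                nrow(tr), unique(tr$bonferroni_threshold)))
for (i in seq_len(nrow(tr)))
  message(sprintf("  %-20s overlap = %d  OR = %.2f  p = %.3g%s",
                  tr$trait[i], tr$n_overlap[i], tr$odds_ratio[i], tr$p[i],
                  ifelse(tr$significant[i], "  *", "")))
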