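#!/usr/bin/env Rscript
# Simulate a two-way admixed discovery cohort and an independent
# replication cohort at the sample sizes of the study design they mirror
# (527 discovery samples of which ~9% self-report European-American; 467
# replication samples). The two cohorts share the same SNP/CpG map and the
# same causal effects -- only the individuals differ -- so the replication
# stage is meaningful. Writes all cohort files under results/data/.

suppressMessages(library(admixmeth))

cfg_for <- function(n, seed) {
  sim_config(n_individuals = n, frac_ea = 49 / 527,
             chromosomes = data.frame(chrom = paste0("chr", 1:2),
                                      morgans = 1.5, bp = 3e7),
             n_snps_per_chrom = 500, n_cpgs = 150, n_control_probes = 40,
             seed = seed)
}

cfg_disc <- cfg_for(527, 101)
positions <- simulate_positions(cfg_disc)          # shared map
effects <- default_effect_spec(positions$cpgs, positions$snps, cfg_disc)

for (grp in list(list(name = "discovery", cfg = cfg_disc),
                 list(name = "replication", cfg = cfg_for(467, 202)))) {
  cfg <- grp$cfg
  panel <- simulate_genotypes(simulate_tracts(cfg, positions), cfg)
  covariates <- simulate_covariates(panel, cfg)
  meth <- simulate_methylation(panel, covariates, cfg, effect_spec = effects)
  cohort <- structure(list(panel = panel, covariates = covariates,
                           methylation = meth$methylation,
                           control = meth$control, batch = meth$batch,
                           truth = meth$truth, config = cfg),
                      class = "admix_cohort")
  dir <- file.path("results", "data", grp$name)
  write_cohort(cohort, dir)
  message(sprintf("%s: %d individuals, %d SNPs, %d CpGs (%d causal) -> %s",
                  grp$name, cfg$n_individuals, nrow(panel$snps),
                  nrow(panel$cpgs), nrow(effects), dir))
}
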