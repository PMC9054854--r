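# Small cohort configurations shared across test files. All fixtures are
# generated in code; nothing is read from disk.

small_config <- function(seed = 11, n_cpgs = 12, ...) {
  sim_config(n_individuals = 80,
             chromosomes = data.frame(chrom = "chr1", morgans = 1, bp = 2e7),
             n_snps_per_chrom = 120, n_cpgs = n_cpgs, n_control_probes = 15,
             seed = seed, ...)
}

# covariate design used throughout: intercept + the simulated covariates
covariate_design <- function(covariates) {
  cols <- c("age", "smoker", "log10_peth", "adherence", "log10_vl",
            "wbc", "cd4", "cd8", "gran", "nk", "bcell", "mono")
  cbind(intercept = 1, as.matrix(covariates[, cols]))
}

# simulate one CpG-SNP pair from the ancestry meQTL model with simple
# covariates; returns everything the three-model fit needs
simulate_pair <- function(n = 400, b_la = 0, b_afr = 0, b_eur = 0,
                          sigma = 1, f_afr = 0.5, f_eur = 0.5,
                          theta_a = 8, theta_b = 2) {
  theta <- rbeta(n, theta_a, theta_b)
  anc1 <- rbinom(n, 1, theta); anc2 <- rbinom(n, 1, theta)
  h1 <- rbinom(n, 1, ifelse(anc1 == 1, f_afr, f_eur))
  h2 <- rbinom(n, 1, ifelse(anc2 == 1, f_afr, f_eur))
  snp_afr <- h1 * (anc1 == 1) + h2 * (anc2 == 1)
  snp_eur <- h1 * (anc1 == 0) + h2 * (anc2 == 0)
  la <- (anc1 + anc2) / 2
  age <- rnorm(n, 50, 7)
  X <- cbind(intercept = 1, age = age, la = la)
  y <- 0.01 * age + b_la * la + b_afr * snp_afr + b_eur * snp_eur +
    rnorm(n, 0, sigma)
  list(y = y, X = X, dosage = snp_afr + snp_eur,
       snp_afr = snp_afr, snp_eur = snp_eur, la = la)
}
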