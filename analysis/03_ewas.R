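#!/usr/bin/env Rscript
# Two-stage EWAS of self-reported race (all samples), global ancestry and
# local ancestry (admixed samples only, LA additionally adjusted for GA),
# in the discovery cohort; then replication of each hit set in the
# independent cohort using count-derived Bonferroni thresholds with the
# concordant-direction rule. The discovery cutoff is Bonferroni at the
# number of simulated CpGs (the desk-scale analogue of an epigenome-wide
# cutoff).

suppressMessages({library(admixmeth); library(data.table)})

cov_cols <- c("age", "smoker", "log10_peth", "adherence", "log10_vl",
              "wbc", "cd4", "cd8", "gran", "nk", "bcell", "mono")

load_group <- function(grp) {
  dir <- file.path("results", "data", grp)
  list(dir = dir,
       M = read_matrix_tsv(file.path(dir, "methylation.tsv")),
       ctrl = read_matrix_tsv(file.path(dir, "control_probes.tsv")),
       covs = as.data.frame(fread(file.path(dir, "covariates.tsv"))),
       la = t(read_matrix_tsv(file.path(dir, "local_ancestry_cpg.tsv"))),
       ga = fread(file.path(dir, "global_ancestry.tsv"))$global_afr,
       cpgs = as.data.frame(fread(file.path(dir, "cpg_manifest.tsv"))))
}

run_three <- function(g, alpha) {
  cpcs <- control_probe_pcs(g$ctrl, k = min(30, nrow(g$ctrl) - 1))
  X_of <- function(rows, extra = NULL)
    cbind(intercept = 1, as.matrix(g$covs[rows, cov_cols]),
          cpcs[rows, , drop = FALSE], extra)
  aa <- g$covs$race == 1
  scans <- list()
  for (v in c("race", "ga", "la")) {
    rows <- if (v == "race") rep(TRUE, nrow(g$covs)) else aa
    anc <- switch(v, race = g$covs$race[rows], ga = g$ga[rows],
                  la = g$la[rows, , drop = FALSE])
    extra <- if (v == "la") cbind(ga = g$ga[rows]) else NULL
    X0 <- X_of(rows, extra)
    rpcs <- stage1_residual_pcs(g$M[, rows, drop = FALSE], X0, k = 5)
    scans[[v]] <- run_ewas(g$M[, rows, drop = FALSE], anc,
                           cbind(X0, rpcs), alpha = alpha)
  }
  scans
}

disc <- load_group("discovery")
repl <- load_group("replication")
alpha <- bonferroni_threshold(0.05, nrow(disc$M))
disc_scans <- run_three(disc, alpha)
repl_scans <- run_three(repl, alpha)

dir.create("results/ewas", showWarnings = FALSE, recursive = TRUE)
for (v in names(disc_scans)) {
  d <- disc_scans[[v]]
  fwrite(cbind(as.data.frame(d), chrom = disc$cpgs$chrom,
               pos = disc$cpgs$pos),
         sprintf("results/ewas/discovery_%s.tsv", v), sep = "\t")
  message(sprintf("discovery %-4s: %3d significant CpGs (lambda = %.2f)",
                  v, sum(d$significant), attr(d, "lambda")))
  if (any(d$significant)) {
    rp <- replicate_ewas(d, repl_scans[[v]])
    fwrite(rp$flags, sprintf("results/ewas/replication_%s.tsv", v),
           sep = "\t")
    message(sprintf(
      "  replication: %d/%d (%.0f%%) at p < %.3g with concordant sign",
      rp$summary$n_replicated, rp$summary$n_discovery,
      rp$summary$pct_replicated, rp$summary$threshold))
  }
}
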