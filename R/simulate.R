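#' Simulation configuration for a two-way admixed cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()] and the
#' stage-level generators. The defaults describe a cohort resembling an
#' African-American study population: individual global African proportions
#' \eqn{\theta_i \sim Beta(2, 0.5)} (mean 0.8, effective range roughly
#' 0.15 to 1, matching the wide admixture spread of self-identified
#' African-American cohorts), 7 generations since admixture,
#' a uniform genetic map, and covariates (age, smoking, viral load,
#' adherence, alcohol biomarker, white-blood-cell count, six cell-type
#' proportions) drawn to match typical values in HIV cohort samples.
#'
#' @param n_individuals number of diploid individuals.
#' @param chromosomes data.frame with columns `chrom`, `morgans` (genetic
#'   length), `bp` (physical length). Default: one 2-Morgan, 200-Mb
#'   chromosome.
#' @param n_snps_per_chrom SNPs simulated per chromosome.
#' @param g generations since admixture (tract breakpoints arise as a
#'   Poisson process of rate `g` per Morgan).
#' @param theta_alpha,theta_beta Beta parameters for the global African
#'   proportion of admixed (AA) individuals.
#' @param frac_ea fraction of individuals labelled European-American; their
#'   \eqn{\theta_i} is drawn from `Beta(theta_alpha_ea, theta_beta_ea)`.
#' @param theta_alpha_ea,theta_beta_ea Beta parameters for EA individuals.
#' @param freq_pairs optional data.frame with columns `f_afr`, `f_eur`
#'   (one row per SNP, values in (0,1)); when `NULL`, ancestral allele
#'   frequencies are drawn from a Balding–Nichols model with `fst`.
#' @param fst divergence used when drawing ancestral frequencies.
#' @param n_cpgs number of CpG probes.
#' @param effect_spec optional data.frame describing causal CpGs (columns
#'   `cpg`, `b_la`, `b_afr`, `b_eur`, optional `snp`); when `NULL`,
#'   [default_effect_spec()] assigns effects mirroring the canonical
#'   ancestry-specific patterns to `causal_frac` of the CpGs.
#' @param causal_frac fraction of CpGs made causal by the default spec.
#' @param sigma_eps residual (noise) standard deviation of methylation
#'   M-values.
#' @param covariate_effects named numeric vector of covariate effects on
#'   every CpG's M-value (names must be covariate columns).
#' @param n_control_probes number of array control probes.
#' @param n_batches number of processing batches.
#' @param batch_effect_sd SD of per-probe batch shifts on control probes.
#' @param meth_batch_sd SD of per-CpG batch loadings on methylation (shared
#'   batch structure between control probes and methylation, which is what
#'   the control-probe principal components are meant to absorb).
#' @param la_window_bp total flanking span used to anchor causal SNPs and
#'   define local ancestry at a CpG (1 Mb, i.e. +/- 500 kb).
#' @param confound_theta_age if nonzero, adds `confound_theta_age *
#'   (theta_i - mean(theta))` to age, creating ancestry–covariate
#'   confounding for adjustment tests.
#' @param genetic_map optional named list (by chromosome) of data.frames
#'   with columns `bp`, `morgans`; interpolated to place SNPs on the
#'   genetic map. `NULL` means a uniform map.
#' @param seed integer seed; all generator randomness fans out from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 478,
                       chromosomes = data.frame(chrom = "chr1",
                                                morgans = 2,
                                                bp = 2e8),
                       n_snps_per_chrom = 1000,
                       g = 7,
                       theta_alpha = 2, theta_beta = 0.5,
                       frac_ea = 0,
                       theta_alpha_ea = 1, theta_beta_ea = 30,
                       freq_pairs = NULL,
                       fst = 0.15,
                       n_cpgs = 200,
                       effect_spec = NULL,
                       causal_frac = 0.1,
                       sigma_eps = 1,
                       covariate_effects = c(age = 0.01, smoker = 0.2),
                       n_control_probes = 40,
                       n_batches = 2,
                       batch_effect_sd = 1,
                       meth_batch_sd = 0.2,
                       la_window_bp = 1e6,
                       confound_theta_age = 0,
                       genetic_map = NULL,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps_per_chrom >= 1, n_cpgs >= 1)
  if (any(chromosomes$morgans <= 0) || any(chromosomes$bp <= 0))
    stop("chromosome genetic and physical lengths must be positive")
  if (g <= 0) stop("generations since admixture 'g' must be positive")
  if (theta_alpha <= 0 || theta_beta <= 0)
    stop("Beta parameters for theta must be positive")
  if (sigma_eps < 0) stop("sigma_eps must be >= 0")
  if (!is.null(freq_pairs)) {
    if (any(freq_pairs$f_afr <= 0 | freq_pairs$f_afr >= 1 |
            freq_pairs$f_eur <= 0 | freq_pairs$f_eur >= 1))
      stop("ancestral allele frequencies must lie strictly in (0, 1)")
  }
  cfg <- list(n_individuals = as.integer(n_individuals),
              chromosomes = chromosomes,
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              g = g,
              theta_alpha = theta_alpha, theta_beta = theta_beta,
              frac_ea = frac_ea,
              theta_alpha_ea = theta_alpha_ea,
              theta_beta_ea = theta_beta_ea,
              freq_pairs = freq_pairs, fst = fst,
              n_cpgs = as.integer(n_cpgs),
              effect_spec = effect_spec, causal_frac = causal_frac,
              sigma_eps = sigma_eps,
              covariate_effects = covariate_effects,
              n_control_probes = as.integer(n_control_probes),
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              meth_batch_sd = meth_batch_sd,
              la_window_bp = la_window_bp,
              confound_theta_age = confound_theta_age,
              genetic_map = genetic_map,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# One global seed fans out to fixed per-component substreams so any stage can
# be regenerated in isolation and stays stable when other stages change.
.substream <- function(seed, component) {
  offsets <- c(tracts = 11L, genotypes = 23L, covariates = 37L,
               methylation = 53L, control = 71L, positions = 89L)
  set.seed((seed * 101L + offsets[[component]]) %% .Machine$integer.max)
}

#' Simulate SNP and CpG positions for a configuration
#'
#' SNP positions are uniform along each chromosome; genetic positions come
#' from the uniform map (constant Morgan/bp) unless `config$genetic_map`
#' supplies one. CpGs are likewise placed uniformly and given boolean
#' genomic annotations at rates resembling a methylation array manifest.
#'
#' @param config a [sim_config()] object.
#' @return list with data.frames `snps` (snp_id, chrom, pos, morgans,
#'   f_afr, f_eur) and `cpgs` (cpg_id, chrom, pos, plus 11 annotation
#'   columns).
#' @export
simulate_positions <- function(config) {
  .substream(config$seed, "positions")
  snps <- do.call(rbind, lapply(seq_len(nrow(config$chromosomes)), function(i) {
    ch <- config$chromosomes[i, ]
    pos <- sort(sample.int(ch$bp, config$n_snps_per_chrom))
    data.frame(chrom = ch$chrom, pos = pos,
               morgans = .bp_to_morgans(pos, ch, config$genetic_map))
  }))
  snps$snp_id <- sprintf("rs%06d", seq_len(nrow(snps)))
  if (is.null(config$freq_pairs)) {
    # Balding-Nichols: shared ancestral frequency, Beta-distributed
    # population frequencies with divergence fst
    p <- runif(nrow(snps), 0.05, 0.95)
    a <- (1 - config$fst) / config$fst
    snps$f_afr <- pmin(pmax(rbeta(nrow(snps), p * a, (1 - p) * a), 0.01), 0.99)
    snps$f_eur <- pmin(pmax(rbeta(nrow(snps), p * a, (1 - p) * a), 0.01), 0.99)
  } else {
    stopifnot(nrow(config$freq_pairs) == nrow(snps))
    snps$f_afr <- config$freq_pairs$f_afr
    snps$f_eur <- config$freq_pairs$f_eur
  }
  n_cpg_per_chrom <- diff(round(seq(0, config$n_cpgs,
                                    length.out = nrow(config$chromosomes) + 1)))
  cpgs <- do.call(rbind, lapply(seq_len(nrow(config$chromosomes)), function(i) {
    ch <- config$chromosomes[i, ]
    if (n_cpg_per_chrom[i] == 0) return(NULL)
    data.frame(chrom = ch$chrom,
               pos = sort(sample.int(ch$bp, n_cpg_per_chrom[i])))
  }))
  cpgs$cpg_id <- sprintf("cg%08d", seq_len(nrow(cpgs)))
  ann_rates <- c("UTR3" = 0.05, Body = 0.35, FirstExon = 0.05, "UTR5" = 0.12,
                 TSS200 = 0.10, TSS1500 = 0.15, Island = 0.31, N_Shore = 0.13,
                 S_Shore = 0.10, N_Shelf = 0.05, S_Shelf = 0.04)
  for (a in names(ann_rates))
    cpgs[[a]] <- runif(nrow(cpgs)) < ann_rates[[a]]
  list(snps = snps[, c("snp_id", "chrom", "pos", "morgans", "f_afr", "f_eur")],
       cpgs = cpgs[, c("cpg_id", "chrom", "pos", names(ann_rates))])
}

.bp_to_morgans <- function(pos, chrom_row, genetic_map) {
  if (!is.null(genetic_map) && chrom_row$chrom %in% names(genetic_map)) {
    gm <- genetic_map[[chrom_row$chrom]]
    stats::approx(gm$bp, gm$morgans, xout = pos, rule = 2)$y
  } else {
    pos / chrom_row$bp * chrom_row$morgans
  }
}

#' Simulate admixture tracts and per-SNP haplotype ancestry
#'
#' Each individual draws a global African proportion \eqn{\theta_i}; along
#' each haplotype, tract breakpoints follow a Poisson process of rate `g`
#' per Morgan and each tract is African with probability \eqn{\theta_i},
#' independently (Pool–Nielsen-style model). Ancestry labels are recorded
#' at the simulated SNP positions.
#'
#' @param config a [sim_config()] object.
#' @param positions optional output of [simulate_positions()]; generated
#'   when missing.
#' @return a `haplotype_panel` list with elements `ancestry`
#'   (n x 2 x n_snps integer array; 1 = AFR, 0 = EUR), `snps`, `cpgs`,
#'   `theta` (true global African proportions), `race` (1 = AA, 0 = EA),
#'   and `individuals`.
#' @export
simulate_tracts <- function(config, positions = NULL) {
  if (is.null(positions)) positions <- simulate_positions(config)
  .substream(config$seed, "tracts")
  n <- config$n_individuals
  n_ea <- round(config$frac_ea * n)
  race <- c(rep(0L, n_ea), rep(1L, n - n_ea))
  theta <- numeric(n)
  theta[race == 1] <- rbeta(sum(race == 1), config$theta_alpha, config$theta_beta)
  theta[race == 0] <- rbeta(sum(race == 0), config$theta_alpha_ea,
                            config$theta_beta_ea)
  snps <- positions$snps
  m <- nrow(snps)
  anc <- array(0L, dim = c(n, 2, m))
  n_breakpoints <- matrix(0L, n, 2)   # summed over chromosomes
  for (ci in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes[ci, ]
    idx <- which(snps$chrom == ch$chrom)
    snp_m <- snps$morgans[idx]
    L <- ch$morgans
    for (i in seq_len(n)) {
      for (h in 1:2) {
        nb <- stats::rpois(1, config$g * L)
        bk <- sort(stats::runif(nb, 0, L))
        tract_anc <- stats::rbinom(nb + 1L, 1L, theta[i])
        anc[i, h, idx] <- tract_anc[findInterval(snp_m, bk) + 1L]
        n_breakpoints[i, h] <- n_breakpoints[i, h] + nb
      }
    }
  }
  structure(list(ancestry = anc, snps = snps, cpgs = positions$cpgs,
                 theta = theta, race = race,
                 n_breakpoints = n_breakpoints,
                 individuals = sprintf("id%04d", seq_len(n))),
            class = "haplotype_panel")
}

#' Simulate phased alleles given haplotype ancestry
#'
#' Each haplotype allele is Bernoulli with the allele frequency of its
#' local ancestral population: `f_afr` on African tracts, `f_eur` on
#' European tracts.
#'
#' @param panel output of [simulate_tracts()].
#' @param config the same [sim_config()].
#' @return the panel with an `alleles` element added (n x 2 x n_snps,
#'   values 0/1).
#' @export
simulate_genotypes <- function(panel, config) {
  stopifnot(inherits(panel, "haplotype_panel"))
  # closed [0,1]: the degenerate ends give deterministic alleles, which is
  # useful for exact checks; config-supplied frequencies are kept in (0,1)
  f_afr <- panel$snps$f_afr; f_eur <- panel$snps$f_eur
  if (any(f_afr < 0 | f_afr > 1 | f_eur < 0 | f_eur > 1))
    stop("allele frequencies must lie in [0, 1]")
  .substream(config$seed, "genotypes")
  d <- dim(panel$ancestry)
  pr <- array(rep(f_eur, each = d[1] * d[2]), dim = d)
  pr[panel$ancestry == 1L] <- array(rep(f_afr, each = d[1] * d[2]),
                                    dim = d)[panel$ancestry == 1L]
  panel$alleles <- array(stats::rbinom(length(pr), 1L, pr), dim = d)
  panel
}

#' Simulate the covariate table
#'
#' Age, smoking, alcohol biomarker (log10 PEth), adherence, viral load
#' (log10), white-blood-cell count and six cell-type proportions, plus the
#' self-reported race label carried by the panel. Cell proportions are a
#' 7-component Dirichlet draw (six named types plus remainder) so they are
#' nonnegative and sum to less than one.
#'
#' @param panel a `haplotype_panel` (provides `race` and `theta`).
#' @param config a [sim_config()].
#' @return data.frame with one row per individual.
#' @export
simulate_covariates <- function(panel, config) {
  .substream(config$seed, "covariates")
  n <- config$n_individuals
  cell_means <- c(cd4 = 0.05, cd8 = 0.18, gran = 0.52, nk = 0.08,
                  bcell = 0.09, mono = 0.12)
  cell_means <- cell_means / sum(cell_means) * 0.96
  alpha <- c(cell_means, rest = 0.04) * 60
  gm <- matrix(stats::rgamma(n * 7, shape = rep(alpha, each = n)), nrow = n)
  cells <- gm[, 1:6] / rowSums(gm)
  colnames(cells) <- names(cell_means)
  cov <- data.frame(
    id = panel$individuals,
    age = stats::rnorm(n, 49.4, 7.2) +
      config$confound_theta_age * (panel$theta - mean(panel$theta)),
    smoker = stats::rbinom(n, 1, 0.61),
    log10_peth = stats::rnorm(n, 1.6, 2.3),
    adherence = stats::rbinom(n, 1, 0.78),
    log10_vl = stats::rnorm(n, 2.7, 1.2),
    wbc = pmax(stats::rnorm(n, 5.2, 1.9), 0.5),
    cells,
    race = panel$race)
  cov
}

#' Default causal-effect specification
#'
#' Assigns `causal_frac` of the CpGs a local-ancestry effect and a cis-SNP
#' effect pattern cycling through the canonical ancestry-specific shapes:
#' comparable (0.5, 0.5), opposite (0.5, -0.5), African-only (0.5, 0),
#' European-only (0, 0.5), and same-direction different-magnitude
#' (0.3, 0.8). The local-ancestry effect defaults to 3 M-value units per
#' unit of African proportion (0.75 per 25% increase, the scale of strong
#' reported LA-methylation associations). The causal SNP for each CpG is
#' the nearest SNP within the local-ancestry window.
#'
#' @param cpgs,snps position tables from [simulate_positions()].
#' @param config a [sim_config()].
#' @return data.frame with columns `cpg`, `snp`, `b_la`, `b_afr`, `b_eur`.
#' @export
default_effect_spec <- function(cpgs, snps, config) {
  n_causal <- max(1L, round(config$causal_frac * nrow(cpgs)))
  idx <- round(seq(1, nrow(cpgs), length.out = n_causal))
  pats <- matrix(c(0.5, 0.5,   0.5, -0.5,   0.5, 0,   0, 0.5,   0.3, 0.8),
                 ncol = 2, byrow = TRUE)
  spec <- data.frame(cpg = cpgs$cpg_id[idx],
                     snp = NA_character_,
                     b_la = 3,
                     b_afr = pats[(seq_len(n_causal) - 1) %% 5 + 1, 1],
                     b_eur = pats[(seq_len(n_causal) - 1) %% 5 + 1, 2])
  half <- config$la_window_bp / 2
  for (j in seq_len(n_causal)) {
    cp <- cpgs[idx[j], ]
    cand <- which(snps$chrom == cp$chrom & abs(snps$pos - cp$pos) <= half)
    if (length(cand) == 0) stop("no SNP within the window of causal CpG ",
                                cp$cpg_id)
    spec$snp[j] <- snps$snp_id[cand[which.min(abs(snps$pos[cand] - cp$pos))]]
  }
  spec
}

#' Simulate methylation M-values and control probes
#'
#' Causal CpGs follow the ancestry meQTL model
#' \deqn{M = \sum_i b_i x_i + b_{LA} LA + b_{AFR} SNP_{AFR} +
#'       b_{EUR} SNP_{EUR} + \epsilon,}
#' where LA is the distance-weighted local African proportion at the CpG,
#' and SNP_AFR/SNP_EUR are the alternate-allele counts carried on African-
#' and European-origin haplotypes of the causal SNP. Non-causal CpGs get
#' covariate effects and noise only. All CpGs and the control probes share
#' a batch factor; control probes otherwise carry noise around a probe
#' baseline.
#'
#' @param panel a `haplotype_panel` with alleles.
#' @param covariates output of [simulate_covariates()].
#' @param config a [sim_config()].
#' @param effect_spec optional data.frame (`cpg`, `snp`, `b_la`, `b_afr`,
#'   `b_eur`); default from [default_effect_spec()].
#' @return list with `methylation` (CpG x sample matrix of M-values),
#'   `control` (probe x sample matrix), `batch` (per-sample batch index)
#'   and `truth` (the ground-truth registry used for recovery tests).
#' @export
simulate_methylation <- function(panel, covariates, config,
                                 effect_spec = config$effect_spec) {
  if (is.null(effect_spec))
    effect_spec <- default_effect_spec(panel$cpgs, panel$snps, config)
  half <- config$la_window_bp / 2
  # validate: each causal SNP inside its CpG's window
  for (j in seq_len(nrow(effect_spec))) {
    cp <- panel$cpgs[panel$cpgs$cpg_id == effect_spec$cpg[j], ]
    sn <- panel$snps[panel$snps$snp_id == effect_spec$snp[j], ]
    if (nrow(cp) == 0 || nrow(sn) == 0 ||
        cp$chrom != sn$chrom || abs(cp$pos - sn$pos) > half)
      stop("causal SNP ", effect_spec$snp[j],
           " falls outside the window of CpG ", effect_spec$cpg[j])
  }
  .substream(config$seed, "methylation")
  n <- config$n_individuals
  n_cpg <- nrow(panel$cpgs)
  ce <- config$covariate_effects
  eta_cov <- rep(0, n)
  for (nm in names(ce)) eta_cov <- eta_cov + ce[[nm]] * covariates[[nm]]
  intercepts <- stats::rnorm(n_cpg, 0, 1)
  M <- matrix(stats::rnorm(n_cpg * n, 0, config$sigma_eps),
              nrow = n_cpg, dimnames = list(panel$cpgs$cpg_id,
                                            panel$individuals))
  M <- M + intercepts + rep(eta_cov, each = n_cpg)
  afr_dos <- afr_dosage(panel)
  dec <- decompose_panel(panel)
  for (j in seq_len(nrow(effect_spec))) {
    ci <- match(effect_spec$cpg[j], panel$cpgs$cpg_id)
    si <- match(effect_spec$snp[j], panel$snps$snp_id)
    on_chrom <- panel$snps$chrom == panel$cpgs$chrom[ci]
    la <- la_at_cpg(afr_dos[, on_chrom, drop = FALSE],
                    panel$snps$pos[on_chrom], panel$cpgs$pos[ci],
                    window_bp = config$la_window_bp)
    M[ci, ] <- M[ci, ] + effect_spec$b_la[j] * la +
      effect_spec$b_afr[j] * dec$afr[, si] +
      effect_spec$b_eur[j] * dec$eur[, si]
  }
  .substream(config$seed, "control")
  batch <- rep(seq_len(config$n_batches), length.out = n)
  batch_factor <- stats::rnorm(config$n_batches, 0, 1)[batch]
  ctrl_load <- stats::rnorm(config$n_control_probes, 0, config$batch_effect_sd)
  ctrl <- outer(stats::rnorm(config$n_control_probes, 0, 1), rep(1, n)) +
    outer(ctrl_load, batch_factor) +
    matrix(stats::rnorm(config$n_control_probes * n, 0, 0.5),
           nrow = config$n_control_probes)
  dimnames(ctrl) <- list(sprintf("ctrl%03d", seq_len(config$n_control_probes)),
                         panel$individuals)
  meth_load <- stats::rnorm(n_cpg, 0, config$meth_batch_sd)
  M <- M + outer(meth_load, batch_factor)
  truth <- list(effect_spec = effect_spec,
                covariate_effects = as.list(ce),
                sigma_eps = config$sigma_eps,
                theta = panel$theta,
                intercepts = intercepts,
                seed = config$seed)
  list(methylation = M, control = ctrl, batch = batch, truth = truth)
}

#' Simulate a complete admixed cohort
#'
#' Runs the full generator: positions, ancestry tracts, phased alleles,
#' covariates, methylation and control probes.
#'
#' @param config a [sim_config()] object.
#' @return an `admix_cohort` list: `panel`, `covariates`, `methylation`,
#'   `control`, `batch`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_genotypes(simulate_tracts(config), config)
  covariates <- simulate_covariates(panel, config)
  meth <- simulate_methylation(panel, covariates, config)
  structure(list(panel = panel, covariates = covariates,
                 methylation = meth$methylation, control = meth$control,
                 batch = meth$batch, truth = meth$truth, config = config),
            class = "admix_cohort")
}

#' African-allele dosage of local ancestry per SNP
#'
#' Counts African-origin haplotypes per individual and SNP (0, 1 or 2) —
#' the raw material for the CpG-anchored local-ancestry summary.
#'
#' @param panel a `haplotype_panel`.
#' @return n x n_snps integer matrix.
#' @export
afr_dosage <- function(panel) {
  panel$ancestry[, 1, ] + panel$ancestry[, 2, ]
}
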