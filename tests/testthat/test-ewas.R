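test_that("control-probe PCs match a dense eigendecomposition and are orthogonal", {
  set.seed(3)
  ctrl <- matrix(rnorm(5 * 8), 5, 8,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  scores <- control_probe_pcs(ctrl, k = 4)
  # variance of scores equals the covariance eigenvalues (samples as obs)
  ev <- eigen(stats::cov(t(ctrl)), symmetric = TRUE)$values[1:4]
  expect_equal(apply(scores, 2, function(s) sum(s^2)) / (8 - 1), ev,
               tolerance = 1e-10, ignore_attr = TRUE)
  g <- crossprod(scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # rank-1 matrix: PC1 carries all the variance and k truncates
  r1 <- outer(1:5, rnorm(8))
  expect_warning(s1 <- control_probe_pcs(r1, k = 4), "rank")
  expect_equal(ncol(s1), 1L)
  # deterministic sign convention
  expect_identical(control_probe_pcs(ctrl, k = 4),
                   control_probe_pcs(ctrl, k = 4))
})

test_that("stage-one residual PCs come from genuine least-squares residuals", {
  set.seed(9)
  n <- 20; p <- 4
  X <- cbind(intercept = 1, matrix(rnorm(n * (p - 1)), n,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  M <- matrix(rnorm(30 * n), 30, n)
  # explicit hat-matrix oracle
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R_oracle <- M - M %*% t(H)
  Q <- qr.Q(qr(X))
  R_impl <- M - (M %*% Q) %*% t(Q)
  expect_equal(R_impl, R_oracle, tolerance = 1e-10)
  scores <- stage1_residual_pcs(M, X, k = 3)
  # residuals behind the PCs are orthogonal to every covariate column
  expect_lt(max(abs(crossprod(R_impl %*% X))), 1e-14 * n * 30 * 100)
  expect_lt(max(abs(cor(t(R_oracle), X[, -1]))), 1e-8)
  expect_equal(dim(scores), c(n, 3L))
  # collinear design is reported with the offending column
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(stage1_residual_pcs(M, Xbad, k = 2), "dup|collinear")
  # noiseless covariate-only methylation: degenerate residuals flagged
  M0 <- matrix(rnorm(6 * p), 6, p) %*% t(X)
  expect_warning(s0 <- stage1_residual_pcs(M0, X, k = 2), "degenerate")
  expect_true(attr(s0, "degenerate"))
})

test_that("the association scan recovers a noiseless LA effect exactly", {
  cfg <- small_config(seed = 19, sigma_eps = 0, meth_batch_sd = 0,
                      covariate_effects = c(age = 0.01, smoker = 0.2))
  panel <- simulate_genotypes(simulate_tracts(cfg), cfg)
  covs <- simulate_covariates(panel, cfg)
  spec <- default_effect_spec(panel$cpgs, panel$snps, cfg)
  spec$b_la <- 0.8; spec$b_afr <- 0; spec$b_eur <- 0
  meth <- simulate_methylation(panel, covs, cfg, effect_spec = spec)
  la <- la_matrix(afr_dosage(panel), panel$snps, panel$cpgs)
  X <- cbind(intercept = 1, age = covs$age, smoker = covs$smoker)
  res <- run_ewas(meth$methylation, la, X, alpha = 0.05)
  causal <- res$cpg %in% spec$cpg
  expect_equal(res$estimate[causal], rep(0.8, sum(causal)), tolerance = 1e-8)
  # effects reported per 25% increase in local African ancestry
  expect_equal(res$estimate[causal] * 0.25, rep(0.2, sum(causal)),
               tolerance = 1e-8)
  expect_equal(res$estimate[!causal], rep(0, sum(!causal)), tolerance = 1e-6)
})

test_that("per-CpG OLS matches the explicit normal-equations solution", {
  set.seed(23)
  n <- 6
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
  anc <- rnorm(n)
  y <- rnorm(n)
  res <- run_ewas(matrix(y, 1, dimnames = list("cg1", NULL)), anc, X,
                  alpha = 0.05)
  fit <- lm(y ~ anc + X - 1)
  sm <- summary(fit)$coefficients
  expect_equal(res$estimate, unname(sm["anc", "Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(sm["anc", "Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p, unname(sm["anc", "Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("null scans are calibrated and estimates unbiased", {
  set.seed(101)
  n <- 60; n_cpg <- 2000
  X <- cbind(intercept = 1, age = rnorm(n))
  anc <- runif(n)
  M <- matrix(rnorm(n_cpg * n), n_cpg, n,
              dimnames = list(paste0("cg", 1:n_cpg), NULL))
  res <- run_ewas(M, anc, X, alpha = 1.16e-7)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_cpg))
  expect_lt(abs(attr(res, "lambda") - 1), 0.1)
  # unbiasedness with a common true effect across 500 CpGs
  n2 <- 200
  anc2 <- runif(n2)
  X2 <- matrix(1, n2, 1, dimnames = list(NULL, "intercept"))
  M2 <- matrix(rnorm(500 * n2), 500, n2,
               dimnames = list(paste0("cg", 1:500), NULL)) +
    rep(0.8 * anc2, each = 500)
  res2 <- run_ewas(M2, anc2, X2, alpha = 1.16e-7)
  bias <- mean(res2$estimate) - 0.8
  expect_lt(abs(bias), 2 * sd(res2$estimate) / sqrt(500))
})

test_that("scan output is invariant to sample and covariate order", {
  cfg <- small_config(seed = 29)
  co <- simulate_cohort(cfg)
  la <- la_matrix(afr_dosage(co$panel), co$panel$snps, co$panel$cpgs)
  X <- covariate_design(co$covariates)
  res <- run_ewas(co$methylation, la, X, alpha = 0.05)
  perm <- sample(ncol(co$methylation))
  res_p <- run_ewas(co$methylation[, perm], la[perm, ], X[perm, ],
                    alpha = 0.05)
  expect_equal(res_p$estimate, res$estimate, tolerance = 1e-9)
  expect_equal(res_p$p, res$p, tolerance = 1e-9)
  cperm <- c(1, sample(2:ncol(X)))
  res_c <- run_ewas(co$methylation, la, X[, cperm], alpha = 0.05)
  expect_equal(res_c$estimate, res$estimate, tolerance = 1e-9)
})

test_that("genomic inflation matches its defining formula", {
  # exact uniform quantiles and a constant 0.5 both give lambda = 1
  expect_equal(genomic_inflation((1:999) / 1000), 1, tolerance = 1e-12)
  expect_equal(genomic_inflation(rep(0.5, 7)), 1, tolerance = 1e-12)
  p11 <- c(0.9, 0.52, 0.3, 0.21, 0.17, 0.11, 0.08, 0.05, 0.02, 0.004, 1e-6)
  oracle <- median(qchisq(1 - p11, df = 1)) / qchisq(0.5, df = 1)
  expect_equal(genomic_inflation(p11), oracle, tolerance = 1e-12)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("Bonferroni thresholds reproduce the printed study cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 708), 3), 7.06e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 30), 3), 1.67e-3)
  expect_equal(bonferroni_threshold(0.3, 1), 0.3)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("replication requires the corrected p-value and a concordant sign", {
  disc <- data.frame(cpg = paste0("cg", 1:5),
                     estimate = c(1, -1, 2, 0.5, 1),
                     p = rep(1e-10, 5), significant = TRUE)
  # identical tables: everything replicates
  self <- replicate_ewas(disc, disc)
  expect_equal(self$summary$pct_replicated, 100)
  # flip one sign, push one p above threshold, drop one CpG entirely
  rep_tab <- disc
  rep_tab$estimate[2] <- 1
  rep_tab$p[3] <- 0.04
  rep_tab <- rep_tab[rep_tab$cpg != "cg5", ]
  out <- replicate_ewas(disc, rep_tab)
  expect_equal(out$summary$threshold, 0.05 / 5)
  flags <- out$flags
  expect_false(flags$replicated[flags$cpg == "cg2"])   # sign flip
  expect_false(flags$replicated[flags$cpg == "cg3"])   # p too large
  expect_false(flags$testable[flags$cpg == "cg5"])     # absent from array
  expect_equal(out$summary$n_replicated, 2)
  expect_equal(out$summary$pct_replicated, 40)         # untestable kept in denom
  expect_equal(replicate_ewas(disc, rep_tab,
                              drop_untestable = TRUE)$summary$pct_replicated,
               50)
})

test_that("residual PCs do not inflate ancestry test statistics", {
  # confounded construction: a latent factor correlated with ancestry loads
  # on every CpG; the two-stage scan should not be more inflated than the
  # single-stage scan
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 120; n_cpg <- 300
    ga <- rbeta(n, 2, 0.5)
    latent <- ga + rnorm(n, 0, 0.3)
    load <- rnorm(n_cpg, 0, 0.6)
    X <- cbind(intercept = 1, age = rnorm(n))
    M <- matrix(rnorm(n_cpg * n), n_cpg, n,
                dimnames = list(paste0("cg", 1:n_cpg), NULL)) +
      outer(load, latent)
    single <- run_ewas(M, ga, X, alpha = 1e-7)
    rpcs <- stage1_residual_pcs(M, X, k = 5)
    two_stage <- run_ewas(M, ga, cbind(X, rpcs), alpha = 1e-7)
    expect_lte(attr(two_stage, "lambda"), attr(single, "lambda") + 0.02)
  }
})
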