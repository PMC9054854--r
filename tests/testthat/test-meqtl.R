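test_that("the two ancestry-model parameterizations are algebraically identical", {
  set.seed(14)
  for (rep in 1:5) {
    pr <- simulate_pair(n = 120, b_afr = runif(1, -1, 1),
                        b_eur = runif(1, -1, 1), b_la = 0.5)
    fit <- fit_three_models(pr$y, pr$X, pr$dosage, pr$snp_afr, pr$snp_eur)
    # reparameterized design: total dosage + half-difference
    halfdiff <- (pr$snp_afr - pr$snp_eur) / 2
    lm2 <- lm(pr$y ~ pr$X + pr$dosage + halfdiff - 1)
    expect_equal(sum(residuals(lm2)^2), fit$ancestry$rss, tolerance = 1e-10)
    expect_equal(unname(fitted(lm2)),
                 unname(pr$y - (pr$y - as.vector(
                   cbind(pr$X, pr$snp_afr, pr$snp_eur) %*%
                     c(fit$ancestry$coef)))), tolerance = 1e-8)
    co <- coef(lm2)
    expect_equal(unname(co["pr$dosage"]), fit$b_average, tolerance = 1e-8)
    expect_equal(unname(co["halfdiff"]), fit$b_diff, tolerance = 1e-8)
    expect_equal(fit$b_average, (fit$b_afr + fit$b_eur) / 2,
                 tolerance = 1e-12)
    expect_equal(fit$b_diff, fit$b_afr - fit$b_eur, tolerance = 1e-12)
  }
})

test_that("an eight-sample worked example matches the normal equations", {
  y <- c(1.2, -0.4, 0.8, 2.1, -1.0, 0.3, 1.7, 0.2)
  X <- cbind(intercept = 1,
             age = c(41, 52, 47, 60, 39, 55, 44, 50),
             la = c(1, 0.5, 1, 0.5, 0, 0.5, 1, 0))
  snp_afr <- c(2, 1, 0, 1, 0, 0, 2, 0)
  snp_eur <- c(0, 0, 1, 1, 1, 0, 0, 2)
  fit <- fit_three_models(y, X, snp_afr + snp_eur, snp_afr, snp_eur)
  lmo <- lm(y ~ X + snp_afr + snp_eur - 1)
  expect_equal(fit$b_afr, unname(coef(lmo)["snp_afr"]), tolerance = 1e-10)
  expect_equal(fit$b_eur, unname(coef(lmo)["snp_eur"]), tolerance = 1e-10)
  sm <- summary(lmo)$coefficients
  expect_equal(fit$p_afr, unname(sm["snp_afr", 4]), tolerance = 1e-10)
  lmc <- lm(y ~ X + I(snp_afr + snp_eur) - 1)
  expect_equal(fit$b_snp, unname(coef(lmc)[4]), tolerance = 1e-10)
})

test_that("noiseless decomposed effects are recovered exactly", {
  set.seed(31)
  pr <- simulate_pair(n = 200, b_afr = 0.5, b_eur = -0.5, b_la = 0.8,
                      sigma = 0)
  fit <- fit_three_models(pr$y, pr$X, pr$dosage, pr$snp_afr, pr$snp_eur)
  expect_equal(fit$b_afr, 0.5, tolerance = 1e-8)
  expect_equal(fit$b_eur, -0.5, tolerance = 1e-8)
  # equal true effects: conventional model estimates the shared slope and
  # the ancestry model cannot beat it by more than noise (here, none)
  pr2 <- simulate_pair(n = 200, b_afr = 0.7, b_eur = 0.7, sigma = 0)
  fit2 <- fit_three_models(pr2$y, pr2$X, pr2$dosage, pr2$snp_afr, pr2$snp_eur)
  expect_equal(fit2$b_snp, 0.7, tolerance = 1e-8)
  expect_equal(fit2$conventional$rss, fit2$ancestry$rss, tolerance = 1e-8)
})

test_that("nested F tests agree with anova() and the t-squared identity", {
  set.seed(7)
  pr <- simulate_pair(n = 60, b_afr = 0.4, b_eur = 0.1)
  fit <- fit_three_models(pr$y, pr$X, pr$dosage, pr$snp_afr, pr$snp_eur)
  l0 <- lm(pr$y ~ pr$X - 1)
  l1 <- lm(pr$y ~ pr$X + pr$dosage - 1)
  halfdiff <- (pr$snp_afr - pr$snp_eur) / 2
  l2 <- lm(pr$y ~ pr$X + pr$dosage + halfdiff - 1)
  expect_equal(fit$p_conv, anova(l0, l1)$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(fit$p_anc, anova(l0, l2)$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(fit$p_diff, anova(l1, l2)$`Pr(>F)`[2], tolerance = 1e-10)
  # F(1, nu) = t^2: the difference test equals the b_diff coefficient test
  expect_equal(fit$p_diff,
               summary(l2)$coefficients["halfdiff", "Pr(>|t|)"],
               tolerance = 1e-10)
  # identical fits: F = 0, p = 1
  same <- nested_f_test(list(rss = 10, df = 5), list(rss = 10, df = 4))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(nested_f_test(list(rss = 10, df = 4), list(rss = 10, df = 5)),
               "not nested")
  expect_error(nested_f_test(list(rss = 1, df = 5), list(rss = 9, df = 4)),
               "not nested")
})

test_that("a SNP never observed on one ancestry is flagged inestimable", {
  set.seed(3)
  n <- 80
  la <- runif(n)
  X <- cbind(intercept = 1, la = la)
  snp_afr <- rbinom(n, 2, 0.3)
  snp_eur <- rep(0, n)
  y <- rnorm(n) + 0.3 * snp_afr
  fit <- fit_three_models(y, X, snp_afr, snp_afr, snp_eur)
  expect_true(fit$inestimable)
  expect_true(is.na(fit$b_afr))
  expect_false(is.na(fit$b_snp))        # conventional model still fits
  expect_false(is.na(fit$p_conv))
})

test_that("the difference test grows more powerful with the true difference", {
  set.seed(55)
  diffs <- c(0, 0.4, 0.8)
  rates <- vapply(diffs, function(d) {
    rej <- replicate(150, {
      pr <- simulate_pair(n = 150, b_afr = 0.3 + d / 2, b_eur = 0.3 - d / 2)
      fit <- fit_three_models(pr$y, pr$X, pr$dosage, pr$snp_afr, pr$snp_eur)
      !is.na(fit$p_diff) && fit$p_diff < 0.05
    })
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.12)
  expect_gt(rates[3], rates[1])
})

test_that("the cis scan enumerates windowed pairs and derives thresholds", {
  set.seed(61)
  n <- 100
  snps <- data.frame(snp_id = paste0("s", 1:6), chrom = "chr1",
                     pos = c(1e5, 2e5, 3e5, 4e5, 5e6, 6e6))
  cpgs <- data.frame(cpg_id = paste0("cg", 1:3), chrom = "chr1",
                     pos = c(2e5, 3e5, 2.5e5))
  theta <- rbeta(n, 2, 0.5)
  anc1 <- matrix(rbinom(n * 6, 1, theta), n, 6)
  anc2 <- matrix(rbinom(n * 6, 1, theta), n, 6)
  al1 <- matrix(rbinom(n * 6, 1, 0.4), n, 6)
  al2 <- matrix(rbinom(n * 6, 1, 0.4), n, 6)
  dec <- list(afr = al1 * anc1 + al2 * anc2,
              eur = al1 * (1 - anc1) + al2 * (1 - anc2))
  dec$total <- dec$afr + dec$eur
  colnames(dec$total) <- snps$snp_id
  la <- matrix(runif(n * 3), n, 3)
  M <- matrix(rnorm(3 * n), 3, n, dimnames = list(cpgs$cpg_id, NULL))
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  sc <- cis_scan(M, cpgs, snps, dec, la, X, window_bp = 1e6)
  # 4 SNPs lie within +/- 500 kb of each of the 3 CpGs
  expect_equal(sc$n_pairs, 12L)
  expect_equal(sc$meqtl_threshold, 0.05 / 12)
  # CpG processing order does not change per-pair results
  ord <- c(3, 1, 2)
  sc2 <- cis_scan(M[ord, ], cpgs[ord, ], snps, dec, la[, ord], X,
                  window_bp = 1e6)
  key <- function(s) s$records[order(s$records$cpg, s$records$snp),
                               c("cpg", "snp", "p_anc", "b_afr")]
  expect_equal(key(sc2), key(sc), ignore_attr = TRUE)
  # a CpG with no SNP in its window is skipped and logged
  cpg_far <- data.frame(cpg_id = "cg_far", chrom = "chr1", pos = 3e6)
  sc3 <- cis_scan(M[1, , drop = FALSE], cpg_far, snps, dec,
                  la[, 1, drop = FALSE], X, window_bp = 1e6)
  expect_equal(sc3$n_pairs, 0L)
  expect_equal(sc3$skipped_cpgs, "cg_far")
})

test_that("ancestry-effect patterns follow the published taxonomy", {
  thr <- 1e-3
  # opposite signs, both significant (effects as printed for the
  # opposite-direction exemplar)
  expect_equal(classify_pattern(-0.36, 0.44, 1e-5, 1e-5, 1e-8,
                                p_diff_threshold = thr), "opposite")
  # same direction, different magnitude
  expect_equal(classify_pattern(0.32, 0.80, 1e-5, 1e-6, 1e-8,
                                p_diff_threshold = thr),
               "same_direction_diff_magnitude")
  # single-ancestry effects
  expect_equal(classify_pattern(0.50, 0.02, 1e-6, 0.7, 1e-8,
                                p_diff_threshold = thr), "african_only")
  expect_equal(classify_pattern(0.01, 0.45, 0.6, 1e-6, 1e-8,
                                p_diff_threshold = thr), "european_only")
  # non-significant difference: comparable regardless of coefficients
  expect_equal(classify_pattern(0.5, 0.4, 1e-6, 1e-6, 0.2,
                                p_diff_threshold = thr), "comparable")
  # vectorized and exactly one label each
  labs <- classify_pattern(c(-0.36, 0.32), c(0.44, 0.80), c(1e-5, 1e-5),
                           c(1e-5, 1e-6), c(1e-8, 1e-8),
                           p_diff_threshold = thr)
  expect_equal(labs, c("opposite", "same_direction_diff_magnitude"))
})

test_that("meQTL replication uses count-derived thresholds", {
  leads <- data.frame(cpg = paste0("cg", 1:785), snp = paste0("s", 1:785),
                      sig_diff = c(rep(TRUE, 109), rep(FALSE, 676)))
  repl <- data.frame(cpg = leads$cpg, snp = leads$snp,
                     p_anc = 1e-10, p_diff = 1e-10)
  out <- replicate_meqtl(leads, repl)
  expect_equal(signif(out$summary$threshold_anc, 3), 6.37e-5)
  expect_equal(signif(out$summary$threshold_diff, 3), 4.59e-4)
  expect_equal(out$summary$pct_replicated, 100)
  expect_equal(out$summary$n_diff_replicated, 109)
  # a lead missing from the replication genotypes is not testable
  repl2 <- repl[-1, ]
  out2 <- replicate_meqtl(leads, repl2)
  expect_false(out2$flags$testable[1])
  expect_equal(out2$summary$n_replicated, 784)
})
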