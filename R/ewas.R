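# Shared least-squares helper: normal-equations fit with coefficient
# standard errors. Designs here are small and well-conditioned; a Cholesky
# failure signals genuine collinearity and is reported as such.
ols_fit <- function(X, y) {
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  XtX <- crossprod(X)
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXinv)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("design matrix is rank deficient (collinear: ",
         paste(bad, collapse = ", "), ")")
  }
  coef <- drop(XtXinv %*% crossprod(X, y))
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  se <- sqrt(pmax(diag(XtXinv), 0) * rss / df)
  names(coef) <- names(se) <- colnames(X)
  list(coef = coef, se = se, rss = rss, df = df, n = length(y),
       residuals = res)
}

.fix_pc_sign <- function(scores, loadings) {
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  scores
}

#' Principal components of control-probe intensities
#'
#' Samples are observations and probes are variables; probe means are
#' removed, scores come from the singular value decomposition and are
#' ordered by variance. The sign of each component is fixed by making its
#' largest-magnitude probe loading positive so outputs are stable across
#' runs.
#'
#' @param control probes x samples matrix.
#' @param k number of components (default 30, the number adjusted in the
#'   association models). Truncated with a warning when it exceeds the
#'   matrix rank.
#' @return samples x k matrix of PC scores (columns `cPC1`, ...).
#' @export
control_probe_pcs <- function(control, k = 30) {
  X <- scale(t(control), center = TRUE, scale = FALSE)
  sv <- svd(X)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (k > rank) {
    warning("requested ", k, " PCs but rank is ", rank, "; truncating")
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  scores <- .fix_pc_sign(scores, sv$v[, seq_len(k), drop = FALSE])
  dimnames(scores) <- list(colnames(control), paste0("cPC", seq_len(k)))
  scores
}

#' Stage-one residual principal components
#'
#' First stage of the two-stage association scan: every CpG's M-value is
#' regressed on all covariates except the ancestry variable of interest;
#' the top-k principal components of the stacked residual matrix are
#' returned, to be adjusted in the second-stage model where they absorb
#' unmodelled structure and reduce test-statistic inflation.
#'
#' @param M CpGs x samples matrix of M-values.
#' @param X samples x covariates design matrix (including intercept,
#'   excluding the ancestry variable of interest).
#' @param k number of residual PCs (default 5).
#' @return samples x k matrix of scores (columns `rPC1`, ...); attribute
#'   `degenerate` is TRUE when the residual matrix is numerically zero.
#' @export
stage1_residual_pcs <- function(M, X, k = 5) {
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("stage-1 design is rank deficient (collinear: ",
         paste(colnames(X)[q$pivot[-seq_len(q$rank)]], collapse = ", "), ")")
  Q <- qr.Q(q)
  R <- M - (M %*% Q) %*% t(Q)          # least-squares residuals, every CpG
  degenerate <- max(abs(R)) < 1e-8 * max(1, max(abs(M)))
  if (degenerate)
    warning("residual matrix is numerically zero; residual PCs are degenerate")
  Xr <- scale(t(R), center = TRUE, scale = FALSE)
  sv <- svd(Xr)
  k <- min(k, ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  scores <- .fix_pc_sign(scores, sv$v[, seq_len(k), drop = FALSE])
  dimnames(scores) <- list(colnames(M), paste0("rPC", seq_len(k)))
  attr(scores, "degenerate") <- degenerate
  scores
}

#' Epigenome-wide association scan
#'
#' Second-stage model: per CpG, ordinary least squares of the methylation
#' M-value on the ancestry variable plus covariates (which should include
#' control-probe PCs and the stage-one residual PCs), with a two-sided t
#' test on the ancestry coefficient. The ancestry variable is either one
#' value per sample (self-reported race, global ancestry) or a
#' samples x CpGs matrix (local ancestry, which varies by CpG).
#'
#' @param M CpGs x samples matrix of M-values.
#' @param ancestry numeric vector (length = samples) or samples x CpGs
#'   matrix of local-ancestry proportions.
#' @param X samples x covariates design (must include an intercept
#'   column).
#' @param alpha epigenome-wide significance cutoff for the `significant`
#'   flag (default 1.16e-7).
#' @return object of class `ewas_result`: data.frame with per-CpG
#'   `estimate`, `se`, `t`, `p`, `n`, `significant`, plus attributes
#'   `lambda` (genomic inflation of the ancestry p-values) and `alpha`.
#' @export
run_ewas <- function(M, ancestry, X, alpha = 1.16e-7) {
  n_cpg <- nrow(M)
  la_mode <- is.matrix(ancestry)
  if (la_mode) stopifnot(ncol(ancestry) == n_cpg, nrow(ancestry) == ncol(M))
  else stopifnot(length(ancestry) == ncol(M))
  out <- data.frame(cpg = rownames(M), estimate = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, n = NA_integer_)
  skipped <- character(0)
  for (i in seq_len(n_cpg)) {
    a <- if (la_mode) ancestry[, i] else ancestry
    Xi <- cbind(ancestry = a, X)
    yi <- M[i, ]
    ok <- stats::complete.cases(Xi, yi)
    if (sum(ok) <= ncol(Xi)) { skipped <- c(skipped, out$cpg[i]); next }
    fit <- ols_fit(Xi[ok, , drop = FALSE], yi[ok])
    tval <- fit$coef[1] / fit$se[1]
    out$estimate[i] <- fit$coef[1]
    out$se[i] <- fit$se[1]
    out$t[i] <- tval
    out$p[i] <- 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE)
    out$n[i] <- fit$n
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  structure(out, class = c("ewas_result", "data.frame"),
            lambda = genomic_inflation(out$p[!is.na(out$p)]),
            alpha = alpha, skipped = skipped)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square statistics implied by the
#' p-values divided by the null median \eqn{\chi^2_1(0.5) \approx 0.4549}.
#' Values near 1 indicate well-calibrated tests.
#'
#' @param p vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Bonferroni threshold
#'
#' @param alpha family-wise error rate in (0,1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Replication of discovery EWAS hits
#'
#' A discovery-significant CpG replicates when its replication p-value is
#' below `alpha` Bonferroni-corrected for the number of discovery hits and
#' the effect direction is concordant. CpGs absent from the replication
#' results are counted "not testable"; by default they stay in the
#' denominator of the replication percentage.
#'
#' @param discovery,replication `ewas_result` data.frames (or any
#'   data.frame with `cpg`, `estimate`, `p`, `significant`).
#' @param alpha total replication alpha (default 0.05).
#' @param drop_untestable exclude untestable CpGs from the percentage
#'   denominator.
#' @return list with per-CpG `flags` data.frame and a `summary` list
#'   (threshold, counts, percentage, Pearson correlation of effects).
#' @export
replicate_ewas <- function(discovery, replication, alpha = 0.05,
                           drop_untestable = FALSE) {
  disc <- discovery[discovery$significant, ]
  m <- nrow(disc)
  if (m == 0) stop("no discovery-significant CpGs to replicate")
  thr <- bonferroni_threshold(alpha, m)
  idx <- match(disc$cpg, replication$cpg)
  testable <- !is.na(idx) & !is.na(replication$p[idx])
  rep_p <- replication$p[idx]
  rep_est <- replication$estimate[idx]
  replicated <- testable & rep_p < thr &
    sign(rep_est) == sign(disc$estimate)
  flags <- data.frame(cpg = disc$cpg, discovery_estimate = disc$estimate,
                      replication_estimate = rep_est,
                      replication_p = rep_p,
                      testable = testable,
                      replicated = replicated %in% TRUE)
  denom <- if (drop_untestable) sum(testable) else m
  eff_cor <- if (sum(testable) >= 3 &&
                 stats::sd(disc$estimate[testable]) > 0 &&
                 stats::sd(rep_est[testable]) > 0)
    stats::cor(disc$estimate[testable], rep_est[testable]) else NA_real_
  list(flags = flags,
       summary = list(threshold = thr, n_discovery = m,
                      n_testable = sum(testable),
                      n_replicated = sum(flags$replicated),
                      pct_replicated = 100 * sum(flags$replicated) / denom,
                      effect_correlation = eff_cor))
}
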