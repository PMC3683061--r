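# Independent oracles and fixture builders used across the suite.

# Exact HWE p-value by direct evaluation of the conditional multinomial
# probabilities with log-factorials (independent of the package's ratio
# recurrence).
hwe_enumeration_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nA <- 2 * nbb + nab
  nA <- min(nA, 2 * n - nA)
  if (nA == 0) return(1)
  hets <- seq(nA %% 2, nA, by = 2)
  lp <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- n - h - a
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  po <- p[match(nab, hets)]
  sum(p[p <= po * (1 + 1e-12)])
}

# Dual C-SVM objective via kernlab's interior-point QP solver (independent
# of the package's SMO); the objective is evaluated directly at the returned
# solution.
qp_svm_objective <- function(K, y, C) {
  n <- length(y)
  Q <- outer(y, y) * unclass(K)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q, A = t(y), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), maxiter = 200)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * sum(a * (Q %*% a))
}

# AUC as the tie-corrected pairwise concordance count.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random linearly separable two-class problem.
random_separable <- function(n, d = 2, margin = 1) {
  y <- sample(c(-1, 1), n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + y * (2 + margin)
  list(X = X, y = y)
}

# Small genotype matrix fixture with given call matrix.
toy_genotype <- function(calls, chrom = NULL) {
  rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("rs%d", seq_len(ncol(calls)))
  genotype_matrix(calls, chrom = chrom)
}

# Small in-memory cohort bundle with controllable per-view signal; used for
# protocol tests without touching the image pipeline.
toy_bundle <- function(n = 40, n_pos = 10, d_effect = 0, g_effect = 0,
                       i_effect = 0, p_feats = c(D = 5, G = 6, I = 4)) {
  ids <- sprintf("s%03d", seq_len(n))
  y <- rep(-1, n)
  y[seq_len(n_pos)] <- 1
  mk <- function(p, eff) {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(ids, NULL))
    x[, 1] <- x[, 1] + eff * (y > 0)
    if (p > 1) x[, 2] <- x[, 2] + 0.6 * eff * (y > 0)
    x
  }
  match_subjects(demographics = mk(p_feats[["D"]], d_effect),
                 genotypes = mk(p_feats[["G"]], g_effect),
                 images = mk(p_feats[["I"]], i_effect),
                 labels = stats::setNames(y, ids))
}
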