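# Independent oracles used to check the package's own implementations.
# These deliberately share no code with the solver / evaluation paths.

# Proximal-gradient (FISTA) minimizer of the weighted-L1 logistic
# objective: -sum loglik + lambda * sum w_j |beta_j|, intercept
# unpenalized. Run to high precision on small instances only.
oracle_weighted_l1 <- function(x, y, lambda, weights,
                               max_iter = 100000, tol = 1e-14) {
  x <- as.matrix(x)
  p <- ncol(x)
  w <- rep_len(as.numeric(weights), p)
  keep <- is.finite(w)
  xt <- cbind(1, x[, keep, drop = FALSE])
  wk <- w[keep]
  L <- 0.25 * max(eigen(crossprod(xt), symmetric = TRUE,
                        only.values = TRUE)$values)
  obj <- function(th) {
    eta <- drop(xt %*% th)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    -ll + lambda * sum(wk * abs(th[-1]))
  }
  grad <- function(th) {
    eta <- drop(xt %*% th)
    -drop(crossprod(xt, y - plogis(eta)))
  }
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  th <- c(qlogis(mean(y)), rep(0, sum(keep)))
  z <- th
  tk <- 1
  f_prev <- obj(th)
  for (it in seq_len(max_iter)) {
    u <- z - grad(z) / L
    th_new <- c(u[1], soft(u[-1], lambda * wk / L))
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- th_new + ((tk - 1) / t_new) * (th_new - th)
    th <- th_new
    tk <- t_new
    if (it %% 200 == 0) {
      f_cur <- obj(th)
      if (abs(f_prev - f_cur) < tol * max(1, abs(f_cur))) break
      f_prev <- f_cur
    }
  }
  beta <- numeric(p)
  beta[keep] <- th[-1]
  list(intercept = th[1], beta = beta, objective = obj(th))
}

# Trapezoidal integration of the empirical ROC polygon.
trapezoid_auc <- function(p, y) {
  thr <- sort(unique(p), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(p[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p[y == 0] >= t), numeric(1))
  xs <- c(0, fpr)
  ys <- c(0, tpr)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

# Rank-based AUC (Mann-Whitney with ties counted 1/2).
rank_auc <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(c(p[y == 1], p[y == 0]), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Paired permutation test for the AUC difference of two score vectors on
# the same subjects: per-subject swap of the two scores with prob 1/2.
perm_auc_difference_p <- function(pa, pb, y, B = 10000, seed = 1) {
  obs <- abs(rank_auc(pa, y) - rank_auc(pb, y))
  n <- length(y)
  hits <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    sw <- runif(n) < 0.5
    a2 <- ifelse(sw, pb, pa)
    b2 <- ifelse(sw, pa, pb)
    if (abs(rank_auc(a2, y) - rank_auc(b2, y)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# Sign-flip permutation p-value for a paired mean difference.
perm_paired_p <- function(d, B = 10000, seed = 1) {
  obs <- abs(mean(d))
  set.seed(seed)
  hits <- sum(vapply(seq_len(B), function(b) {
    abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE))) >=
      obs - 1e-12
  }, logical(1)))
  (hits + 1) / (B + 1)
}

# Small random logistic instance for solver tests.
random_instance <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(25:40, 1)
  if (is.null(p)) p <- sample(2:6, 1)
  x <- matrix(rnorm(n * p), n, p)
  x <- scale(x)
  colnames(x) <- paste0("v", seq_len(p))
  beta <- rnorm(p, 0, 0.8)
  y <- rbinom(n, 1, plogis(drop(x %*% beta)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(x = x, y = y)
}

# Small signal cohort design used by pipeline tests.
signal_design <- function(seed, contrast = "lung_adk") {
  co <- generate_cohort(default_cohort_spec(contrast, seed = seed))
  qc <- qc_cohort(co)
  d <- build_design(qc$retained, qc$retained_compounds, contrast)
  d$qc <- qc
  d
}
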