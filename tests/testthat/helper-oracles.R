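# Independent oracles shared by the model and evaluation test files. These
# deliberately use different algorithms from the implementation they check:
# numerical quadrature, explicit matrix inversion, and pairwise enumeration.

toy_params <- function(sigma_w2 = 1e-6, sigma_e2 = 4,
                       G = matrix(c(25, 0.005, 0.005, 4e-6), 2, 2)) {
  model_params(c("(Intercept)" = 90, age = -0.5,
                 f508delheterozygous = -2, f508delneither_unknown = -1,
                 sexmale = 1, medicaidTRUE = -3),
               G, sigma_w2, sigma_e2)
}

random_design <- function(n) {
  cbind("(Intercept)" = 1, age = runif(n, 8, 30),
        f508delheterozygous = rbinom(n, 1, .4),
        f508delneither_unknown = 0, sexmale = rbinom(n, 1, .5),
        medicaidTRUE = rbinom(n, 1, .5))
}

# numerical oracle: Cov(W(s), W(t)) = sigma_w2 * int_0^s int_0^t min(u,v),
# as nested adaptive quadrature (the inner integral is split at v = u where
# the integrand has a kink)
ibm_numeric <- function(s, t, sigma_w2 = 1) {
  if (s == 0 || t == 0) return(0)
  inner <- function(u) {
    vapply(u, function(ui) {
      a <- stats::integrate(function(v) pmin(ui, v), 0, min(ui, t),
                            rel.tol = 1e-11)$value
      b <- if (t > ui) stats::integrate(function(v) pmin(ui, v), ui, t,
                                        rel.tol = 1e-11)$value else 0
      a + b
    }, numeric(1))
  }
  sigma_w2 * stats::integrate(inner, 0, s, rel.tol = 1e-11)$value
}

# partitioned-Gaussian conditioning with explicit matrix inversion
conditioning_oracle <- function(params, ht, hy, hX, ft, fX) {
  allt <- c(ht, ft)
  Z <- cbind(1, allt)
  V <- Z %*% params$G %*% t(Z) +
    outer(allt, allt, function(a, b) ibm_kernel(a, b, params$sigma_w2)) +
    diag(params$sigma_e2, length(allt))
  mu <- drop(rbind(hX, fX) %*% params$beta)
  hi <- seq_along(ht); fi <- length(ht) + seq_along(ft)
  m <- mu[fi] + V[fi, hi] %*% solve(V[hi, hi]) %*% (hy - mu[hi])
  S <- V[fi, fi] - V[fi, hi] %*% solve(V[hi, hi]) %*% V[hi, fi]
  list(mean = drop(m), cov = S)
}

# pair-counting oracle for the Mann-Whitney statistic
auc_pairs <- function(scores, outcomes) {
  pos <- scores[outcomes]; neg <- scores[!outcomes]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive oracle: evaluate TPR/FPR at every candidate threshold directly
roc_bruteforce <- function(scores, outcomes) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(th) {
    pred <- scores >= th
    data.frame(threshold = th,
               tpr = sum(pred & outcomes) / sum(outcomes),
               fpr = sum(pred & !outcomes) / sum(!outcomes))
  }))
}
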