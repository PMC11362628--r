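# Stochastic-process model: IBM kernel, marginal covariance, likelihood,
# conditional forecasting, and PEx probabilities, each against an
# independent oracle.

test_that("IBM kernel matches the closed-form worked values", {
  expect_equal(ibm_kernel(1, 1, 1), 1 / 3)
  expect_equal(ibm_kernel(0, 5, 1), 0)
  expect_equal(ibm_kernel(1, 2, 1), 5 / 6)
  expect_equal(ibm_kernel(2, 1, 1), ibm_kernel(1, 2, 1))  # symmetry
  expect_error(ibm_kernel(-1, 2), class = "pexfair_param_error")
})

test_that("IBM kernel matches numerical double integration of min(u,v)", {
  skip_if_not_installed("pracma")
  set.seed(5)
  pts <- cbind(s = runif(20, 0, 8), t = runif(20, 0, 8))
  for (i in seq_len(nrow(pts))) {
    expect_lt(abs(ibm_kernel(pts[i, "s"], pts[i, "t"], 0.37) -
                    ibm_numeric(pts[i, "s"], pts[i, "t"], 0.37)), 1e-6)
  }
})

test_that("marginal covariance has the stated structure and is PSD", {
  p0 <- toy_params(G = matrix(0, 2, 2), sigma_w2 = 0, sigma_e2 = 2.5)
  expect_equal(marginal_covariance(0, p0), matrix(2.5, 1, 1))
  set.seed(8)
  for (rep in 1:10) {
    tt <- sort(runif(6, 0, 1000))
    V <- marginal_covariance(tt, toy_params())
    expect_equal(V, t(V))
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("simulated trajectory covariance recovers the analytic kernel", {
  # shared oracle between the generator and the model: sample covariance of
  # many simulated trajectories at fixed times vs Z G Z' + sw2 K + se2 I
  params <- toy_params(sigma_w2 = 5e-7, sigma_e2 = 4)
  tt <- c(0, 200, 500, 900)
  pat <- patient_row("P1")
  n_rep <- 4000
  set.seed(123)
  Y <- t(replicate(n_rep, as.numeric(simulate_fev1(pat, tt, params))))
  expect_equal(sum(apply(Y, 2, function(y) sum(y %in% c(1, 150)))), 0) # unclipped regime
  S <- cov(Y)
  V <- marginal_covariance(tt, params)
  # elementwise within Monte-Carlo error: sd of a covariance entry is
  # roughly sqrt((V_ii V_jj + V_ij^2)/n); allow 4 of those
  tol <- 4 * sqrt((outer(diag(V), diag(V)) + V^2) / n_rep)
  expect_true(all(abs(S - V) < tol))
})

test_that("noise-free limit reproduces the fixed-effect mean curve", {
  params <- toy_params(G = matrix(0, 2, 2), sigma_w2 = 0, sigma_e2 = 1e-12)
  pat <- patient_row("P1", f508del = "heterozygous")
  tt <- c(0, 100, 400)
  set.seed(1)
  y <- as.numeric(simulate_fev1(pat, tt, params))
  age <- 10 + tt / 365.25
  mu <- 90 - 0.5 * age - 2  # intercept + age + het, female, no medicaid
  expect_equal(y, mu, tolerance = 1e-4)
})

test_that("log-likelihood matches closed forms and dense-matrix oracle", {
  # single standard-normal residual at zero
  p1 <- model_params(c("(Intercept)" = 90), matrix(0, 2, 2), 0, 1,
                     formula = ~1)
  reg1 <- registry(patient_row("P1"), encounter_rows("P1", 0, 90))
  expect_equal(lung_loglik(reg1, p1), -0.5 * log(2 * pi))

  # block-diagonal sum vs one dense multivariate normal over all patients
  reg <- generate_registry(sim_config(n_patients = 3, seed = 21))
  params <- toy_params()
  ll <- lung_loglik(reg, params)
  ef <- merge(reg$encounters, reg$patients, by = "patient_id")
  ef <- ef[order(ef$patient_id, ef$t), ]
  X <- pexfair:::lung_design_matrix(ef, params$formula)
  resid <- ef$fev1_pp - drop(X %*% params$beta)
  n <- nrow(ef)
  V <- matrix(0, n, n)
  for (pid in unique(ef$patient_id)) {
    i <- which(ef$patient_id == pid)
    V[i, i] <- marginal_covariance(ef$t[i], params)
  }
  dense <- -0.5 * (n * log(2 * pi) +
                     determinant(V, logarithm = TRUE)$modulus +
                     drop(resid %*% solve(V, resid)))
  expect_equal(ll, as.numeric(dense), tolerance = 1e-8)

  # Gaussian monotonicity: growing the residual lowers the likelihood
  reg_shift <- registry(patient_row("P1"), encounter_rows("P1", 0, 95))
  expect_lt(lung_loglik(reg_shift, p1), lung_loglik(reg1, p1))
})

test_that("conditional prediction equals partitioned-Gaussian conditioning", {
  set.seed(17)
  params <- toy_params()
  for (rep in 1:12) {
    n_h <- sample(1:4, 1); n_f <- sample(1:2, 1)
    tt <- sort(runif(n_h + n_f, 0, 1200))
    ht <- tt[seq_len(n_h)]; ft <- tt[n_h + seq_len(n_f)]
    hX <- random_design(n_h); fX <- random_design(n_f)
    hy <- 90 + rnorm(n_h, 0, 8)
    fc <- conditional_prediction(params, ht, hy, hX, ft, fX)
    oracle <- conditioning_oracle(params, ht, hy, hX, ft, fX)
    expect_lt(max(abs(fc$mean - oracle$mean)), 1e-8)
    expect_lt(norm(fc$covariance - oracle$cov, "F"), 1e-8)
  }
})

test_that("empty history returns the prior; tiny noise interpolates", {
  params <- toy_params()
  fX <- random_design(2); ft <- c(100, 300)
  fc <- conditional_prediction(params, numeric(0), numeric(0),
                               fX[0, , drop = FALSE], ft, fX)
  expect_equal(fc$mean, drop(fX %*% params$beta))
  Z <- cbind(1, ft)
  prior <- Z %*% params$G %*% t(Z) +
    outer(ft, ft, function(a, b) ibm_kernel(a, b, params$sigma_w2)) +
    diag(params$sigma_e2, 2)
  expect_equal(fc$covariance, prior)

  p_small <- toy_params(sigma_e2 = 1e-9)
  ht <- c(50, 200); hy <- c(88, 84); hX <- random_design(2)
  fc2 <- conditional_prediction(p_small, ht, hy, hX, 200 + 1e-7,
                                hX[2, , drop = FALSE])
  expect_equal(fc2$mean, 84, tolerance = 1e-3)
  expect_lt(fc2$covariance[1, 1], 1e-4)
})

test_that("single-grid-point PEx probability matches the analytic normal form", {
  set.seed(31)
  params <- toy_params()
  for (rep in 1:5) {
    ht <- sort(runif(3, 0, 300)); hy <- 85 + rnorm(3, 0, 6)
    hX <- random_design(3)
    t0 <- max(ht) + 1
    thr <- runif(1, 70, 90)
    step <- 50
    fc <- conditional_prediction(params, ht, hy, hX, t0 + step,
                                 matrix(hX[3, ], 1))
    exact <- pnorm((thr - fc$mean) / sqrt(fc$covariance[1, 1]))
    n_mc <- 4000
    p_mc <- pex_probability(params, ht, hy, hX, t = t0, threshold = thr,
                            horizons = c(h = step), future_X = hX[3, ],
                            grid_step_days = step, n_samples = n_mc, seed = rep)
    mc_se <- sqrt(max(exact * (1 - exact), 1e-6) / n_mc)
    expect_lt(abs(p_mc[["h"]] - exact), 3 * mc_se + 1e-9)
  }
})

test_that("far-above-threshold forecasts give near-zero probability", {
  params <- toy_params(G = matrix(0, 2, 2), sigma_w2 = 0, sigma_e2 = 1)
  hX <- random_design(1)
  # prior mean is ~ 75-85; threshold 40 below it with total sd ~ 1
  mu <- drop(hX %*% params$beta)
  p <- pex_probability(params, numeric(0), numeric(0), hX[0, , drop = FALSE],
                       t = 0, threshold = mu - 40, horizons = c(m = 30.4375),
                       future_X = hX[1, ], n_samples = 2000, seed = 2)
  expect_lt(p[["m"]], 0.001)
})

test_that("PEx probability is monotone nondecreasing in the horizon", {
  set.seed(12)
  params <- toy_params()
  for (rep in 1:5) {
    ht <- sort(runif(4, 0, 400)); hy <- 85 + rnorm(4, 0, 6)
    hX <- random_design(4)
    p <- pex_probability(params, ht, hy, hX, t = max(ht), threshold = 80,
                         horizons = default_horizons(), future_X = hX[4, ],
                         n_samples = 300, seed = rep)
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("invalid parameter objects are rejected", {
  expect_error(model_params(c(a = 1), matrix(c(1, 2, 2, 1), 2), 1, 1),
               class = "pexfair_param_error")  # G not PSD
  expect_error(model_params(c(a = 1), matrix(c(1, 0.5, 0, 1), 2), 1, 1),
               class = "pexfair_param_error")  # G not symmetric
  expect_error(model_params(c(a = 1), diag(2), -1, 1),
               class = "pexfair_param_error")
  expect_error(model_params(c(a = 1), diag(2), 1, 0),
               class = "pexfair_param_error")
})

test_that("model fit recovers generating parameters on a small cohort", {
  # smaller, faster cousin of the full recovery study in the acceptance
  # suite: 80 patients, ~15 visits
  true <- model_params(c("(Intercept)" = 100, age = -0.7,
                         f508delheterozygous = -2, f508delneither_unknown = -1,
                         sexmale = 1, medicaidTRUE = -4),
                       matrix(c(81, 0, 0, 1.6e-5), 2, 2),
                       sigma_w2 = 2e-8, sigma_e2 = 16)
  cfg <- sim_config(n_patients = 80, followup_years_mean = 3.5,
                    true_params = true, iv_trigger_pp = 0, seed = 77)
  reg <- generate_registry(cfg)
  fit <- fit_lung_model(reg)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$sigma_e2 - 16) / 16, 0.2)
  # truth within 3 GLS standard errors for each coefficient
  z <- abs(fit$params$beta - true$beta) / fit$beta_se
  expect_true(all(z < 3))
  # fitted likelihood at least as high as at the generating parameters
  true_ll <- lung_loglik(reg, true)
  expect_gte(fit$loglik, true_ll - 1e-6)
})
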