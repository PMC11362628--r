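# Longitudinal FEV1 model: fixed effects + random intercept/slope +
# continuous-time integrated Brownian motion (IBM) + measurement error.
# The IBM term is what makes within-patient serial correlation nonstationary:
# Var(W(t)) grows like t^3, so forecasts degrade smoothly with lead time.

#' Default fixed-effect design for the lung function model
#'
#' Age at encounter, F508del genotype, sex, and Medicaid insurance use. The
#' model accepts any formula over patient and encounter columns; this subset
#' keeps simulation-based parameter recovery identifiable at modest cohort
#' sizes.
#'
#' @return A formula.
#' @export
default_lung_formula <- function() {
  ~ age + f508del + sex + medicaid
}

#' Parameters of the stochastic-process lung function model
#'
#' The model for FEV1 percent predicted of patient i at time t (days since
#' first encounter) is
#'   y_i(t) = x_i(t)' beta + b0_i + b1_i t + W_i(t) + e_i(t),
#' with (b0_i, b1_i) ~ N(0, G), W_i integrated Brownian motion with scale
#' `sigma_w2`, and iid measurement error with variance `sigma_e2`.
#'
#' @param beta Named numeric vector of fixed-effect coefficients; names must
#'   match the columns of the design matrix built from `formula`.
#' @param G 2x2 symmetric positive semidefinite covariance of the random
#'   intercept (percent predicted^2) and slope (percent predicted^2 / day^2).
#' @param sigma_w2 IBM scale, percent predicted^2 per day^3, >= 0.
#' @param sigma_e2 Residual variance, percent predicted^2, > 0.
#' @param formula Fixed-effect design formula.
#' @return An object of class `lung_params`.
#' @export
model_params <- function(beta, G, sigma_w2, sigma_e2,
                         formula = default_lung_formula()) {
  G <- as.matrix(G)
  stopifnot(is.numeric(beta), all(is.finite(beta)),
            identical(dim(G), c(2L, 2L)), is_number(sigma_w2), is_number(sigma_e2))
  if (max(abs(G - t(G))) > 1e-10) {
    stop_named("pexfair_param_error", "G must be symmetric")
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop_named("pexfair_param_error", "G is not positive semidefinite")
  }
  if (sigma_w2 < 0) stop_named("pexfair_param_error", "sigma_w2 must be >= 0")
  if (sigma_e2 <= 0) stop_named("pexfair_param_error", "sigma_e2 must be > 0")
  structure(list(beta = beta, G = G, sigma_w2 = sigma_w2, sigma_e2 = sigma_e2,
                 formula = formula),
            class = "lung_params")
}

#' @export
print.lung_params <- function(x, ...) {
  cat("<lung_params>\n  beta:\n")
  print(x$beta)
  cat(sprintf("  G: [%g, %g; %g, %g]\n", x$G[1, 1], x$G[1, 2], x$G[2, 1], x$G[2, 2]))
  cat(sprintf("  sigma_w2: %g  sigma_e2: %g\n", x$sigma_w2, x$sigma_e2))
  invisible(x)
}

#' Integrated Brownian motion covariance kernel
#'
#' Covariance of W(s) and W(t) where W(t) is the time integral of standard
#' Brownian motion scaled by `sigma_w2`:
#' `sigma_w2 * min(s,t)^2 * (3*max(s,t) - min(s,t)) / 6`.
#'
#' @param s,t Nonnegative times (days); recycled to a common length.
#' @param sigma_w2 Process scale, >= 0.
#' @return Covariance value(s).
#' @export
ibm_kernel <- function(s, t, sigma_w2 = 1) {
  if (any(s < 0) || any(t < 0)) {
    stop_named("pexfair_param_error", "ibm_kernel requires nonnegative times")
  }
  mn <- pmin(s, t)
  mx <- pmax(s, t)
  sigma_w2 * mn^2 * (3 * mx - mn) / 6
}

ibm_kernel_matrix <- function(times, sigma_w2 = 1) {
  n <- length(times)
  mn <- outer(times, times, pmin)
  mx <- outer(times, times, pmax)
  sigma_w2 * mn^2 * (3 * mx - mn) / 6
}

#' Marginal covariance of one patient's FEV1 measurements
#'
#' `Z G Z' + sigma_w2 * K_ibm + sigma_e2 * I` with Z = [1, t].
#'
#' @param times Increasing measurement times in days.
#' @param params A `lung_params`.
#' @return Symmetric positive definite matrix.
#' @export
marginal_covariance <- function(times, params) {
  stopifnot(inherits(params, "lung_params"))
  if (is.unsorted(times)) stop_named("pexfair_param_error", "times must be increasing")
  Z <- cbind(1, times)
  Z %*% params$G %*% t(Z) + ibm_kernel_matrix(times, params$sigma_w2) +
    diag(params$sigma_e2, length(times))
}

# Cholesky with a documented jitter fallback: on failure adds
# 1e-8 * mean(diag) to the diagonal (repeatedly, up to 6 times, scaling by
# 10) and emits one warning naming the final jitter.
chol_jitter <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(R)) return(R)
  jit <- 1e-8 * mean(diag(V))
  for (k in 1:6) {
    R <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (!is.null(R)) {
      warning(sprintf("covariance not positive definite; added jitter %g", jit),
              call. = FALSE)
      return(R)
    }
    jit <- jit * 10
  }
  stop_named("pexfair_numeric_error",
             "covariance matrix is singular even after jitter; consider larger sigma_e2")
}

# Build the fixed-effect design matrix for encounter rows joined with their
# patient rows. Factors get the registry's canonical level order so
# coefficient names are stable across data sets.
lung_design_matrix <- function(df, formula = default_lung_formula()) {
  if ("f508del" %in% names(df)) {
    df$f508del <- factor(df$f508del, levels = F508_LEVELS)
  }
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = SEX_LEVELS)
  if ("race" %in% names(df)) df$race <- factor(df$race, levels = RACE_LEVELS)
  stats::model.matrix(formula, df)
}

# Join encounters with patient covariates; the one place the two tables meet.
encounter_frame <- function(reg) {
  merge(reg$encounters, reg$patients, by = "patient_id", sort = FALSE)
}

# Per-patient (y, X, t) blocks in a stable patient order.
patient_blocks <- function(reg, formula) {
  ef <- encounter_frame(reg)
  ord <- order(ef$patient_id, ef$t)
  ef <- ef[ord, , drop = FALSE]
  X <- lung_design_matrix(ef, formula)
  idx <- split(seq_len(nrow(ef)), ef$patient_id)
  lapply(idx, function(i) {
    tt <- ef$t[i]
    # unit-scale IBM kernel and Z cached once; the optimizer reuses them at
    # every likelihood evaluation
    list(y = ef$fev1_pp[i], X = X[i, , drop = FALSE], t = tt,
         Z = cbind(1, tt), K0 = ibm_kernel_matrix(tt, 1))
  })
}

#' Marginal log-likelihood of the lung function model
#'
#' Sum over patients of the multivariate normal log density of the FEV1
#' residuals (y - X beta) under each patient's marginal covariance.
#'
#' @param reg A `cf_registry`.
#' @param params A `lung_params` with beta named for the design of
#'   `params$formula`.
#' @return Scalar log-likelihood.
#' @export
lung_loglik <- function(reg, params) {
  stopifnot(inherits(reg, "cf_registry"), inherits(params, "lung_params"))
  blocks <- patient_blocks(reg, params$formula)
  ll <- 0
  for (b in blocks) {
    V <- marginal_covariance(b$t, params)
    R <- chol_jitter(V)
    r <- b$y - drop(b$X %*% params$beta)
    w <- backsolve(R, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
  }
  ll
}

# Variance parameters on an unconstrained scale:
# theta = (log L11, L21, log L22, log sigma_w2, log sigma_e2) with G = L L'.
theta_to_vc <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  list(G = L %*% t(L), sigma_w2 = exp(theta[4]), sigma_e2 = exp(theta[5]))
}

vc_to_theta <- function(G, sigma_w2, sigma_e2) {
  L <- t(chol(G + diag(1e-12 * max(diag(G), 1), 2)))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]), log(max(sigma_w2, 1e-12)), log(sigma_e2))
}

# Profiled (beta solved by GLS) negative log-likelihood and GLS summaries
# for a given variance parameter vector.
profiled_nll <- function(theta, blocks, reml = FALSE) {
  vc <- theta_to_vc(theta)
  p <- ncol(blocks[[1]]$X)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yty <- 0
  logdet <- 0
  n_total <- 0
  for (b in blocks) {
    n_i <- length(b$y)
    V <- b$Z %*% tcrossprod(vc$G, b$Z) + vc$sigma_w2 * b$K0
    diag(V) <- diag(V) + vc$sigma_e2
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(nll = 1e10))
    W <- backsolve(R, cbind(b$X, b$y), transpose = TRUE)
    Wx <- W[, seq_len(p), drop = FALSE]
    wy <- W[, p + 1L]
    XtVX <- XtVX + crossprod(Wx)
    XtVy <- XtVy + drop(crossprod(Wx, wy))
    yty <- yty + sum(wy^2)
    logdet <- logdet + 2 * sum(log(diag(R)))
    n_total <- n_total + n_i
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10))
  quad <- yty - sum(beta * XtVy)
  nll <- 0.5 * (logdet + n_total * log(2 * pi) + quad)
  if (reml) nll <- nll + 0.5 * determinant(XtVX, logarithm = TRUE)$modulus
  list(nll = as.numeric(nll), beta = beta, XtVX = XtVX)
}

#' Fit the lung function model by maximum (restricted) likelihood
#'
#' Variance components are optimized on an unconstrained scale (log standard
#' deviations, Cholesky factor of G) with fixed effects profiled out by
#' generalized least squares, using Nelder-Mead.
#'
#' @param reg A `cf_registry` with at least 2 patients.
#' @param formula Fixed-effect design formula over encounter and patient
#'   columns.
#' @param init Optional `lung_params` used as a starting point.
#' @param method "ML" (default) or "REML".
#' @param control Passed to `stats::optim` (default `maxit = 1000`).
#' @return A list of class `lung_fit`: `params` (a `lung_params`), `beta_se`
#'   (GLS standard errors), `loglik`, `converged`, `iterations`.
#' @export
fit_lung_model <- function(reg, formula = default_lung_formula(), init = NULL,
                           method = c("ML", "REML"), control = list(maxit = 1000)) {
  stopifnot(inherits(reg, "cf_registry"))
  method <- match.arg(method)
  if (nrow(reg$patients) < 2L) {
    stop_named("pexfair_param_error", "fitting requires at least 2 patients")
  }
  blocks <- patient_blocks(reg, formula)
  X_all <- do.call(rbind, lapply(blocks, `[[`, "X"))
  if (qr(X_all)$rank < ncol(X_all)) {
    stop_named("pexfair_param_error", "fixed-effect design matrix is rank deficient")
  }

  if (is.null(init)) {
    # moment-flavored starting values: split the raw residual variance
    # between patient-level heterogeneity and noise
    y_all <- unlist(lapply(blocks, `[[`, "y"))
    v0 <- stats::var(y_all)
    theta0 <- vc_to_theta(diag(c(v0 / 2, 1e-6)), 1e-9, v0 / 4)
  } else {
    stopifnot(inherits(init, "lung_params"))
    theta0 <- vc_to_theta(init$G, init$sigma_w2, init$sigma_e2)
  }

  reml <- method == "REML"
  fn <- function(theta) profiled_nll(theta, blocks, reml = reml)$nll
  # Nelder-Mead with restarts: the simplex can collapse early in 5
  # dimensions, so re-launch from the incumbent until no further gain
  opt <- stats::optim(theta0, fn, method = "Nelder-Mead", control = control)
  n_eval <- opt$counts[["function"]]
  for (restart in 1:5) {
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead", control = control)
    n_eval <- n_eval + opt2$counts[["function"]]
    improved <- opt$value - opt2$value
    opt <- opt2
    if (improved < 1e-5) break
  }
  opt$counts[["function"]] <- n_eval
  fin <- profiled_nll(opt$par, blocks, reml = reml)
  vc <- theta_to_vc(opt$par)
  beta <- fin$beta
  names(beta) <- colnames(blocks[[1]]$X)
  params <- model_params(beta, vc$G, vc$sigma_w2, vc$sigma_e2, formula = formula)
  beta_se <- sqrt(diag(solve(fin$XtVX)))
  names(beta_se) <- names(beta)
  structure(list(params = params, beta_se = beta_se,
                 loglik = -fin$nll, converged = opt$convergence == 0L,
                 iterations = opt$counts[["function"]], method = method),
            class = "lung_fit")
}

#' @export
print.lung_fit <- function(x, ...) {
  cat(sprintf("<lung_fit> %s, logLik %.3f, converged: %s (%d evaluations)\n",
              x$method, x$loglik, x$converged, x$iterations))
  print(x$params)
  invisible(x)
}

#' Conditional forecast of future FEV1 measurements
#'
#' Gaussian conditioning of the joint (history, future) normal vector on the
#' observed history. With an empty history the prior mean and covariance are
#' returned. The forecast targets future *measurements* (the quantity the
#' exacerbation labeling rule sees), so `sigma_e2` is included on the future
#' diagonal by default.
#'
#' @param params A `lung_params`.
#' @param hist_t,hist_y Observed times (days) and FEV1 values; may be empty.
#' @param hist_X Design matrix rows for the history (n_hist x p).
#' @param future_t Future times, all greater than `max(hist_t)`.
#' @param future_X Design matrix rows for the future times.
#' @param include_noise Add `sigma_e2` to the future covariance diagonal.
#' @return List of class `lung_forecast` with `times`, `mean`, `covariance`.
#' @export
conditional_prediction <- function(params, hist_t, hist_y, hist_X,
                                   future_t, future_X, include_noise = TRUE) {
  stopifnot(inherits(params, "lung_params"))
  n_h <- length(hist_t)
  n_f <- length(future_t)
  stopifnot(length(hist_y) == n_h, n_f >= 1L)
  if (n_h > 0 && any(future_t <= max(hist_t))) {
    stop_named("pexfair_param_error", "future times must exceed all history times")
  }
  mu_f <- drop(future_X %*% params$beta)
  all_t <- c(hist_t, future_t)
  Z <- cbind(1, all_t)
  V <- Z %*% params$G %*% t(Z) + ibm_kernel_matrix(all_t, params$sigma_w2)
  if (n_h > 0) diag(V)[1:n_h] <- diag(V)[1:n_h] + params$sigma_e2
  if (include_noise) {
    diag(V)[(n_h + 1):(n_h + n_f)] <- diag(V)[(n_h + 1):(n_h + n_f)] + params$sigma_e2
  }
  if (n_h == 0L) {
    out <- list(times = future_t, mean = mu_f,
                covariance = V)
    return(structure(out, class = "lung_forecast"))
  }
  hi <- 1:n_h
  fi <- (n_h + 1):(n_h + n_f)
  V_hh <- V[hi, hi, drop = FALSE]
  V_fh <- V[fi, hi, drop = FALSE]
  V_ff <- V[fi, fi, drop = FALSE]
  mu_h <- drop(hist_X %*% params$beta)
  R <- chol_jitter(V_hh)
  # A = V_fh V_hh^-1 via two triangular solves
  W <- backsolve(R, t(V_fh), transpose = TRUE)      # R'^-1 V_hf
  alpha <- backsolve(R, hist_y - mu_h, transpose = TRUE)
  mean_f <- mu_f + drop(crossprod(W, alpha))
  cov_f <- V_ff - crossprod(W)
  cov_f <- (cov_f + t(cov_f)) / 2
  structure(list(times = future_t, mean = mean_f, covariance = cov_f),
            class = "lung_forecast")
}

# Draw n joint samples (rows) from a lung_forecast.
forecast_samples <- function(forecast, n) {
  S <- forecast$covariance
  d <- diag(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    R <- chol(S + diag(1e-10 * max(mean(d), 1), nrow(S)))
  }
  z <- matrix(stats::rnorm(n * nrow(S)), n, nrow(S))
  sweep(z %*% R, 2, forecast$mean, `+`)
}

#' Probability of a FIES-defined exacerbation within prediction horizons
#'
#' Monte Carlo estimate of the probability that the forecast FEV1 path drops
#' to or below `threshold` at some monthly grid point within each horizon:
#' P(min over grid points in (t, t + horizon] of predicted FEV1 <= threshold).
#' All horizons are evaluated on one set of joint samples over the union
#' grid, so the estimates are monotone nondecreasing in the horizon by
#' construction.
#'
#' @param params A `lung_params`.
#' @param hist_t,hist_y,hist_X Patient history as in
#'   [conditional_prediction()].
#' @param t Prediction origin (days); history times must be <= t.
#' @param threshold FEV1 level defining the event (baseline minus the FIES
#'   drop).
#' @param horizons Horizon lengths in days, default 3/6/12 months.
#' @param future_X Single design row (covariates frozen at time t), recycled
#'   over the grid.
#' @param grid_step_days Forecast grid spacing, default one month.
#' @param n_samples Monte Carlo sample size.
#' @param seed Optional seed for reproducibility.
#' @return Named numeric vector of probabilities, one per horizon.
#' @export
pex_probability <- function(params, hist_t, hist_y, hist_X, t, threshold,
                            horizons = default_horizons(), future_X,
                            grid_step_days = DAYS_PER_MONTH,
                            n_samples = 500, seed = NULL) {
  stopifnot(max(horizons) > 0, grid_step_days > 0)
  if (!is.finite(threshold)) {
    stop_named("pexfair_param_error", "threshold (FIES baseline) must be defined")
  }
  n_grid <- ceiling(max(horizons) / grid_step_days - 1e-9)
  grid <- t + grid_step_days * seq_len(n_grid)
  Xf <- matrix(rep(as.numeric(future_X), each = n_grid), nrow = n_grid)
  colnames(Xf) <- colnames(hist_X)
  fc <- conditional_prediction(params, hist_t, hist_y, hist_X, grid, Xf,
                               include_noise = TRUE)
  samples <- with_seed(seed, forecast_samples(fc, n_samples))
  cummin_paths <- t(apply(samples, 1, cummin))
  if (n_grid == 1L) cummin_paths <- matrix(samples, ncol = 1L)
  out <- vapply(horizons, function(h) {
    k <- max(1L, min(n_grid, floor(h / grid_step_days + 1e-9)))
    mean(cummin_paths[, k] <= threshold)
  }, numeric(1))
  names(out) <- names(horizons) %||% as.character(horizons)
  out
}

#' Per-encounter exacerbation probabilities for a whole registry
#'
#' Applies [pex_probability()] at every encounter with a defined FIES
#' baseline, conditioning on the patient's full history up to and including
#' that encounter. Fixed-effect covariates are frozen at their value at the
#' prediction origin.
#'
#' @param reg A `cf_registry`.
#' @param labels FIES labels from [fies_label_registry()] (provides the
#'   per-encounter baseline).
#' @param params A `lung_params`.
#' @param fies A `fies_config` (defines the drop threshold semantics).
#' @param horizons Horizons in days.
#' @param n_samples,grid_step_days,seed Monte Carlo settings.
#' @return Data frame: `patient_id`, `t`, `horizon_days`, `pex_prob`,
#'   `baseline_pp`. Encounters without a defined baseline are skipped.
#' @export
predict_pex <- function(reg, labels, params, fies = fies_config(),
                        horizons = default_horizons(),
                        n_samples = 500, grid_step_days = DAYS_PER_MONTH,
                        seed = NULL) {
  stopifnot(inherits(reg, "cf_registry"), inherits(params, "lung_params"))
  ef <- encounter_frame(reg)
  ef <- ef[order(ef$patient_id, ef$t), , drop = FALSE]
  X <- lung_design_matrix(ef, params$formula)
  lab <- labels[order(labels$patient_id, labels$t), , drop = FALSE]
  if (!isTRUE(all.equal(lab$t, ef$t)) || !identical(lab$patient_id, ef$patient_id)) {
    stop_named("pexfair_param_error", "labels do not align with registry encounters")
  }
  idx_by_pat <- split(seq_len(nrow(ef)), ef$patient_id)
  res <- vector("list", length(idx_by_pat))
  k <- 0L
  with_seed(seed, {
    for (idx in idx_by_pat) {
      tt <- ef$t[idx]
      yy <- ef$fev1_pp[idx]
      Xi <- X[idx, , drop = FALSE]
      rows <- list()
      for (j in seq_along(idx)) {
        base <- lab$baseline_pp[idx[j]]
        if (is.na(base)) next
        thr <- fies_threshold(base, fies)
        p <- pex_probability(params, tt[1:j], yy[1:j], Xi[1:j, , drop = FALSE],
                             t = tt[j], threshold = thr, horizons = horizons,
                             future_X = Xi[j, ], grid_step_days = grid_step_days,
                             n_samples = n_samples, seed = NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = ef$patient_id[idx[j]], t = tt[j],
          horizon_days = unname(horizons), pex_prob = unname(p),
          baseline_pp = base, stringsAsFactors = FALSE)
      }
      k <- k + 1L
      res[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), t = numeric(),
                      horizon_days = numeric(), pex_prob = numeric(),
                      baseline_pp = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
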