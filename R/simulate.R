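# Synthetic registry generator. Emulates the longitudinal structure the
# audit assumes -- group-structured covariates, irregular visit times,
# serially correlated FEV1 trajectories, IV-antibiotic episodes -- without
# claiming to reproduce any real registry's marginals. Group-level
# differences (visit rates, covariate locations) are config entries whose
# defaults mirror published group summaries qualitatively.

#' Default race-conditional simulation structure
#'
#' @return Named list of the race-conditional default tables used by
#'   [sim_config()]: genotype probabilities, encounter rates, continuous
#'   covariate centers, and event probabilities.
#' @keywords internal
sim_defaults <- function() {
  list(
    genotype_probs_by_race = rbind(
      White = c(homozygous = 0.492, heterozygous = 0.367, neither_unknown = 0.141),
      Black = c(homozygous = 0.186, heterozygous = 0.411, neither_unknown = 0.403),
      Other = c(homozygous = 0.308, heterozygous = 0.375, neither_unknown = 0.317)
    ),
    encounter_rate_by_race = c(White = 5.25, Black = 4.95, Other = 5.30),
    covariate_means_by_race = rbind(
      # rows: race; centers are medians on the natural scale
      White = c(primary_road_density = 0.0015, secondary_road_density = 0.0030,
                deprivation_index = 0.335, greenspace_fraction = 0.828,
                distance_to_center = 60, drive_time_to_center = 50),
      Black = c(primary_road_density = 0.0025, secondary_road_density = 0.0050,
                deprivation_index = 0.404, greenspace_fraction = 0.707,
                distance_to_center = 30, drive_time_to_center = 30),
      Other = c(primary_road_density = 0.0020, secondary_road_density = 0.0040,
                deprivation_index = 0.364, greenspace_fraction = 0.723,
                distance_to_center = 50, drive_time_to_center = 45)
    ),
    covariate_event_probs_by_race = rbind(
      White = c(insurance_private = 0.516, smoker = 0.03, smoking_household = 0.025,
                secondhand_smoke = 0.057, female = 0.478, medicaid = 0.40,
                cfrd = 0.20, pa_positive = 0.50, mrsa_positive = 0.25),
      Black = c(insurance_private = 0.282, smoker = 0.03, smoking_household = 0.039,
                secondhand_smoke = 0.081, female = 0.485, medicaid = 0.65,
                cfrd = 0.20, pa_positive = 0.50, mrsa_positive = 0.25),
      Other = c(insurance_private = 0.370, smoker = 0.03, smoking_household = 0.047,
                secondhand_smoke = 0.064, female = 0.490, medicaid = 0.55,
                cfrd = 0.20, pa_positive = 0.50, mrsa_positive = 0.25)
    )
  )
}

#' Default generative parameters for the lung function model
#'
#' Intercept near normal lung function, mild decline with age, genotype and
#' insurance effects of a few percent-predicted points, between-patient
#' intercept SD of 10 points, slope SD of 0.004 points/day (about 1.5
#' points/year), an IBM scale giving a forecast SD of roughly half a point
#' at one year, and a visit-to-visit residual SD of 6 points (the level
#' needed for the rolling-baseline event rule to fire at roughly one
#' exacerbation encounter per patient-year at typical visit frequencies).
#'
#' @return A `lung_params`.
#' @export
default_true_params <- function() {
  beta <- c("(Intercept)" = 105, age = -0.8,
            f508delheterozygous = -2, f508delneither_unknown = -1,
            sexmale = 1, medicaidTRUE = -4)
  G <- matrix(c(100, -0.01, -0.01, 1.6e-5), 2, 2)
  model_params(beta, G, sigma_w2 = 2e-8, sigma_e2 = 36)
}

#' Simulation configuration
#'
#' Defines the cohort being emulated: group mix, race-conditional genotype
#' and covariate distributions, follow-up and visit-rate structure, the
#' generative lung function model, and the IV-episode rule. All group
#' contrasts live here, as data, not in code.
#'
#' @param n_patients Number of patients.
#' @param race_probs Probabilities over White/Black/Other.
#' @param ethnicity_probs Probabilities over Hispanic/NonHispanic/Unknown.
#' @param genotype_probs_by_race 3x3 matrix, rows = race, columns = F508del
#'   levels; rows sum to 1.
#' @param followup_years_mean Mean of the Gamma(shape 2) follow-up duration.
#' @param encounter_rate_by_race Visits per year by race (homogeneous
#'   Poisson process).
#' @param covariate_means_by_race Race x covariate matrix of natural-scale
#'   centers (medians) for the continuous place-based covariates.
#' @param covariate_event_probs_by_race Race x indicator matrix of event
#'   probabilities for boolean covariates.
#' @param log_scale_sd SD of the log/logit-scale spread of continuous
#'   covariates around their race-specific centers.
#' @param baseline_age_mean_excess Mean (years) of the exponential excess of
#'   baseline age over the 6-year cohort entry floor.
#' @param true_params A `lung_params` used as the generative model.
#' @param iv_trigger_pp Visits with FEV1 below this start an IV episode.
#' @param iv_duration_days Length of an IV episode.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200,
                       race_probs = c(White = 0.928, Black = 0.044, Other = 0.028),
                       ethnicity_probs = c(Hispanic = 0.077, NonHispanic = 0.887,
                                           Unknown = 0.036),
                       genotype_probs_by_race = sim_defaults()$genotype_probs_by_race,
                       followup_years_mean = 7.8,
                       encounter_rate_by_race = sim_defaults()$encounter_rate_by_race,
                       covariate_means_by_race = sim_defaults()$covariate_means_by_race,
                       covariate_event_probs_by_race = sim_defaults()$covariate_event_probs_by_race,
                       log_scale_sd = 0.5,
                       baseline_age_mean_excess = 7,
                       true_params = default_true_params(),
                       iv_trigger_pp = 65, iv_duration_days = 14,
                       seed = 1L) {
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop_named("pexfair_param_error", "%s must be a probability vector summing to 1", what)
    }
  }
  check_probs(race_probs, "race_probs")
  check_probs(ethnicity_probs, "ethnicity_probs")
  for (r in RACE_LEVELS) check_probs(genotype_probs_by_race[r, ],
                                     paste0("genotype_probs_by_race[", r, ",]"))
  stopifnot(n_patients > 0, followup_years_mean > 0,
            all(encounter_rate_by_race > 0), iv_duration_days >= 0,
            inherits(true_params, "lung_params"))
  structure(list(
    n_patients = as.integer(n_patients), race_probs = race_probs,
    ethnicity_probs = ethnicity_probs,
    genotype_probs_by_race = genotype_probs_by_race,
    followup_years_mean = followup_years_mean,
    encounter_rate_by_race = encounter_rate_by_race,
    covariate_means_by_race = covariate_means_by_race,
    covariate_event_probs_by_race = covariate_event_probs_by_race,
    log_scale_sd = log_scale_sd,
    baseline_age_mean_excess = baseline_age_mean_excess,
    true_params = true_params, iv_trigger_pp = iv_trigger_pp,
    iv_duration_days = iv_duration_days, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Fairness-gap injection specification
#'
#' A controlled departure from group exchangeability, used to verify the
#' audit can detect a performance gap it should detect (and stays quiet when
#' there is none).
#'
#' @param gap_mode `"none"`, `"noise_inflation"` (multiplies the target
#'   group's residual SD by `magnitude`), `"covariate_shift"` (adds
#'   `magnitude` to the log/logit-scale location of the target group's
#'   continuous covariates), or `"visit_sparsity"` (multiplies the target
#'   group's visit rate by `magnitude`).
#' @param target_group Race level the gap applies to.
#' @param magnitude Positive scalar.
#' @return An object of class `fairness_gap`.
#' @export
fairness_gap <- function(gap_mode = c("none", "noise_inflation", "covariate_shift",
                                      "visit_sparsity"),
                         target_group = "Black", magnitude = 1) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(target_group %in% RACE_LEVELS)
  if (gap_mode != "none" && !(is_number(magnitude) && magnitude > 0)) {
    stop_named("pexfair_param_error", "magnitude must be a positive scalar")
  }
  structure(list(gap_mode = gap_mode, target_group = target_group,
                 magnitude = magnitude), class = "fairness_gap")
}

draw_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic patient table
#'
#' Race, ethnicity, and genotype come from the configured categoricals;
#' continuous place-based covariates are log-normal (densities, distance,
#' drive time) or logit-normal (deprivation, greenspace) around
#' race-specific centers; boolean covariates are race-conditional Bernoulli.
#' Drive time is reported in 5-minute bins.
#'
#' @param config A `sim_config`.
#' @param gap A `fairness_gap`; `covariate_shift` is applied here.
#' @param n Number of patients (defaults to `config$n_patients`).
#' @return Data frame with the patient schema of [registry_schema()].
#' @export
generate_patients <- function(config, gap = fairness_gap("none"),
                              n = config$n_patients) {
  race <- draw_level(n, config$race_probs)
  ethnicity <- draw_level(n, config$ethnicity_probs)
  f508del <- character(n)
  for (r in RACE_LEVELS) {
    idx <- race == r
    if (any(idx)) f508del[idx] <- draw_level(sum(idx), config$genotype_probs_by_race[r, ])
  }
  ev <- config$covariate_event_probs_by_race
  p_of <- function(col) ev[race, col]
  sex <- ifelse(stats::runif(n) < p_of("female"), "female", "male")
  shift <- function(col) {
    s <- numeric(n)
    if (gap$gap_mode == "covariate_shift") s[race == gap$target_group] <- gap$magnitude
    s
  }
  cm <- config$covariate_means_by_race
  draw_lognormal <- function(col) {
    exp(log(cm[race, col]) + shift(col) + stats::rnorm(n, 0, config$log_scale_sd))
  }
  draw_logitnormal <- function(col) {
    stats::plogis(stats::qlogis(cm[race, col]) + shift(col) +
                    stats::rnorm(n, 0, config$log_scale_sd))
  }
  drive <- draw_lognormal("drive_time_to_center")
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    race = race, ethnicity = ethnicity, sex = sex, f508del = f508del,
    baseline_age = 6 + stats::rexp(n, 1 / config$baseline_age_mean_excess),
    insurance_private = stats::runif(n) < p_of("insurance_private"),
    smoker = stats::runif(n) < p_of("smoker"),
    smoking_household = stats::runif(n) < p_of("smoking_household"),
    secondhand_smoke = stats::runif(n) < p_of("secondhand_smoke"),
    primary_road_density = draw_lognormal("primary_road_density"),
    secondary_road_density = draw_lognormal("secondary_road_density"),
    deprivation_index = draw_logitnormal("deprivation_index"),
    greenspace_fraction = draw_logitnormal("greenspace_fraction"),
    distance_to_center = draw_lognormal("distance_to_center"),
    drive_time_to_center = 5 * ceiling(drive / 5),
    stringsAsFactors = FALSE
  )
}

#' Generate one patient's encounter times
#'
#' Follow-up duration is Gamma(shape 2) with the configured mean (right
#' skew with few near-zero follow-ups, matching registry-style follow-up
#' quartiles); visits beyond the mandatory first visit at t = 0 arrive as a
#' homogeneous Poisson process at the race-specific rate. At least one
#' encounter (t = 0) is always returned.
#'
#' @param patient One-row patient data frame (only `race` is used).
#' @param config A `sim_config`.
#' @param gap A `fairness_gap`; `visit_sparsity` thins the rate here.
#' @param followup_years Optional fixed follow-up; default drawn.
#' @return Increasing numeric vector of times in days, starting at 0.
#' @export
generate_encounter_times <- function(patient, config, gap = fairness_gap("none"),
                                     followup_years = NULL) {
  rate <- config$encounter_rate_by_race[[patient$race]]
  if (gap$gap_mode == "visit_sparsity" && patient$race == gap$target_group) {
    rate <- rate * gap$magnitude
  }
  if (is.null(followup_years)) {
    followup_years <- stats::rgamma(1, shape = 2, rate = 2 / config$followup_years_mean)
  }
  n_extra <- stats::rpois(1, rate * followup_years)
  extra <- sort(stats::runif(n_extra, 0, followup_years * DAYS_PER_YEAR))
  unique(c(0, extra))
}

#' Simulate an FEV1 trajectory
#'
#' Draws `X beta + b0 + b1 t + W(t) + e` with (b0, b1) ~ N(0, G), W
#' integrated Brownian motion, and iid measurement noise, then clips to
#' [1, 150] (clip events are counted in the `"n_clipped"` attribute, never
#' silent).
#'
#' @param patient One-row patient data frame.
#' @param times Increasing times in days.
#' @param params A `lung_params`.
#' @param medicaid Logical Medicaid flag(s) used in the design (recycled).
#' @param noise_scale Multiplier on the residual SD (noise-inflation gaps).
#' @return Numeric vector of FEV1 percent predicted values.
#' @export
simulate_fev1 <- function(patient, times, params, medicaid = FALSE,
                          noise_scale = 1) {
  if (is.unsorted(times)) stop_named("pexfair_param_error", "times must be increasing")
  n <- length(times)
  df <- data.frame(age = patient$baseline_age + times / DAYS_PER_YEAR,
                   f508del = patient$f508del, sex = patient$sex,
                   medicaid = rep_len(medicaid, n))
  X <- lung_design_matrix(df, params$formula)
  mu <- drop(X %*% params$beta)
  ev <- eigen(params$G, symmetric = TRUE)
  sqrtG <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  b <- drop(sqrtG %*% stats::rnorm(2))
  w <- numeric(n)
  if (params$sigma_w2 > 0) {
    K <- ibm_kernel_matrix(times, params$sigma_w2)
    pos <- times > 0
    if (any(pos)) {
      Kp <- K[pos, pos, drop = FALSE]
      R <- tryCatch(chol(Kp), error = function(e) chol(Kp + diag(1e-12 * max(diag(Kp)), nrow(Kp))))
      w[pos] <- drop(t(R) %*% stats::rnorm(sum(pos)))
    }
  }
  e <- stats::rnorm(n, 0, sqrt(params$sigma_e2) * noise_scale)
  y <- mu + b[1] + b[2] * times + w + e
  n_clip <- sum(y < 1 | y > 150)
  y <- pmin(pmax(y, 1), 150)
  attr(y, "n_clipped") <- n_clip
  y
}

#' Flag IV-antibiotic episodes from the FEV1 trace
#'
#' A visit with FEV1 below `iv_trigger_pp` starts an episode: subsequent
#' visits within `iv_duration_days` after it are flagged `on_iv`. The
#' triggering visit itself is not flagged.
#'
#' @param t Increasing visit times (days).
#' @param fev1_pp FEV1 values at those visits.
#' @param config A `sim_config` (uses `iv_trigger_pp`, `iv_duration_days`).
#' @return Logical vector of `on_iv` flags.
#' @export
simulate_iv_episodes <- function(t, fev1_pp, config) {
  n <- length(t)
  on_iv <- logical(n)
  if (config$iv_duration_days <= 0) return(on_iv)
  triggers <- t[fev1_pp < config$iv_trigger_pp]
  for (tr in triggers) {
    on_iv <- on_iv | (t > tr & t <= tr + config$iv_duration_days)
  }
  on_iv
}

#' Generate a complete synthetic registry
#'
#' Composes patient generation, visit-time generation, FEV1 simulation, and
#' IV-episode flagging into a validated `cf_registry`, deterministically
#' under `config$seed`. The number of clipped FEV1 values is attached as
#' attribute `"n_clipped"`.
#'
#' @param config A `sim_config`.
#' @param gap A `fairness_gap`.
#' @return A `cf_registry`.
#' @export
generate_registry <- function(config, gap = fairness_gap("none")) {
  stopifnot(inherits(config, "sim_config"), inherits(gap, "fairness_gap"))
  with_seed(config$seed, {
    patients <- generate_patients(config, gap)
    ev <- config$covariate_event_probs_by_race
    enc_list <- vector("list", nrow(patients))
    n_clipped <- 0L
    for (i in seq_len(nrow(patients))) {
      p <- patients[i, , drop = FALSE]
      tt <- generate_encounter_times(p, config, gap)
      medicaid <- stats::runif(1) < ev[p$race, "medicaid"]
      cfrd <- stats::runif(1) < ev[p$race, "cfrd"]
      pa <- stats::runif(1) < ev[p$race, "pa_positive"]
      mrsa <- stats::runif(1) < ev[p$race, "mrsa_positive"]
      noise_scale <- if (gap$gap_mode == "noise_inflation" &&
                         p$race == gap$target_group) gap$magnitude else 1
      y <- simulate_fev1(p, tt, config$true_params, medicaid = medicaid,
                         noise_scale = noise_scale)
      n_clipped <- n_clipped + attr(y, "n_clipped")
      enc_list[[i]] <- data.frame(
        patient_id = p$patient_id, t = tt,
        age = p$baseline_age + tt / DAYS_PER_YEAR,
        fev1_pp = as.numeric(y),
        on_iv = simulate_iv_episodes(tt, as.numeric(y), config),
        medicaid = medicaid, cfrd = cfrd, pa_positive = pa,
        mrsa_positive = mrsa, stringsAsFactors = FALSE)
    }
    reg <- registry(patients, do.call(rbind, enc_list))
    attr(reg, "n_clipped") <- n_clipped
    reg
  })
}
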