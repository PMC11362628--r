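# Fixtures built in code: tiny hand-checkable registries and random
# trajectory generators shared across test files.

patient_row <- function(patient_id = "P1", race = "White", ethnicity = "NonHispanic",
                        sex = "female", f508del = "homozygous", baseline_age = 10,
                        deprivation_index = 0.3, greenspace_fraction = 0.8) {
  data.frame(patient_id = patient_id, race = race, ethnicity = ethnicity,
             sex = sex, f508del = f508del, baseline_age = baseline_age,
             insurance_private = TRUE, smoker = FALSE, smoking_household = FALSE,
             secondhand_smoke = FALSE, primary_road_density = 0.002,
             secondary_road_density = 0.004, deprivation_index = deprivation_index,
             greenspace_fraction = greenspace_fraction, distance_to_center = 25,
             drive_time_to_center = 30, stringsAsFactors = FALSE)
}

encounter_rows <- function(patient_id, t, fev1_pp, on_iv = FALSE, age0 = 10,
                           medicaid = FALSE) {
  data.frame(patient_id = patient_id, t = t, age = age0 + t / 365.25,
             fev1_pp = fev1_pp, on_iv = rep_len(on_iv, length(t)),
             medicaid = rep_len(medicaid, length(t)), cfrd = FALSE,
             pa_positive = FALSE, mrsa_positive = FALSE, stringsAsFactors = FALSE)
}

two_patient_registry <- function() {
  patients <- rbind(patient_row("P1", race = "White"),
                    patient_row("P2", race = "Black", sex = "male",
                                f508del = "heterozygous"))
  encounters <- rbind(encounter_rows("P1", c(0, 60, 120), c(100, 98, 85)),
                      encounter_rows("P2", c(0, 90), c(80, 78)))
  registry(patients, encounters)
}

# Random one-patient encounter table for FIES property tests.
random_trajectory <- function(n_max = 50, p_iv = 0.15) {
  n <- sample(2:n_max, 1)
  t <- sort(sample(seq(0, 900, by = 1), n))
  encounter_rows("PX", t, fev1_pp = round(runif(n, 40, 120), 1),
                 on_iv = runif(n) < p_iv)
}

# From-scratch FIES reference labeler: at every encounter it rebuilds the
# candidate set by filtering the entire past against the window, IV, and
# exclusion rules using the labels assigned so far. Deliberately quadratic
# and structured unlike the one-pass implementation.
fies_label_bruteforce <- function(enc, config = fies_config()) {
  n <- nrow(enc)
  is_pex <- rep(NA, n)
  baseline <- rep(NA_real_, n)
  n_cand <- integer(n)
  in_excl <- logical(n)
  for (i in seq_len(n)) {
    pex_prior <- enc$t[which(is_pex[seq_len(i - 1L)] %in% TRUE)]
    in_excl[i] <- length(pex_prior) > 0 &&
      any(pex_prior < enc$t[i] & enc$t[i] - pex_prior <= config$exclusion_days)
    vals <- c()
    for (j in seq_len(i - 1L)) {
      if (enc$t[j] < enc$t[i] - config$lookback_days) next
      if (enc$on_iv[j]) next
      tainted <- FALSE
      for (tp in pex_prior) {
        if (tp <= enc$t[j] && enc$t[j] - tp <= config$exclusion_days) tainted <- TRUE
      }
      if (tainted) next
      vals <- c(vals, enc$fev1_pp[j])
    }
    if (in_excl[i] && config$exclusion_labeling == "unlabeled") next
    if (length(vals) >= 1) {
      vals <- sort(vals, decreasing = TRUE)
      baseline[i] <- mean(vals[seq_len(min(2, length(vals)))])
      n_cand[i] <- min(2L, length(vals))
      thr <- if (config$threshold_mode == "absolute_points") {
        baseline[i] - config$threshold_value
      } else {
        baseline[i] * (1 - config$threshold_value / 100)
      }
      is_pex[i] <- enc$fev1_pp[i] <= thr
    }
  }
  data.frame(t = enc$t, baseline_pp = baseline, baseline_n = n_cand,
             is_pex = is_pex, in_exclusion_window = in_excl)
}

expect_labels_match_bruteforce <- function(enc, config = fies_config()) {
  fast <- fies_label_patient(enc, config)
  slow <- fies_label_bruteforce(enc, config)
  expect_equal(fast$baseline_pp, slow$baseline_pp)
  expect_equal(fast$baseline_n, slow$baseline_n)
  expect_equal(fast$is_pex, slow$is_pex)
  expect_equal(fast$in_exclusion_window, slow$in_exclusion_window)
}

# Small scored-record fixture builder for ROC tests.
make_records <- function(scores, outcomes, race = "White", ethnicity = "NonHispanic") {
  data.frame(patient_id = sprintf("P%d", seq_along(scores)), t = 0,
             horizon = 365.25, score = scores, outcome = outcomes,
             race = rep_len(race, length(scores)),
             ethnicity = rep_len(ethnicity, length(scores)),
             stringsAsFactors = FALSE)
}
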