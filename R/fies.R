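# FEV1-indicated exacerbation signal (FIES): a rolling-baseline event
# definition. At each visit, the baseline is the mean of the two highest
# FEV1 values in the preceding 12 months taken while off IV antibiotics and
# outside the 28-day window after a previous exacerbation; a visit whose
# FEV1 sits 10 or more percent-predicted points below that baseline is an
# exacerbation (PEx).

#' FIES labeling configuration
#'
#' @param lookback_days Baseline window length; default 365.25 (12 months).
#' @param exclusion_days Measurements within this many days after a previous
#'   PEx are excluded from future baseline candidate sets; default 28.
#' @param threshold_mode `"absolute_points"` (default): a PEx is a drop of at
#'   least `threshold_value` percent-predicted points below baseline.
#'   `"relative_fraction"`: a drop to at or below
#'   `baseline * (1 - threshold_value/100)`.
#' @param threshold_value Size of the qualifying drop; default 10.
#' @param exclusion_labeling `"label"` (default): encounters inside the
#'   28-day exclusion window still receive a PEx label (and can start a new
#'   exclusion window); `"unlabeled"`: such encounters get an undefined
#'   label.
#' @return An object of class `fies_config`.
#' @export
fies_config <- function(lookback_days = DAYS_PER_YEAR, exclusion_days = 28,
                        threshold_mode = c("absolute_points", "relative_fraction"),
                        threshold_value = 10,
                        exclusion_labeling = c("label", "unlabeled")) {
  threshold_mode <- match.arg(threshold_mode)
  exclusion_labeling <- match.arg(exclusion_labeling)
  stopifnot(is_number(lookback_days), is_number(exclusion_days),
            is_number(threshold_value))
  if (!(lookback_days > exclusion_days && exclusion_days > 0)) {
    stop_named("pexfair_param_error", "need lookback_days > exclusion_days > 0")
  }
  if (threshold_value <= 0) stop_named("pexfair_param_error", "threshold_value must be > 0")
  structure(list(lookback_days = lookback_days, exclusion_days = exclusion_days,
                 threshold_mode = threshold_mode, threshold_value = threshold_value,
                 exclusion_labeling = exclusion_labeling),
            class = "fies_config")
}

# FEV1 level at or below which a visit qualifies as a PEx, given a baseline.
fies_threshold <- function(baseline_pp, config) {
  if (config$threshold_mode == "absolute_points") {
    baseline_pp - config$threshold_value
  } else {
    baseline_pp * (1 - config$threshold_value / 100)
  }
}

#' Rolling FIES baseline at one time point
#'
#' Candidate measurements are those with time in `[t - lookback_days, t)`,
#' taken off IV antibiotics, and not within `exclusion_days` after any prior
#' PEx (the PEx measurement itself is also excluded). The baseline is the
#' mean of the two largest candidate values; with exactly one candidate,
#' that value; with none, undefined.
#'
#' @param history Data frame of one patient's prior encounters with columns
#'   `t`, `fev1_pp`, `on_iv`; all times strictly before `t`.
#' @param t Evaluation time in days.
#' @param prior_pex_times Times of previously identified PEx events.
#' @param config A `fies_config`.
#' @return List with `baseline_pp` (NA if undefined) and `baseline_n` (0, 1,
#'   or 2 candidate measurements used).
#' @export
fies_baseline <- function(history, t, prior_pex_times = numeric(0),
                          config = fies_config()) {
  if (nrow(history) && is.unsorted(history$t, strictly = TRUE)) {
    stop_named("pexfair_param_error", "history must be sorted by strictly increasing t")
  }
  if (nrow(history) && any(history$t >= t)) {
    stop_named("pexfair_param_error", "history times must all be < t")
  }
  cand <- candidate_values(history, t, prior_pex_times, config)
  if (length(cand) == 0L) return(list(baseline_pp = NA_real_, baseline_n = 0L))
  top <- sort(cand, decreasing = TRUE)[seq_len(min(2L, length(cand)))]
  list(baseline_pp = mean(top), baseline_n = length(top))
}

candidate_values <- function(history, t, prior_pex_times, config) {
  if (!nrow(history)) return(numeric(0))
  in_window <- history$t >= t - config$lookback_days & history$t < t
  off_iv <- !history$on_iv
  # a measurement taken within exclusion_days at-or-after any prior PEx
  # (including at the PEx itself, lag 0) never re-enters a candidate set
  excluded <- vapply(history$t, function(s) {
    any(prior_pex_times <= s & s - prior_pex_times <= config$exclusion_days)
  }, logical(1))
  history$fev1_pp[in_window & off_iv & !excluded]
}

#' Label one patient's encounters with FIES
#'
#' A single chronological pass: at each encounter the baseline is computed
#' from the already-labeled past, the PEx indicator is set by comparing the
#' encounter's FEV1 with the baseline threshold, and newly identified PEx
#' events open an exclusion window affecting future baselines. Labels depend
#' only on the past, never the future.
#'
#' @param encounters One patient's encounters, sorted by `t`, with columns
#'   `patient_id`, `t`, `fev1_pp`, `on_iv`.
#' @param config A `fies_config`.
#' @return Data frame with one row per encounter: `patient_id`, `t`,
#'   `fev1_pp`, `baseline_pp` (NA when undefined), `baseline_n`, `is_pex`
#'   (NA when the baseline is undefined), `in_exclusion_window`.
#' @export
fies_label_patient <- function(encounters, config = fies_config()) {
  n <- nrow(encounters)
  if (is.unsorted(encounters$t, strictly = TRUE)) {
    stop_named("pexfair_param_error", "encounters must be sorted by strictly increasing t")
  }
  baseline_pp <- rep(NA_real_, n)
  baseline_n <- integer(n)
  is_pex <- rep(NA, n)
  in_excl <- logical(n)
  pex_times <- numeric(0)
  for (i in seq_len(n)) {
    t_i <- encounters$t[i]
    in_excl[i] <- any(pex_times < t_i & t_i - pex_times <= config$exclusion_days)
    hist_i <- encounters[seq_len(i - 1L), c("t", "fev1_pp", "on_iv"), drop = FALSE]
    b <- fies_baseline(hist_i, t_i, pex_times, config)
    baseline_pp[i] <- b$baseline_pp
    baseline_n[i] <- b$baseline_n
    if (in_excl[i] && config$exclusion_labeling == "unlabeled") {
      baseline_pp[i] <- NA_real_
      baseline_n[i] <- 0L
      next
    }
    if (!is.na(b$baseline_pp)) {
      is_pex[i] <- encounters$fev1_pp[i] <= fies_threshold(b$baseline_pp, config)
      if (isTRUE(is_pex[i])) pex_times <- c(pex_times, t_i)
    }
  }
  data.frame(patient_id = encounters$patient_id, t = encounters$t,
             fev1_pp = encounters$fev1_pp, baseline_pp = baseline_pp,
             baseline_n = baseline_n, is_pex = is_pex,
             in_exclusion_window = in_excl, stringsAsFactors = FALSE)
}

#' Label every patient in a registry with FIES
#'
#' @param reg A `cf_registry`.
#' @param config A `fies_config`.
#' @return Data frame of per-encounter labels, rows aligned with
#'   `reg$encounters`.
#' @export
fies_label_registry <- function(reg, config = fies_config()) {
  stopifnot(inherits(reg, "cf_registry"))
  enc <- reg$encounters
  parts <- lapply(split(enc, enc$patient_id), fies_label_patient, config = config)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Rapid lung function decline flag
#'
#' TRUE when the current FEV1 sits strictly more than `threshold_value`
#' percent-predicted points below the maximum FEV1 observed in the lookback
#' window; undefined (NA) when the window holds no measurements.
#'
#' @param history Prior encounters of one patient (`t`, `fev1_pp`).
#' @param t Evaluation time in days.
#' @param fev1_pp FEV1 percent predicted at time `t`.
#' @param config A `fies_config` (only `lookback_days` and `threshold_value`
#'   are used; the comparison is strict regardless of `threshold_mode`).
#' @return TRUE/FALSE, or NA when undefined.
#' @export
rapid_decline_flag <- function(history, t, fev1_pp, config = fies_config()) {
  if (nrow(history) && any(history$t >= t)) {
    stop_named("pexfair_param_error", "history times must all be < t")
  }
  in_window <- history$t >= t - config$lookback_days & history$t < t
  if (!any(in_window)) return(NA)
  fev1_pp < max(history$fev1_pp[in_window]) - config$threshold_value
}
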