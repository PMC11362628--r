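# Group-fairness audit of PEx predictions: pooled ROC and Youden-optimal
# cutoff, group-specific sensitivity/specificity at the shared (or
# group-specific) cutoff, and stratified bootstrap confidence intervals.
# Classification convention throughout: score >= cutoff predicts a PEx.

#' Assemble prediction records for ROC evaluation
#'
#' Pairs each predicted PEx probability with its realized outcome. Under
#' `"any_visit_in_horizon"` the outcome is TRUE when at least one labeled
#' encounter in `(t, t + horizon]` is a PEx, FALSE when the window holds
#' labeled encounters and none is a PEx; encounters whose window holds no
#' labeled visit have no confirmable outcome and are dropped (the count is
#' attached as attribute `"n_dropped"`). Under `"exact_date_only"` only the
#' single next labeled visit inside the window adjudicates the outcome.
#'
#' @param reg A `cf_registry` (provides race/ethnicity).
#' @param labels FIES labels from [fies_label_registry()].
#' @param probabilities Data frame from [predict_pex()].
#' @param horizon Horizon in days (> 0); selects the matching rows of
#'   `probabilities`.
#' @param outcome_mode `"any_visit_in_horizon"` (default) or
#'   `"exact_date_only"`.
#' @return Data frame with columns `patient_id`, `t`, `horizon`, `score`,
#'   `outcome`, `race`, `ethnicity`.
#' @export
build_records <- function(reg, labels, probabilities, horizon,
                          outcome_mode = c("any_visit_in_horizon", "exact_date_only")) {
  outcome_mode <- match.arg(outcome_mode)
  if (!is_number(horizon) || horizon <= 0) {
    stop_named("pexfair_param_error", "horizon must be a positive number of days")
  }
  probs <- probabilities[abs(probabilities$horizon_days - horizon) < 1e-6, , drop = FALSE]
  lab_by_pat <- split(labels[!is.na(labels$is_pex), c("t", "is_pex")],
                      labels$patient_id[!is.na(labels$is_pex)])
  pat <- reg$patients
  race <- stats::setNames(pat$race, pat$patient_id)
  ethnicity <- stats::setNames(pat$ethnicity, pat$patient_id)
  n <- nrow(probs)
  outcome <- rep(NA, n)
  for (i in seq_len(n)) {
    lb <- lab_by_pat[[probs$patient_id[i]]]
    if (is.null(lb)) next
    in_win <- lb$t > probs$t[i] & lb$t <= probs$t[i] + horizon
    if (!any(in_win)) next
    outcome[i] <- if (outcome_mode == "any_visit_in_horizon") {
      any(lb$is_pex[in_win])
    } else {
      lb$is_pex[which(in_win)[1L]]
    }
  }
  keep <- !is.na(outcome)
  out <- data.frame(patient_id = probs$patient_id[keep], t = probs$t[keep],
                    horizon = rep(horizon, sum(keep)), score = probs$pex_prob[keep],
                    outcome = outcome[keep],
                    race = unname(race[probs$patient_id[keep]]),
                    ethnicity = unname(ethnicity[probs$patient_id[keep]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

check_two_classes <- function(outcomes) {
  if (!any(outcomes)) stop_named("pexfair_roc_error", "no positive records")
  if (all(outcomes)) stop_named("pexfair_roc_error", "no negative records")
}

#' ROC curve points
#'
#' One operating point per distinct score (classification rule: score >=
#' threshold is positive), plus an `Inf` sentinel where nothing is called
#' positive. Tied scores collapse into a single threshold.
#'
#' @param scores Numeric prediction scores.
#' @param outcomes Logical outcomes; both classes must be present.
#' @return Data frame with `threshold`, `tpr`, `fpr`, ordered by decreasing
#'   threshold (so FPR is nondecreasing).
#' @export
roc_points <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  check_two_classes(outcomes)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  tpr <- vapply(thr, function(th) sum(outcomes & scores >= th) / n_pos, numeric(1))
  fpr <- vapply(thr, function(th) sum(!outcomes & scores >= th) / n_neg, numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; identical to the Mann-Whitney
#' statistic P(score+ > score-) + 0.5 P(tie).
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, outcomes) {
  check_two_classes(outcomes)
  # rank formulation: exact, O(n log n), ties counted half
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

trapezoid_auc <- function(roc) {
  # area under the (fpr, tpr) polyline; used to prove the rank identity
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Youden-optimal classification cutoff
#'
#' The threshold maximizing J = sensitivity + specificity - 1 over the
#' distinct observed scores; among ties the smallest maximizing threshold is
#' returned.
#'
#' @inheritParams roc_points
#' @return A cutoff probability.
#' @export
youden_cutoff <- function(scores, outcomes) {
  roc <- roc_points(scores, outcomes)
  roc <- roc[is.finite(roc$threshold), , drop = FALSE]
  j <- roc$tpr - roc$fpr
  best <- which(j >= max(j) - 1e-12)
  min(roc$threshold[best])
}

sens_spec <- function(scores, outcomes, cutoff) {
  pred <- scores >= cutoff
  c(sensitivity = sum(pred & outcomes) / sum(outcomes),
    specificity = sum(!pred & !outcomes) / sum(!outcomes))
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples positive and negative records separately with replacement
#' (strata = outcome classes), recomputes the metric per replicate, and
#' returns the percentile interval.
#'
#' @param scores,outcomes The records being resampled.
#' @param metric_fn Function of (scores, outcomes) returning a scalar.
#' @param B Number of replicates, default 2000.
#' @param level Confidence level, default 0.95.
#' @param seed Optional seed.
#' @return Numeric `c(lower, upper)` with the replicate values in attribute
#'   `"replicates"`.
#' @export
stratified_bootstrap_ci <- function(scores, outcomes, metric_fn, B = 2000,
                                    level = 0.95, seed = NULL) {
  stopifnot(B >= 1)
  pos <- which(outcomes)
  neg <- which(!outcomes)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    tryCatch(metric_fn(scores[i], outcomes[i]), error = function(e) NA_real_)
  }, numeric(1)))
  if (mean(is.na(reps)) > 0.5) {
    stop_named("pexfair_roc_error", "metric undefined in more than half of bootstrap replicates")
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  attr(ci, "replicates") <- reps
  ci
}

#' Group-specific ROC metrics at a cutoff
#'
#' Within each level of the grouping variable: AUC, and sensitivity and
#' specificity at either the shared overall cutoff or a per-group
#' Youden-optimal cutoff. Levels with a single outcome class are reported
#' with NA metrics and a warning rather than an error. When grouping by
#' ethnicity, `"Unknown"` is excluded.
#'
#' @param records Data frame from [build_records()].
#' @param cutoff Overall cutoff (used in `"shared"` mode).
#' @param group_by `"race"` or `"ethnicity"`.
#' @param cutoff_mode `"shared"` (default) or `"group_specific"`.
#' @param B,level,seed Bootstrap settings (B = 0 skips intervals).
#' @return Data frame, one row per group level.
#' @export
group_metrics <- function(records, cutoff, group_by = c("race", "ethnicity"),
                          cutoff_mode = c("shared", "group_specific"),
                          B = 2000, level = 0.95, seed = NULL) {
  group_by <- match.arg(group_by)
  cutoff_mode <- match.arg(cutoff_mode)
  levels_all <- if (group_by == "race") RACE_LEVELS else setdiff(ETHNICITY_LEVELS, "Unknown")
  levels_all <- intersect(levels_all, unique(records[[group_by]]))
  rows <- lapply(seq_along(levels_all), function(gi) {
    g <- levels_all[gi]
    rec <- records[records[[group_by]] == g, , drop = FALSE]
    row <- data.frame(group_by = group_by, group = g, n = nrow(rec),
                      n_pos = sum(rec$outcome),
                      auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                      sens = NA_real_, sens_lo = NA_real_, sens_hi = NA_real_,
                      spec = NA_real_, spec_lo = NA_real_, spec_hi = NA_real_,
                      cutoff = NA_real_, cutoff_mode = cutoff_mode,
                      auc_se = NA_real_, sens_se = NA_real_, spec_se = NA_real_,
                      stringsAsFactors = FALSE)
    if (!any(rec$outcome) || all(rec$outcome) || nrow(rec) == 0) {
      warning(sprintf("group %s has a single outcome class; metrics undefined", g),
              call. = FALSE)
      return(row)
    }
    cut_g <- if (cutoff_mode == "shared") cutoff else youden_cutoff(rec$score, rec$outcome)
    ss <- sens_spec(rec$score, rec$outcome, cut_g)
    row$auc <- roc_auc(rec$score, rec$outcome)
    row$sens <- ss[["sensitivity"]]
    row$spec <- ss[["specificity"]]
    row$cutoff <- cut_g
    if (B > 0) {
      seed_g <- if (is.null(seed)) NULL else seed + gi
      ci_auc <- stratified_bootstrap_ci(rec$score, rec$outcome, roc_auc,
                                        B = B, level = level, seed = seed_g)
      ci_sens <- stratified_bootstrap_ci(
        rec$score, rec$outcome,
        function(s, o) sens_spec(s, o, cut_g)[["sensitivity"]],
        B = B, level = level, seed = if (is.null(seed_g)) NULL else seed_g + 7919)
      ci_spec <- stratified_bootstrap_ci(
        rec$score, rec$outcome,
        function(s, o) sens_spec(s, o, cut_g)[["specificity"]],
        B = B, level = level, seed = if (is.null(seed_g)) NULL else seed_g + 15817)
      row[c("auc_lo", "auc_hi")] <- ci_auc
      row[c("sens_lo", "sens_hi")] <- ci_sens
      row[c("spec_lo", "spec_hi")] <- ci_spec
      row$auc_se <- stats::sd(attr(ci_auc, "replicates"), na.rm = TRUE)
      row$sens_se <- stats::sd(attr(ci_sens, "replicates"), na.rm = TRUE)
      row$spec_se <- stats::sd(attr(ci_spec, "replicates"), na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full group-fairness report
#'
#' For every horizon: builds prediction records, finds the pooled
#' Youden-optimal cutoff, and reports overall and group-specific AUC,
#' sensitivity, and specificity with stratified bootstrap confidence
#' intervals.
#'
#' @param reg A `cf_registry`.
#' @param labels FIES labels.
#' @param probabilities Output of [predict_pex()].
#' @param horizons Horizons in days.
#' @param group_by Grouping variables to audit (any of "race", "ethnicity").
#' @param cutoff_mode `"shared"` or `"group_specific"`.
#' @param outcome_mode Passed to [build_records()].
#' @param B,level,seed Bootstrap settings.
#' @return Data frame with one row per horizon x group (plus an "Overall"
#'   row per horizon), columns as in [group_metrics()] plus `horizon_days`,
#'   `outcome_mode`, and `n_dropped`.
#' @export
fairness_report <- function(reg, labels, probabilities,
                            horizons = default_horizons(),
                            group_by = c("race", "ethnicity"),
                            cutoff_mode = "shared",
                            outcome_mode = "any_visit_in_horizon",
                            B = 2000, level = 0.95, seed = NULL) {
  out <- list()
  for (h in horizons) {
    records <- build_records(reg, labels, probabilities, h, outcome_mode)
    check_two_classes(records$outcome)
    cutoff <- youden_cutoff(records$score, records$outcome)
    ss <- sens_spec(records$score, records$outcome, cutoff)
    seed_h <- if (is.null(seed)) NULL else stage_seed(seed, sprintf("h%.3f", h))
    ci_auc <- stratified_bootstrap_ci(records$score, records$outcome, roc_auc,
                                      B = max(B, 1), level = level, seed = seed_h)
    overall <- data.frame(
      group_by = "overall", group = "Overall", n = nrow(records),
      n_pos = sum(records$outcome),
      auc = roc_auc(records$score, records$outcome),
      auc_lo = ci_auc[1], auc_hi = ci_auc[2],
      sens = ss[["sensitivity"]], sens_lo = NA_real_, sens_hi = NA_real_,
      spec = ss[["specificity"]], spec_lo = NA_real_, spec_hi = NA_real_,
      cutoff = cutoff, cutoff_mode = cutoff_mode,
      auc_se = stats::sd(attr(ci_auc, "replicates")),
      sens_se = NA_real_, spec_se = NA_real_, stringsAsFactors = FALSE)
    tabs <- lapply(group_by, function(gb) {
      group_metrics(records, cutoff, group_by = gb, cutoff_mode = cutoff_mode,
                    B = B, level = level,
                    seed = if (is.null(seed_h)) NULL else seed_h + string_hash(gb) %% 10000)
    })
    tab <- rbind(overall, do.call(rbind, tabs))
    tab$horizon_days <- h
    tab$outcome_mode <- outcome_mode
    tab$n_dropped <- attr(records, "n_dropped")
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot a fairness report
#'
#' Dot-and-interval panels of group-specific AUC, sensitivity, and
#' specificity by prediction horizon, with the overall value as a reference
#' line.
#'
#' @param report Output of [fairness_report()].
#' @param metric One of "auc", "sens", "spec".
#' @return A ggplot object.
#' @export
plot_fairness_report <- function(report, metric = c("auc", "sens", "spec")) {
  metric <- match.arg(metric)
  lo <- paste0(metric, "_lo")
  hi <- paste0(metric, "_hi")
  grp <- report[report$group_by != "overall", , drop = FALSE]
  ovr <- report[report$group_by == "overall", , drop = FALSE]
  grp$horizon_months <- factor(round(grp$horizon_days / DAYS_PER_MONTH))
  ovr$horizon_months <- factor(round(ovr$horizon_days / DAYS_PER_MONTH))
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_hline(data = ovr, ggplot2::aes(yintercept = .data[[metric]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]],
                                          colour = .data$group_by)) +
    ggplot2::facet_wrap(~horizon_months, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = toupper(metric), colour = NULL) +
    ggplot2::theme_minimal()
}
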