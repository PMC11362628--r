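# Predictor-by-group screening: per-group counts, means/proportions with
# 95% confidence intervals, association tests, and encounter-rate
# statistics -- the machinery behind "which predictors correlate with race".

CONTINUOUS_PREDICTORS <- c(
  "baseline_age", "primary_road_density", "secondary_road_density",
  "deprivation_index", "greenspace_fraction", "distance_to_center",
  "drive_time_to_center"
)
BOOLEAN_PREDICTORS <- PATIENT_BOOL_COLS
CATEGORICAL_PREDICTORS <- c("sex", "f508del", "ethnicity")

# Wilson score interval for a binomial proportion (no continuity
# correction); behaves sensibly at 0/n and n/n.
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = center - half, upper = center + half)
}

t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(lower = NA_real_, upper = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(lower = m - half, upper = m + half)
}

#' Per-group summary of one predictor
#'
#' Boolean predictors get per-group proportions with Wilson 95% intervals;
#' continuous predictors get per-group means with t-based 95% intervals.
#'
#' @param reg A `cf_registry`.
#' @param predictor Name of a patient-table predictor.
#' @param group_by Grouping variable, default `"race"`.
#' @param level Confidence level.
#' @return Data frame: `predictor`, `group`, `n`, `estimate` (mean or
#'   proportion), `lower`, `upper`, `type`.
#' @export
summarize_predictor <- function(reg, predictor, group_by = "race", level = 0.95) {
  stopifnot(inherits(reg, "cf_registry"))
  valid <- c(CONTINUOUS_PREDICTORS, BOOLEAN_PREDICTORS)
  if (!predictor %in% valid) {
    stop_named("pexfair_param_error", "unknown predictor '%s'; valid: %s",
               predictor, paste(valid, collapse = ", "))
  }
  pat <- reg$patients
  groups <- split(pat[[predictor]], pat[[group_by]])
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (predictor %in% BOOLEAN_PREDICTORS) {
      ci <- wilson_ci(sum(x), length(x), level)
      data.frame(predictor = predictor, group = g, n = length(x),
                 estimate = mean(x), lower = ci[["lower"]], upper = ci[["upper"]],
                 type = "proportion", stringsAsFactors = FALSE)
    } else {
      ci <- t_ci(x, level)
      data.frame(predictor = predictor, group = g, n = length(x),
                 estimate = mean(x), lower = ci[["lower"]], upper = ci[["upper"]],
                 type = "mean", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test a predictor's association with group membership
#'
#' Boolean/categorical predictors: Pearson chi-square test of independence
#' (no continuity correction) on the level-by-group contingency table.
#' Continuous predictors: classic one-way ANOVA F test across groups.
#'
#' @param reg A `cf_registry`.
#' @param predictor Predictor name (boolean, categorical, or continuous).
#' @param group_by Grouping variable, default `"race"`.
#' @return List with `statistic`, `p_value`, `df`, `method`.
#' @export
test_association <- function(reg, predictor, group_by = "race") {
  stopifnot(inherits(reg, "cf_registry"))
  pat <- reg$patients
  valid <- c(CONTINUOUS_PREDICTORS, BOOLEAN_PREDICTORS, CATEGORICAL_PREDICTORS)
  if (!predictor %in% valid) {
    stop_named("pexfair_param_error", "unknown predictor '%s'; valid: %s",
               predictor, paste(valid, collapse = ", "))
  }
  if (predictor %in% CONTINUOUS_PREDICTORS) {
    x <- pat[[predictor]]
    g <- factor(pat[[group_by]])
    # the F test needs at least two observations per compared group
    big <- names(which(table(g) >= 2))
    if (length(big) < nlevels(droplevels(g))) {
      warning(sprintf("dropping group(s) with fewer than 2 patients from the %s F test",
                      predictor), call. = FALSE)
      keep <- g %in% big
      x <- x[keep]
      g <- droplevels(g[keep])
    }
    if (nlevels(droplevels(g)) < 2) {
      return(list(statistic = NA_real_, p_value = NA_real_, df = c(NA, NA),
                  method = "one-way ANOVA F test (insufficient groups)"))
    }
    k <- nlevels(droplevels(g))
    df_pars <- c(k - 1, length(x) - k)
    # a between-group sum of squares of zero is F = 0, p = 1 (oneway.test
    # errors on essentially-constant data)
    ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2),
                      na.rm = TRUE)
    if (ss_between < 1e-12 * max(1, stats::var(x))) {
      return(list(statistic = 0, p_value = 1, df = df_pars,
                  method = "one-way ANOVA F test"))
    }
    fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
         df = unname(fit$parameter), method = "one-way ANOVA F test")
  } else {
    tab <- table(pat[[predictor]], pat[[group_by]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      stop_named("pexfair_param_error",
                 "zero expected cell count for '%s'; collapse sparse levels", predictor)
    }
    fit <- stats::chisq.test(tab, correct = FALSE)
    list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
         df = unname(fit$parameter), method = "Pearson chi-square test")
  }
}

#' Per-group encounter-rate statistics
#'
#' Per patient: encounters per year of follow-up (follow-up = last minus
#' first encounter time, floored at 1 day), plus PEx and non-PEx encounter
#' rates when labels are supplied. Per group: the mean over patients with a
#' t-based 95% interval.
#'
#' @param reg A `cf_registry`.
#' @param labels Optional FIES labels (enables the PEx/non-PEx split).
#' @param group_by Grouping variable, default `"race"`.
#' @param level Confidence level.
#' @return Data frame: `group`, `measure`, `n_patients`, `mean`, `lower`,
#'   `upper`.
#' @export
encounter_rates <- function(reg, labels = NULL, group_by = "race", level = 0.95) {
  stopifnot(inherits(reg, "cf_registry"))
  enc <- reg$encounters
  per_pat <- do.call(rbind, lapply(split(enc, enc$patient_id), function(e) {
    fu_years <- max(max(e$t) - min(e$t), 1) / DAYS_PER_YEAR
    data.frame(patient_id = e$patient_id[1], followup_years = fu_years,
               encounters_per_year = nrow(e) / fu_years,
               total_encounters = nrow(e), stringsAsFactors = FALSE)
  }))
  if (!is.null(labels)) {
    pex_counts <- tapply(labels$is_pex, labels$patient_id, function(x) sum(x, na.rm = TRUE))
    nonpex_counts <- tapply(labels$is_pex, labels$patient_id,
                            function(x) sum(!x, na.rm = TRUE))
    per_pat$pex_per_year <- as.numeric(pex_counts[per_pat$patient_id]) / per_pat$followup_years
    per_pat$nonpex_per_year <- as.numeric(nonpex_counts[per_pat$patient_id]) / per_pat$followup_years
  }
  per_pat$group <- reg$patients[[group_by]][match(per_pat$patient_id,
                                                  reg$patients$patient_id)]
  measures <- setdiff(names(per_pat), c("patient_id", "group", "followup_years"))
  rows <- list()
  for (g in unique(per_pat$group)) {
    sub <- per_pat[per_pat$group == g, , drop = FALSE]
    for (m in measures) {
      ci <- t_ci(sub[[m]], level)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, measure = m, n_patients = nrow(sub), mean = mean(sub[[m]]),
        lower = ci[["lower"]], upper = ci[["upper"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype composition within each racial group
#'
#' Counts and within-race percentages of F508del genotype, rounded half-up
#' to one decimal.
#'
#' @param reg A `cf_registry`.
#' @return Data frame: `race`, `f508del`, `n`, `pct` (percent of that race).
#' @export
genotype_by_race <- function(reg) {
  stopifnot(inherits(reg, "cf_registry"))
  pat <- reg$patients
  tab <- table(factor(pat$race, RACE_LEVELS), factor(pat$f508del, F508_LEVELS))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("race", "f508del", "n")
  totals <- rowSums(tab)
  out$pct <- round_half_up(100 * out$n / totals[out$race], 1)
  out <- out[order(match(out$race, RACE_LEVELS), match(out$f508del, F508_LEVELS)), ]
  rownames(out) <- NULL
  out
}

#' Screen every predictor for association with a grouping variable
#'
#' Runs [summarize_predictor()] and [test_association()] over the standard
#' predictor list; p-values are unadjusted.
#'
#' @param reg A `cf_registry`.
#' @param group_by Grouping variable, default `"race"`.
#' @return Data frame of per-group summaries with the predictor-level
#'   association p-value repeated on each row.
#' @export
screening_table <- function(reg, group_by = "race") {
  preds <- c(BOOLEAN_PREDICTORS, CONTINUOUS_PREDICTORS)
  rows <- lapply(preds, function(p) {
    s <- summarize_predictor(reg, p, group_by)
    tst <- test_association(reg, p, group_by)
    s$p_value <- tst$p_value
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
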