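# Registry container: patients + encounters, validation, CSV I/O, and
# cohort composition summaries.

PATIENT_COLS <- c(
  "patient_id", "race", "ethnicity", "sex", "f508del", "baseline_age",
  "insurance_private", "smoker", "smoking_household", "secondhand_smoke",
  "primary_road_density", "secondary_road_density", "deprivation_index",
  "greenspace_fraction", "distance_to_center", "drive_time_to_center"
)

ENCOUNTER_COLS <- c(
  "patient_id", "t", "age", "fev1_pp", "on_iv", "medicaid", "cfrd",
  "pa_positive", "mrsa_positive"
)

PATIENT_BOOL_COLS <- c(
  "insurance_private", "smoker", "smoking_household", "secondhand_smoke"
)
ENCOUNTER_BOOL_COLS <- c("on_iv", "medicaid", "cfrd", "pa_positive", "mrsa_positive")

#' Construct and validate a patient registry
#'
#' Bundles a patient table (one row per patient: demographics, F508del
#' genotype, and place-based covariates) with an encounter table (one row per
#' clinical visit: time in days since the patient's first visit, FEV1 percent
#' predicted, IV-antibiotic flag, and time-varying covariates) and enforces
#' the structural invariants the downstream analysis assumes: valid
#' categorical levels, ages of at least 6 years, covariates within their
#' physical ranges, strictly increasing visit times within each patient, and
#' referential integrity between the two tables.
#'
#' @param patients Data frame with columns `patient_id`, `race`, `ethnicity`,
#'   `sex`, `f508del`, `baseline_age`, four smoking/insurance indicator
#'   columns, and six place-based covariates. See `registry_schema()`.
#' @param encounters Data frame with columns `patient_id`, `t` (days since
#'   first encounter), `age` (years), `fev1_pp` (FEV1 percent predicted, in
#'   (0, 150]), `on_iv`, `medicaid`, `cfrd`, `pa_positive`, `mrsa_positive`.
#' @return An object of class `cf_registry`: a list with elements `patients`
#'   and `encounters`, the latter sorted by (`patient_id`, `t`).
#' @export
registry <- function(patients, encounters) {
  patients <- as.data.frame(patients)
  encounters <- as.data.frame(encounters)
  check_columns(patients, PATIENT_COLS, "patients")
  check_columns(encounters, ENCOUNTER_COLS, "encounters")
  patients$patient_id <- as.character(patients$patient_id)
  encounters$patient_id <- as.character(encounters$patient_id)
  for (col in PATIENT_BOOL_COLS) patients[[col]] <- as_bool(patients[[col]], col)
  for (col in ENCOUNTER_BOOL_COLS) encounters[[col]] <- as_bool(encounters[[col]], col)

  validate_levels(patients$race, RACE_LEVELS, "race")
  validate_levels(patients$ethnicity, ETHNICITY_LEVELS, "ethnicity")
  validate_levels(patients$sex, SEX_LEVELS, "sex")
  validate_levels(patients$f508del, F508_LEVELS, "f508del")

  if (anyDuplicated(patients$patient_id)) {
    stop_named("pexfair_validation_error", "duplicated patient_id in patient table: %s",
               paste(unique(patients$patient_id[duplicated(patients$patient_id)]), collapse = ", "))
  }
  validate_range(patients$baseline_age, 6, Inf, "baseline_age", lower_closed = TRUE)
  for (col in c("primary_road_density", "secondary_road_density",
                "distance_to_center", "drive_time_to_center")) {
    validate_range(patients[[col]], 0, Inf, col, lower_closed = TRUE)
  }
  for (col in c("deprivation_index", "greenspace_fraction")) {
    validate_range(patients[[col]], 0, 1, col, lower_closed = TRUE, upper_closed = TRUE)
  }
  validate_range(encounters$t, 0, Inf, "t", lower_closed = TRUE)
  validate_range(encounters$fev1_pp, 0, 150, "fev1_pp",
                 lower_closed = FALSE, upper_closed = TRUE)

  orphan <- setdiff(encounters$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop_named("pexfair_integrity_error",
               "encounters reference unknown patient id(s): %s",
               paste(sort(orphan), collapse = ", "))
  }
  childless <- setdiff(patients$patient_id, encounters$patient_id)
  if (length(childless)) {
    stop_named("pexfair_integrity_error",
               "patient(s) with no encounters: %s",
               paste(sort(childless), collapse = ", "))
  }

  ord <- order(encounters$patient_id, encounters$t)
  encounters <- encounters[ord, , drop = FALSE]
  rownames(encounters) <- NULL
  rownames(patients) <- NULL
  for (pid in unique(encounters$patient_id)) {
    tt <- encounters$t[encounters$patient_id == pid]
    if (anyDuplicated(tt) || is.unsorted(tt, strictly = TRUE)) {
      stop_named("pexfair_validation_error",
                 "encounter times are not strictly increasing for patient %s", pid)
    }
  }

  structure(list(patients = patients, encounters = encounters),
            class = "cf_registry")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_named("pexfair_schema_error", "%s table is missing column(s): %s",
               what, paste(missing, collapse = ", "))
  }
}

as_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop_named("pexfair_schema_error", "column %s is not boolean (logical or 0/1)", col)
}

validate_levels <- function(x, levels, col) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad)) {
    stop_named("pexfair_validation_error", "column %s has invalid level(s): %s (valid: %s)",
               col, paste(bad, collapse = ", "), paste(levels, collapse = ", "))
  }
}

validate_range <- function(x, lo, hi, col, lower_closed = TRUE, upper_closed = TRUE) {
  if (anyNA(x)) stop_named("pexfair_validation_error", "column %s contains missing values", col)
  ok_lo <- if (lower_closed) x >= lo else x > lo
  ok_hi <- if (upper_closed) x <= hi else x < hi
  if (!all(ok_lo & ok_hi)) {
    stop_named("pexfair_validation_error", "column %s out of range %s%g, %g%s",
               col, if (lower_closed) "[" else "(", lo, hi, if (upper_closed) "]" else ")")
  }
}

#' @export
print.cf_registry <- function(x, ...) {
  cat(sprintf("<cf_registry> %d patients, %d encounters\n",
              nrow(x$patients), nrow(x$encounters)))
  tab <- table(x$patients$race)
  cat("  race:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Registry CSV schema
#'
#' @return List with character vectors `patients` and `encounters`, the exact
#'   column names of the two CSV files. Booleans are serialized as 0/1,
#'   missing values as empty strings, and files are comma-separated UTF-8
#'   with a header row.
#' @export
registry_schema <- function() {
  list(patients = PATIENT_COLS, encounters = ENCOUNTER_COLS)
}

#' Read a registry from patients/encounters CSV files
#'
#' @param patients_path Path to the patients CSV.
#' @param encounters_path Path to the encounters CSV.
#' @return A validated `cf_registry` with encounters sorted by
#'   (`patient_id`, `t`).
#' @export
read_registry <- function(patients_path, encounters_path) {
  for (p in c(patients_path, encounters_path)) {
    if (!file.exists(p)) stop_named("pexfair_io_error", "file does not exist: %s", p)
  }
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  encounters <- utils::read.csv(encounters_path, stringsAsFactors = FALSE,
                                colClasses = c(patient_id = "character"))
  registry(patients, encounters)
}

#' Write a registry to patients.csv and encounters.csv
#'
#' Inverse of `read_registry()`: the written files read back to a registry
#' equal to the input (exactly for categorical and boolean fields, to
#' 15 significant digits for numeric fields).
#'
#' @param reg A `cf_registry`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_registry <- function(reg, out_dir) {
  stopifnot(inherits(reg, "cf_registry"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  patients <- reg$patients
  encounters <- reg$encounters
  for (col in PATIENT_BOOL_COLS) patients[[col]] <- as.integer(patients[[col]])
  for (col in ENCOUNTER_BOOL_COLS) encounters[[col]] <- as.integer(encounters[[col]])
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             encounters = file.path(out_dir, "encounters.csv"))
  utils::write.csv(patients, paths[["patients"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(encounters, paths[["encounters"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Cohort composition summary
#'
#' Counts and percentages of the cohort by race, ethnicity, and F508del
#' genotype, the composition table reported for registry cohorts.
#' Percentages are 100 * count / total, rounded half-up to one decimal, so a
#' full partition sums to 100 within rounding slack.
#'
#' @param reg A `cf_registry`.
#' @param variables Patient columns to tabulate.
#' @return Data frame with columns `variable`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(reg, variables = c("race", "ethnicity", "f508del")) {
  stopifnot(inherits(reg, "cf_registry"))
  n_total <- nrow(reg$patients)
  if (n_total == 0L) stop_named("pexfair_validation_error", "registry has no patients")
  level_sets <- list(race = RACE_LEVELS, ethnicity = ETHNICITY_LEVELS,
                     sex = SEX_LEVELS, f508del = F508_LEVELS)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(reg$patients)) {
      stop_named("pexfair_schema_error", "unknown patient variable: %s", v)
    }
    lev <- level_sets[[v]] %||% sort(unique(as.character(reg$patients[[v]])))
    counts <- table(factor(reg$patients[[v]], levels = lev))
    data.frame(variable = v, level = lev, n = as.integer(counts),
               pct = round_half_up(100 * as.integer(counts) / n_total, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
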