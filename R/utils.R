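# Shared constants and small helpers.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

RACE_LEVELS <- c("White", "Black", "Other")
ETHNICITY_LEVELS <- c("Hispanic", "NonHispanic", "Unknown")
SEX_LEVELS <- c("female", "male")
F508_LEVELS <- c("homozygous", "heterozygous", "neither_unknown")

#' Default prediction horizons
#'
#' The 3-, 6-, and 12-month horizons used throughout the audit, expressed in
#' days under the package's calendar convention (1 month = 30.4375 days).
#'
#' @return Named numeric vector of horizon lengths in days.
#' @export
default_horizons <- function() {
  c("3" = 3 * DAYS_PER_MONTH, "6" = 6 * DAYS_PER_MONTH, "12" = 12 * DAYS_PER_MONTH)
}

# Round half away from zero (presentation rounding for percentages); base
# round() rounds half to even, which does not match printed summary tables.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stable 31-adic string hash into [0, 2^31 - 2]; used to derive per-stage
# seeds from a master seed so no two pipeline stages share a stream.
string_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a stage seed from a master seed
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed, distinct across stage names.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((as.numeric(master_seed) %% 2147483647 + string_hash(stage)) %% 2147483647)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_named <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "pexfair_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
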