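## Shared constants and small helpers.
##
## All window arithmetic is done on integer days (R Date is days since
## 1970-01-01), with half-open intervals [start, end) throughout.

## exposure-window day conventions: 3 months = 91 days, 12 months = 365 days
CURRENT_WINDOW_DAYS <- 91L
RECENT_WINDOW_DAYS  <- 365L
## where "month" arithmetic is needed (not window cut points)
DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR  <- 365.25
## comedication lookback: prescribing in the ~6 months before
COMED_LOOKBACK_DAYS <- 183L

#' Drug classes and outcomes known to the pipeline
#'
#' @return Character vector of antidiabetic drug-class labels
#'   (`drug_classes()`) or outcome labels (`study_outcomes()`); `"death"` is
#'   carried on the patient table, the other outcomes as clinical events.
#' @export
drug_classes <- function() {
  c("metformin", "sulphonylurea", "rosiglitazone", "pioglitazone",
    "insulin", "other_oad")
}

#' @rdname drug_classes
#' @export
study_outcomes <- function() {
  c("death", "acs", "stroke", "heart_failure")
}

## thiazolidinedione members, used for class-level contrasts
tzd_classes <- function() c("rosiglitazone", "pioglitazone")

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

## Age at a date from birth year, assuming mid-year (July 1) birthdays:
## anonymised records carry birth year only.
age_at <- function(birth_year, date) {
  dob <- as.Date(sprintf("%d-07-01", birth_year))
  floor(as.numeric(as_date(date) - dob) / DAYS_PER_YEAR)
}

## Age bands used across reports and adjustment sets; the 50-64 band lets
## the <65 / >=65 stratification nest exactly.
AGE_BAND_BREAKS <- c(40, 50, 65, 75, 85, Inf)
AGE_BAND_LABELS <- c("40-49", "50-64", "65-74", "75-84", "85+")

age_band_of <- function(age) {
  age <- pmax(age, 40)
  cut(age, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS,
      right = FALSE)
}

## Dates (Date) on which a patient's age band changes, within [from, to).
## Band changes happen on July 1 of the year the patient turns 50/65/75/85.
age_band_change_dates <- function(birth_year, from, to) {
  cuts <- AGE_BAND_BREAKS[is.finite(AGE_BAND_BREAKS)][-1]  # 50, 65, 75, 85
  d <- as.Date(sprintf("%d-07-01", birth_year + cuts))
  d[d >= from & d < to]
}

year_of <- function(date) as.integer(format(as_date(date), "%Y"))

## Deterministic sub-seeds for the generator stages; keep below 2^31.
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7L + k * 104729) %% 2147483647
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
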