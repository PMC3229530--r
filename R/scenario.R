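#' Scenario configuration for the synthetic EHR generator
#'
#' Defines a complete simulation scenario: population size and structure,
#' calendar span, per-class prescribing dynamics (baseline initiation
#' hazards with calendar-time multipliers, repeat-prescription cycle,
#' discontinuation), channeling of sicker patients towards insulin and
#' sulphonylureas, outcome hazards with age/sex/severity terms and true
#' per-(class, outcome) rate ratios during current use, the cause-of-death
#' mix, and the partial hospital/death-certificate linkage structure.
#'
#' The defaults emulate a UK primary-care population of type-2 diabetic
#' adults aged 40+ observed 1999--2009: rosiglitazone initiation collapses
#' after 2007 while pioglitazone rises, insulin is channelled to sicker
#' patients, about 40% of practices are linked to hospital data (available
#' from April 1997) and death certificates (from January 2001), and current
#' rosiglitazone use carries a true death rate ratio of 1.2 and heart
#' failure rate ratio of 1.7 versus baseline.
#'
#' @param n_patients,n_practices Population size and number of practices.
#' @param calendar_start,calendar_end Date range of data collection.
#' @param age_mean,age_sd Age distribution at start of follow-up, truncated
#'   to 40--95 years.
#' @param sex_male Proportion male.
#' @param class_initiation_rates Named list, one per drug class:
#'   `list(base = <hazard per person-year>, multipliers = c("2007" = ...))`,
#'   multipliers defaulting to 1 for unlisted years.
#' @param channeling_strength Log-hazard coefficient coupling latent
#'   severity to initiation of the channelled classes.
#' @param channelled_classes Classes whose initiation responds to severity.
#' @param true_log_rr Named numeric, names `"<class>:<outcome>"`; log rate
#'   ratio while current on the class.
#' @param recent_past_log_rr Same shape; effect during recent/past use
#'   (post-discontinuation), default none (0).
#' @param outcome_baseline_hazards Named list per outcome:
#'   `c(base = <hazard/person-year at age 65>, log_hr_age10 = ...,
#'   log_hr_male = ..., log_hr_severity = ...)`.
#' @param prescription_cycle Mean days between repeat prescriptions while
#'   the patient persists on a class.
#' @param persistence Named per-class discontinuation hazard (per
#'   person-year).
#' @param multi_constituent_prob Probability that a thiazolidinedione
#'   prescription is a fixed-dose combination with metformin.
#' @param linkage_fraction Proportion of practices linked to hospital and
#'   death-certificate data.
#' @param hes_start,ons_start Start of the hospital-data and
#'   death-certificate collection windows.
#' @param gp_capture,hospital_capture Probability that a clinical event
#'   produces a GP record / a hospital record (the latter only for linked
#'   practices inside the hospital window).
#' @param cause_of_death_mix Named list (per class, plus `"none"` for
#'   deaths not during current use of a drug of interest) of named
#'   probability vectors over ICD-10 chapter keys (see
#'   [map_icd10_chapter()]).
#' @param missing_covariate_fraction Fraction of smoking/alcohol/BMI
#'   records left missing, to exercise missing-category handling.
#' @param type1_fraction Fraction of patients flagged type-1 diabetic
#'   (excluded by the cohort builder).
#' @param follow_up_mean_years Mean additional follow-up beyond the first
#'   half-year (exponential).
#' @param seed Integer seed; a fixed seed makes the generator output
#'   byte-identical across runs.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [simulate_ehr()], [generate_population()]
#' @export
scenario_config <- function(n_patients = 20000L,
                            n_practices = 200L,
                            calendar_start = "1999-01-01",
                            calendar_end = "2009-12-31",
                            age_mean = 64,
                            age_sd = 12,
                            sex_male = 0.56,
                            class_initiation_rates = default_initiation_rates(),
                            channeling_strength = 0.7,
                            channelled_classes = c("insulin", "sulphonylurea"),
                            true_log_rr = c("rosiglitazone:death" = log(1.2),
                                            "rosiglitazone:heart_failure" = log(1.7)),
                            recent_past_log_rr = numeric(0),
                            outcome_baseline_hazards = default_outcome_hazards(),
                            prescription_cycle = 60,
                            persistence = c(metformin = 0.25, sulphonylurea = 0.3,
                                            rosiglitazone = 0.35, pioglitazone = 0.35,
                                            insulin = 0.15, other_oad = 0.4),
                            multi_constituent_prob = 0.05,
                            linkage_fraction = 0.4,
                            hes_start = "1997-04-01",
                            ons_start = "2001-01-01",
                            gp_capture = 0.9,
                            hospital_capture = 0.7,
                            cause_of_death_mix = default_cause_mix(),
                            missing_covariate_fraction = 0.05,
                            type1_fraction = 0.02,
                            follow_up_mean_years = 5,
                            seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_practices = as.integer(n_practices),
    calendar_start = as_date(calendar_start),
    calendar_end = as_date(calendar_end),
    age_mean = age_mean, age_sd = age_sd,
    sex_male = sex_male,
    class_initiation_rates = class_initiation_rates,
    channeling_strength = channeling_strength,
    channelled_classes = channelled_classes,
    true_log_rr = true_log_rr,
    recent_past_log_rr = recent_past_log_rr,
    outcome_baseline_hazards = outcome_baseline_hazards,
    prescription_cycle = prescription_cycle,
    persistence = persistence,
    multi_constituent_prob = multi_constituent_prob,
    linkage_fraction = linkage_fraction,
    hes_start = as_date(hes_start),
    ons_start = as_date(ons_start),
    gp_capture = gp_capture,
    hospital_capture = hospital_capture,
    cause_of_death_mix = cause_of_death_mix,
    missing_covariate_fraction = missing_covariate_fraction,
    type1_fraction = type1_fraction,
    follow_up_mean_years = follow_up_mean_years,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
}

#' Default per-class initiation dynamics
#'
#' Baseline initiation hazards (per person-year) with calendar-time
#' multipliers reproducing the qualitative prescribing pattern of the late
#' 2000s: rosiglitazone uptake collapsing after regulatory warnings in
#' 2007, pioglitazone rising in its place.
#' @return Named list, one element per drug class.
#' @export
default_initiation_rates <- function() {
  list(
    metformin = list(base = 0.10, multipliers = numeric(0)),
    sulphonylurea = list(base = 0.05, multipliers = numeric(0)),
    rosiglitazone = list(base = 0.030, multipliers = c(
      "1999" = 0.2, "2000" = 0.5, "2007" = 0.55, "2008" = 0.10, "2009" = 0.06)),
    pioglitazone = list(base = 0.030, multipliers = c(
      "1999" = 0.05, "2000" = 0.15, "2001" = 0.25, "2002" = 0.3, "2003" = 0.35,
      "2004" = 0.4, "2005" = 0.45, "2006" = 0.5, "2007" = 0.9, "2008" = 1.5,
      "2009" = 1.0)),
    insulin = list(base = 0.015, multipliers = numeric(0)),
    other_oad = list(base = 0.010, multipliers = numeric(0))
  )
}

#' Default outcome hazard structure
#'
#' Baseline hazards per person-year at age 65, with log hazard ratios per
#' decade of age, for male sex and per SD of latent severity.  Magnitudes
#' give crude death rates near 2 per 100 person-years in thiazolidinedione
#' users, as seen in UK type-2 diabetes cohorts of the period.
#' @return Named list per outcome.
#' @export
default_outcome_hazards <- function() {
  list(
    death = c(base = 0.014, log_hr_age10 = log(2.0),
              log_hr_male = log(1.2), log_hr_severity = log(1.5)),
    acs = c(base = 0.008, log_hr_age10 = log(1.5),
            log_hr_male = log(1.4), log_hr_severity = log(1.3)),
    stroke = c(base = 0.004, log_hr_age10 = log(1.7),
               log_hr_male = log(1.1), log_hr_severity = log(1.3)),
    heart_failure = c(base = 0.007, log_hr_age10 = log(1.8),
                      log_hr_male = log(1.3), log_hr_severity = log(1.4))
  )
}

#' Default primary-cause-of-death mix by current drug class
#'
#' Multinomial probabilities over ICD-10 chapter keys.  The rosiglitazone
#' mix is shifted towards circulatory deaths relative to pioglitazone.
#' @return Named list of named probability vectors.
#' @export
default_cause_mix <- function() {
  base <- c(infectious = 0.02, neoplasm = 0.25, endocrine = 0.08,
            mental = 0.01, nervous = 0.02, circulatory = 0.38,
            respiratory = 0.09, digestive = 0.06, skin = 0.01,
            musculoskeletal = 0.01, genitourinary = 0.02, external = 0.02,
            other = 0.03)
  rosi <- base; rosi["circulatory"] <- 0.48; rosi["neoplasm"] <- 0.20
  rosi["respiratory"] <- 0.12; rosi["endocrine"] <- 0.05
  list(rosiglitazone = rosi / sum(rosi),
       pioglitazone = base / sum(base),
       none = base / sum(base))
}

#' Reference validation scenarios
#'
#' Fixed study conditions used to validate the pipeline against known
#' ground truth:
#'
#' * `"recovery"`: a thiazolidinedione-heavy population observed
#'   2000--2008 with no channeling (so no confounding by severity) and a
#'   true death rate ratio of 1.2 during current rosiglitazone use -- the
#'   conditions under which the adjusted estimate must recover the truth.
#' * `"channeling"`: strong channeling of sicker patients to insulin and
#'   sulphonylureas (coupling 1.0 on the log-hazard scale) with no true
#'   drug effects -- past-use contrasts against metformin then expose
#'   confounding by severity that covariate adjustment can only partly
#'   remove, because severity itself is never observed.
#' * `"no_channeling"`: the same population with channeling switched off
#'   -- all past-use rate ratios are compatible with 1.
#'
#' Insulin prescribing is raised relative to the default scenario so the
#' past-insulin stratum carries usable person-time at moderate sizes.
#'
#' @param type Scenario type.
#' @param seed Integer seed.
#' @param n_patients Population size (the reference experiments use
#'   50,000).
#' @return A [scenario_config()].
#' @export
validation_scenario <- function(type = c("recovery", "channeling",
                                         "no_channeling"),
                                seed = 1L, n_patients = 50000L) {
  type <- match.arg(type)
  rates <- default_initiation_rates()
  if (type == "recovery") {
    rates$rosiglitazone <- list(base = 0.05, multipliers = c(
      "2007" = 0.55, "2008" = 0.10))
    rates$pioglitazone <- list(base = 0.05, multipliers = c(
      "2000" = 0.2, "2001" = 0.3, "2002" = 0.4, "2003" = 0.5,
      "2004" = 0.6, "2005" = 0.7, "2006" = 0.8, "2007" = 1.2,
      "2008" = 1.5))
    scenario_config(
      n_patients = n_patients, n_practices = 400L,
      calendar_start = "2000-01-01", calendar_end = "2008-12-31",
      channeling_strength = 0,
      class_initiation_rates = rates,
      true_log_rr = c("rosiglitazone:death" = log(1.2)),
      follow_up_mean_years = 4, seed = seed)
  } else {
    rates$insulin <- list(base = 0.03, multipliers = numeric(0))
    scenario_config(
      n_patients = n_patients, n_practices = 400L,
      channeling_strength = if (type == "channeling") 1.0 else 0,
      class_initiation_rates = rates,
      persistence = c(metformin = 0.25, sulphonylurea = 0.3,
                      rosiglitazone = 0.35, pioglitazone = 0.35,
                      insulin = 0.4, other_oad = 0.4),
      true_log_rr = numeric(0), seed = seed)
  }
}

validate_scenario <- function(cfg) {
  if (cfg$n_patients <= 0L) stop_config("n_patients must be positive")
  if (cfg$n_practices <= 0L) stop_config("n_practices must be positive")
  if (cfg$calendar_start >= cfg$calendar_end)
    stop_config("calendar_start must precede calendar_end")
  props <- c(cfg$sex_male, cfg$linkage_fraction, cfg$gp_capture,
             cfg$hospital_capture, cfg$missing_covariate_fraction,
             cfg$type1_fraction, cfg$multi_constituent_prob)
  if (any(props < 0 | props > 1))
    stop_config("proportions must lie in [0, 1]")
  missing_cls <- setdiff(drug_classes(), names(cfg$class_initiation_rates))
  if (length(missing_cls))
    stop_config("class_initiation_rates missing classes: %s",
                paste(missing_cls, collapse = ", "))
  for (cl in names(cfg$class_initiation_rates)) {
    r <- cfg$class_initiation_rates[[cl]]
    if (r$base < 0) stop_config("negative initiation rate for %s", cl)
    if (length(r$multipliers) && any(r$multipliers < 0))
      stop_config("calendar multipliers must be non-negative (%s)", cl)
  }
  if (any(cfg$persistence < 0)) stop_config("persistence hazards must be >= 0")
  for (o in names(cfg$outcome_baseline_hazards)) {
    if (cfg$outcome_baseline_hazards[[o]][["base"]] < 0)
      stop_config("negative baseline hazard for outcome %s", o)
  }
  bad_keys <- Filter(function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    length(parts) != 2L || !(parts[1] %in% drug_classes()) ||
      !(parts[2] %in% study_outcomes())
  }, names(cfg$true_log_rr))
  if (length(bad_keys))
    stop_config("unknown (class, outcome) keys in true_log_rr: %s",
                paste(bad_keys, collapse = ", "))
  if (cfg$prescription_cycle <= 0) stop_config("prescription_cycle must be > 0")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d patients in %d practices, %s to %s (seed %d)\n",
              x$n_patients, x$n_practices, format(x$calendar_start),
              format(x$calendar_end), x$seed))
  cat(sprintf("  linkage: %.0f%% of practices; HES from %s, ONS from %s\n",
              100 * x$linkage_fraction, format(x$hes_start),
              format(x$ons_start)))
  if (length(x$true_log_rr)) {
    cat("  true current-use rate ratios:\n")
    for (k in names(x$true_log_rr))
      cat(sprintf("    %s: %.3f\n", k, exp(x$true_log_rr[[k]])))
  }
  invisible(x)
}
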