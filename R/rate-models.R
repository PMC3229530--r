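## Incidence rates and log-linear (Poisson) rate models with person-time
## offset.  Fitting is IRLS via stats::glm with a tight convergence
## tolerance; by Poisson sufficiency, fitting on aggregated
## (exposure x covariate) cells is identical to fitting on raw segments.

#' Incidence rate per 100 person-years
#'
#' @param events Event count.
#' @param person_years Person-years at risk (> 0).
#' @return `100 * events / person_years`.
#' @examples
#' incidence_rate(5, 250)  # 2 per 100 person-years
#' @export
incidence_rate <- function(events, person_years) {
  if (any(person_years <= 0)) stop_config("person_years must be positive")
  100 * events / person_years
}

minimal_adjustment_set <- function() c("age_band", "sex", "calendar_year")

full_adjustment_set <- function(data, linked_only = FALSE,
                                exclude_classes = character(0)) {
  nms <- names(data)
  covs <- c(minimal_adjustment_set(),
            intersect(c("smoking", "alcohol", "bmi"), nms),
            grep("^com_", nms, value = TRUE),
            grep("^rx6m_", nms, value = TRUE))
  ## socioeconomic status is only defined for linked practices
  if (linked_only && "ses_quintile" %in% nms)
    covs <- c(covs, "ses_quintile")
  other <- setdiff(drug_classes(), exclude_classes)
  covs <- c(covs, intersect(paste0("state_", other), nms))
  covs
}

#' Restrict person-time to a current-use contrast between drug classes
#'
#' Keeps segments current on exactly one of `classes` and adds an
#' `exposure` factor with those class labels.
#'
#' @param segments A `person_time` table.
#' @param classes Two or more drug classes to contrast.
#' @param reference Reference level (default the last class given).
#' @return Filtered segment table with an `exposure` column.
#' @export
current_use_contrast <- function(segments, classes,
                                 reference = classes[length(classes)]) {
  dt <- as.data.table(segments)
  cur <- sapply(classes, function(cl) dt[[paste0("state_", cl)]] == "current")
  if (is.null(dim(cur))) cur <- matrix(cur, nrow = 1L)
  n_cur <- rowSums(cur)
  keep <- n_cur == 1L
  dt <- dt[keep]
  dt[, exposure := factor(classes[max.col(cur[keep, , drop = FALSE])],
                          levels = union(reference, classes))]
  dt[, exposure := stats::relevel(exposure, ref = reference)]
  dt[]
}

#' Restrict person-time to a past-use contrast
#'
#' Exposure level `drug_class` where the segment is in the past state of
#' that class; `reference` where it is in the past state of the reference
#' class and not of `drug_class`.
#'
#' @param segments A `person_time` table.
#' @param drug_class Class of interest.
#' @param reference Reference class (default metformin).
#' @return Filtered segment table with an `exposure` column.
#' @export
past_use_contrast <- function(segments, drug_class,
                              reference = "metformin") {
  dt <- as.data.table(segments)
  is_cls <- dt[[paste0("state_", drug_class)]] == "past"
  is_ref <- dt[[paste0("state_", reference)]] == "past" & !is_cls
  dt <- dt[is_cls | is_ref]
  dt[, exposure := factor(fifelse(is_cls[is_cls | is_ref], drug_class,
                                  reference),
                          levels = c(reference, drug_class))]
  dt[]
}

#' Fit a Poisson incidence-rate model with person-time offset
#'
#' Maximises the Poisson log-likelihood of per-cell event counts with a
#' `log(person-years)` offset (IRLS, relative deviance change < 1e-10,
#' at most 100 iterations).  Person-time is first aggregated over the
#' cross-classification of the exposure term and the adjustment
#' covariates, which leaves the estimates unchanged (Poisson
#' sufficiency).  The minimal adjustment set is age band, sex and
#' calendar year; the full set adds lifestyle covariates (missing values
#' as an explicit category), comorbidity history, recent co-medication,
#' current-use indicators of the other drug classes, and -- when the
#' analysis is restricted to linked practices -- the socioeconomic
#' quintile.
#'
#' @param data A `person_time` table with an `events` column (from
#'   [attribute_events()]) and an exposure factor column.
#' @param exposure Name of the exposure column.
#' @param adjustment `"minimal"`, `"full"`, or `"none"` (crude).
#' @param reference Optional reference level of the exposure factor.
#' @param exclude_classes Classes of the contrast itself, excluded from
#'   the other-class current-use adjustment.
#' @param linked_only Is the analysis restricted to linked practices
#'   (enables the socioeconomic covariate)?
#' @return A `rate_model_fit`: tidy coefficient table (`$terms`: term,
#'   level, logRR, se, RR, lower, upper), per-level `$rates` (events,
#'   person-years, rate per 100 py), the fitted glm (`$model`) and
#'   metadata.  Levels with separated likelihoods are flagged and given
#'   infinite confidence limits.
#' @export
fit_rate_model <- function(data, exposure = "exposure",
                           adjustment = c("minimal", "full", "none"),
                           reference = NULL,
                           exclude_classes = character(0),
                           linked_only = FALSE) {
  adjustment <- match.arg(adjustment)
  dt <- as.data.table(data)
  if (!exposure %in% names(dt))
    stop_config("exposure column '%s' not found", exposure)
  if (!"events" %in% names(dt))
    stop_config("data has no 'events' column; run attribute_events() first")
  dt <- dt[py > 0]
  if (sum(dt$events) < 1L) stop_config("no events in data")

  covs <- switch(adjustment,
                 none = character(0),
                 minimal = intersect(minimal_adjustment_set(), names(dt)),
                 full = full_adjustment_set(dt, linked_only,
                                            exclude_classes))
  cells <- dt[, .(events = sum(events), py = sum(py)),
              by = c(exposure, covs)]
  cells[[exposure]] <- droplevels(as.factor(cells[[exposure]]))
  if (!is.null(reference))
    cells[[exposure]] <- stats::relevel(cells[[exposure]], ref = reference)
  for (cv in covs) cells[[cv]] <- as.factor(cells[[cv]])
  ## single-level factors carry no information and break model.matrix
  covs <- covs[vapply(covs, function(cv) nlevels(cells[[cv]]) > 1L, TRUE)]

  fml <- as.formula(paste("events ~", paste(c(exposure, covs),
                                            collapse = " + ")))
  fit <- glm(fml, family = poisson(), data = cells,
             offset = log(cells$py),
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop_config("Poisson model did not converge in %d IRLS iterations",
                fit$iter)

  cf <- coef(summary(fit))
  lv <- levels(cells[[exposure]])
  ref_lv <- lv[1L]
  rows <- lapply(lv, function(l) {
    if (l == ref_lv)
      return(data.table(term = exposure, level = l, logRR = 0, se = 0,
                        RR = 1, lower = NA_real_, upper = NA_real_,
                        separated = FALSE, reference = TRUE))
    nm <- paste0(exposure, l)
    b <- cf[nm, "Estimate"]; s <- cf[nm, "Std. Error"]
    sep <- !is.finite(b) || !is.finite(s) || abs(b) > 15 || s > 50
    data.table(term = exposure, level = l, logRR = b, se = s,
               RR = exp(b),
               lower = if (sep) 0 else exp(b - 1.96 * s),
               upper = if (sep) Inf else exp(b + 1.96 * s),
               separated = sep, reference = FALSE)
  })
  terms <- rbindlist(rows)
  rates <- cells[, .(events = sum(events), person_years = sum(py)),
                 by = exposure]
  setnames(rates, exposure, "level")
  rates[, rate := incidence_rate(events, person_years)]

  structure(list(terms = terms, rates = rates[], model = fit,
                 exposure = exposure, reference = ref_lv,
                 adjustment = adjustment, covariates = covs,
                 n_cells = nrow(cells)),
            class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf("<rate_model_fit> %s adjustment, reference: %s\n",
              x$adjustment, x$reference))
  tab <- merge(x$terms, x$rates, by = "level", sort = FALSE)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i]
    ci <- if (r$reference) "reference"
    else sprintf("RR %.2f (%.2f-%.2f)%s", r$RR, r$lower, r$upper,
                 if (r$separated) " [separated]" else "")
    cat(sprintf("  %-16s %5d events / %9.1f py (%.2f per 100 py)  %s\n",
                r$level, r$events, r$person_years, r$rate, ci))
  }
  invisible(x)
}

## stratum variable definitions shared by run_stratified and the reports
stratum_values <- function(dt, stratum) {
  switch(stratum,
         age65 = fifelse(dt$age_band %in% c("40-49", "50-64"),
                         "<65", ">=65"),
         insulin = fifelse(dt[["state_insulin"]] == "current",
                           "insulin", "no insulin"),
         calendar2007 = fifelse(dt$calendar_year < 2007, "<2007", ">=2007"),
         stop_config("unknown stratum '%s'", stratum))
}

#' Fit a rate model separately within strata
#'
#' Supported stratifications: `"age65"` (below / at-or-above 65 at
#' segment start), `"insulin"` (current insulin co-prescribing of the
#' segment) and `"calendar2007"` (calendar time before / from 2007;
#' segments are already split at year boundaries so the cut is exact).
#' Empty or event-free strata are reported as not estimable, not fatal.
#'
#' @param data Segment table as for [fit_rate_model()].
#' @param stratum One of `"age65"`, `"insulin"`, `"calendar2007"`.
#' @param ... Passed to [fit_rate_model()].
#' @return Named list of `rate_model_fit` or `not_estimable` markers.
#' @export
run_stratified <- function(data, stratum, ...) {
  dt <- as.data.table(data)
  val <- stratum_values(dt, stratum)
  out <- list()
  for (s in sort(unique(val))) {
    sub <- dt[val == s]
    out[[s]] <- if (!nrow(sub) || sum(sub$events) < 1L ||
                    sum(sub$py) <= 0)
      not_estimable("empty stratum or no events")
    else tryCatch(fit_rate_model(sub, ...),
                  error = function(e) not_estimable(conditionMessage(e)))
  }
  out
}

not_estimable <- function(reason) {
  structure(list(reason = reason), class = "not_estimable")
}

#' @export
print.not_estimable <- function(x, ...) {
  cat("<not estimable>", x$reason, "\n")
  invisible(x)
}
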