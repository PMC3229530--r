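## Time-dependent exposure classification and person-time splitting.
##
## Follow-up is partitioned into half-open [start, end) segments labelled
## with a per-class exposure state.  States are defined by time since the
## most recent prescription: current in [rx, rx + 91), recent in
## [last_rx + 91, last_rx + 365), past from last_rx + 365 onwards, never
## before the first prescription.  Because classification is relative to
## the most recent prescription, overlapping current windows from repeat
## prescriptions merge automatically: a repeat prescription extends
## current use.

#' Classify exposure state at given dates for one prescription stream
#'
#' @param rx_dates Prescription dates of one patient for one drug class
#'   (any order; duplicates allowed).
#' @param query_dates Dates at which to evaluate the exposure state.
#' @return Character vector: `"current"`, `"recent"`, `"past"` or
#'   `"never"` per query date.
#' @examples
#' classify_exposure(as.Date("2004-01-01"),
#'                   as.Date("2004-01-01") + c(45, 200, 400))
#' @export
classify_exposure <- function(rx_dates, query_dates) {
  q <- as.numeric(as_date(query_dates))
  rx <- sort(unique(as.numeric(as_date(rx_dates))))
  if (!length(rx)) return(rep("never", length(q)))
  pos <- findInterval(q, rx)
  gap <- q - rx[pmax(pos, 1L)]
  fifelse(pos == 0L, "never",
          fifelse(gap < CURRENT_WINDOW_DAYS, "current",
                  fifelse(gap < RECENT_WINDOW_DAYS, "recent", "past")))
}

## Vectorised multi-patient classification: last prescription at or before
## each (patient, date), then the same gap rule.
classify_exposure_at <- function(cl_rx, patient_ids, dates) {
  rxn <- cl_rx[, .(patient_id, rdate = as.numeric(date))]
  setkey(rxn, patient_id, rdate)
  q <- data.table(patient_id = patient_ids, rdate = as.numeric(dates))
  idx <- rxn[q, roll = Inf, which = TRUE, mult = "last"]
  gap <- q$rdate - rxn$rdate[idx]
  fifelse(is.na(gap), "never",
          fifelse(gap < CURRENT_WINDOW_DAYS, "current",
                  fifelse(gap < RECENT_WINDOW_DAYS, "recent", "past")))
}

## Expand multi-constituent prescriptions into one row per constituent
## class, so a combination product contributes to both class histories.
expand_rx <- function(rx) {
  rx <- as.data.table(rx)
  if (!"multi_constituent" %in% names(rx) ||
      !any(!is.na(rx$multi_constituent)))
    return(rx[, .(patient_id, date, drug_class)])
  extra <- rx[!is.na(multi_constituent),
              .(patient_id, date, drug_class = multi_constituent)]
  unique(rbind(rx[, .(patient_id, date, drug_class)], extra))
}

## Merge prescriptions into episodes of uninterrupted current use: a new
## episode starts when the gap since the previous prescription exceeds the
## current window.  The current interval of an episode is
## [first_rx, last_rx + 91).
current_episodes <- function(rxe) {
  if (!nrow(rxe))
    return(data.table(patient_id = integer(0), drug_class = character(0),
                      episode = integer(0), first_rx = as.Date(character(0)),
                      last_rx = as.Date(character(0))))
  rxn <- unique(data.table(patient_id = rxe$patient_id,
                           drug_class = rxe$drug_class,
                           d = as.numeric(rxe$date)))
  setorder(rxn, patient_id, drug_class, d)
  rxn[, gap := d - shift(d), by = .(patient_id, drug_class)]
  rxn[, episode := cumsum(is.na(gap) | gap > CURRENT_WINDOW_DAYS),
      by = .(patient_id, drug_class)]
  ep <- rxn[, .(first_rx = min(d), last_rx = max(d)),
            by = .(patient_id, drug_class, episode)]
  ep[, `:=`(first_rx = as.Date(first_rx, origin = "1970-01-01"),
            last_rx = as.Date(last_rx, origin = "1970-01-01"))]
  ep[]
}

## fast lookup tables for calendar years and July-1 birthdays
year_lookup <- function(years) {
  setNames(as.numeric(as.Date(sprintf("%d-01-01", years))),
           as.character(years))
}

#' Split follow-up into labelled person-time segments
#'
#' Partitions each cohort entry's follow-up `[index_date, censor_date)` at
#' every exposure-state change of every class, every covariate change,
#' every calendar-year boundary and every age-band boundary, labels each
#' segment with the per-class exposure state and a covariate snapshot
#' (most recent value before segment start; co-medication indicators use a
#' 183-day lookback), and coalesces adjacent segments with identical
#' labels.  When `reference_class` is given, follow-up is additionally
#' censored at the first prescription of that class, implementing the
#' active-comparator censoring that prevents immortal time bias.
#'
#' @param cohort Cohort entries (patient_id, cohort, index_date,
#'   censor_date), e.g. from [build_inception_cohort()].
#' @param patients Patient table (for birth year and sex).
#' @param prescriptions Prescription table; unordered input is sorted and
#'   duplicate prescriptions are idempotent.
#' @param covariates Optional long covariate table (patient_id, date,
#'   covariate, value); `rx6m_*` names are treated as dated co-medication
#'   records, all others as status values.
#' @param reference_class Optional drug class at whose first prescription
#'   follow-up is censored.
#' @param classes Drug classes to track exposure states for.
#' @return A `data.table` of class `person_time`: one row per segment with
#'   `patient_id`, `cohort`, `start`, `end`, `days`, `py`, one
#'   `state_<class>` column per tracked class, `age`, `age_band`,
#'   `calendar_year`, `sex` and one column per covariate.  Segments of a
#'   cohort entry are disjoint and tile `[index_date, censor_date)`.
#' @export
split_person_time <- function(cohort, patients, prescriptions,
                              covariates = NULL, reference_class = NULL,
                              classes = drug_classes()) {
  ce <- as.data.table(cohort)[, .(patient_id, cohort, index_date, censor_date)]
  if (!nrow(ce)) stop_config("empty cohort")
  stopifnot(all(classes %in% drug_classes()))
  pat <- as.data.table(patients)
  rxe <- expand_rx(as.data.table(prescriptions))
  unknown <- setdiff(rxe$patient_id, pat$patient_id)
  if (length(unknown))
    stop_config("prescriptions reference unknown patients: %s",
                paste(head(unknown, 5L), collapse = ", "))
  ## only the cohort's patients matter from here on
  ids <- unique(ce$patient_id)
  rxe <- rxe[patient_id %in% ids]
  rxe[, dnum := as.numeric(date)]
  pat <- pat[patient_id %in% ids]

  if (!is.null(reference_class)) {
    if (!reference_class %in% drug_classes())
      stop_config("unknown reference class '%s'", reference_class)
    ref <- rxe[drug_class == reference_class,
               .(ref_date = min(date)), by = patient_id]
    ce <- ref[ce, on = "patient_id"]
    ce[!is.na(ref_date), censor_date := pmin(censor_date, ref_date)]
    ce[, ref_date := NULL]
  }
  ce <- ce[censor_date > index_date]
  if (!nrow(ce)) stop_config("no follow-up left after censoring")
  ce[, entry := .I]
  ce[, `:=`(i0 = as.numeric(index_date), c1 = as.numeric(censor_date))]

  ## ---- candidate breakpoints (per patient; clipped per entry below) ----
  bp <- list()
  ep <- current_episodes(rxe[drug_class %in% classes])
  if (nrow(ep)) {
    f <- as.numeric(ep$first_rx); l <- as.numeric(ep$last_rx)
    bp$state <- data.table(
      patient_id = rep(ep$patient_id, 3L),
      cut = c(f, l + CURRENT_WINDOW_DAYS, l + RECENT_WINDOW_DAYS))
  }
  yr_range <- (year_of(min(ce$index_date)) - 1L):(year_of(max(ce$censor_date)) + 1L)
  ylk <- year_lookup(yr_range)
  tmp <- ce[, .(patient_id, y0 = year_of(index_date) + 1L,
                y1 = year_of(censor_date - 1L))][y1 >= y0]
  if (nrow(tmp)) {
    nrep <- tmp$y1 - tmp$y0 + 1L
    bp$year <- data.table(
      patient_id = rep(tmp$patient_id, nrep),
      cut = ylk[as.character(sequence(nrep, from = tmp$y0))])
  }
  byrs <- sort(unique(pat$birth_year))
  cutages <- AGE_BAND_BREAKS[is.finite(AGE_BAND_BREAKS)][-1]
  jyrs <- (min(byrs) + min(cutages) - 1L):(max(byrs) + max(cutages) + 1L)
  jul1 <- setNames(as.numeric(as.Date(sprintf("%d-07-01", jyrs))),
                   as.character(jyrs))
  bp$ageband <- data.table(
    patient_id = rep(pat$patient_id, length(cutages)),
    cut = jul1[as.character(rep(pat$birth_year, length(cutages)) +
                              rep(cutages, each = nrow(pat)))])

  cov <- NULL; statnames <- character(0); mednames <- character(0)
  if (!is.null(covariates) && nrow(covariates)) {
    cov <- as.data.table(covariates)[patient_id %in% ids]
    cov[, dnum := as.numeric(date)]
    statnames <- setdiff(unique(cov$covariate),
                         grep("^rx6m_", unique(cov$covariate), value = TRUE))
    mednames <- grep("^rx6m_", unique(cov$covariate), value = TRUE)
    stat <- cov[covariate %in% statnames]
    if (nrow(stat))
      bp$stat <- stat[, .(patient_id, cut = dnum)]
    med <- cov[covariate %in% mednames]
    if (nrow(med)) {
      setorder(med, patient_id, covariate, dnum)
      med[, gap := dnum - shift(dnum), by = .(patient_id, covariate)]
      med[, episode := cumsum(is.na(gap) | gap > COMED_LOOKBACK_DAYS),
          by = .(patient_id, covariate)]
      mep <- med[, .(f = min(dnum), l = max(dnum)),
                 by = .(patient_id, covariate, episode)]
      bp$med <- data.table(patient_id = rep(mep$patient_id, 2L),
                           cut = c(mep$f, mep$l + COMED_LOOKBACK_DAYS))
    }
  }

  cuts <- rbindlist(bp, use.names = TRUE)
  cuts <- ce[, .(patient_id, entry, i0, c1)][cuts, on = "patient_id",
                                             allow.cartesian = TRUE,
                                             nomatch = 0L]
  cuts <- cuts[cut > i0 & cut < c1, .(entry, cut)]
  cuts <- rbind(cuts, ce[, .(entry, cut = i0)], ce[, .(entry, cut = c1)])
  cuts <- unique(cuts)
  setorder(cuts, entry, cut)
  seg <- cuts[, .(s = cut[-.N], e = cut[-1]), by = entry]
  seg <- ce[, .(entry, patient_id, cohort)][seg, on = "entry"]

  ## ---- labels ----
  for (cl in classes) {
    rxc <- rxe[drug_class == cl, .(patient_id, rdate = dnum)]
    if (!nrow(rxc)) { seg[, (paste0("state_", cl)) := "never"]; next }
    setkey(rxc, patient_id, rdate)
    idx <- rxc[seg[, .(patient_id, rdate = s)], roll = Inf, which = TRUE,
               mult = "last"]
    gap <- seg$s - rxc$rdate[idx]
    seg[, (paste0("state_", cl)) :=
          fifelse(is.na(gap), "never",
                  fifelse(gap < CURRENT_WINDOW_DAYS, "current",
                          fifelse(gap < RECENT_WINDOW_DAYS, "recent",
                                  "past")))]
  }

  seg <- pat[, .(patient_id, birth_year, sex)][seg, on = "patient_id"]
  dobl <- setNames(as.numeric(as.Date(sprintf("%d-07-01", byrs))),
                   as.character(byrs))
  seg[, age := as.integer(floor((s - dobl[as.character(birth_year)]) /
                                  DAYS_PER_YEAR))]
  seg[, age_band := age_band_of(age)]
  ystarts <- ylk[order(ylk)]
  seg[, calendar_year := as.integer(names(ystarts))[findInterval(s, ystarts)]]
  seg[, birth_year := NULL]

  if (!is.null(cov)) {
    for (nm in statnames) {
      sv <- cov[covariate == nm, .(patient_id, rdate = dnum, value)]
      setkey(sv, patient_id, rdate)
      idx <- sv[seg[, .(patient_id, rdate = s)], roll = Inf, which = TRUE,
                mult = "last"]
      val <- sv$value[idx]
      val[is.na(val)] <- "missing"
      seg[, (nm) := val]
    }
    for (nm in mednames) {
      sv <- cov[covariate == nm, .(patient_id, rdate = dnum)]
      setkey(sv, patient_id, rdate)
      idx <- sv[seg[, .(patient_id, rdate = s)], roll = Inf, which = TRUE,
                mult = "last"]
      gap <- seg$s - sv$rdate[idx]
      seg[, (nm) := as.integer(!is.na(gap) & gap < COMED_LOOKBACK_DAYS)]
    }
    if ("bmi" %in% names(seg)) seg[, bmi := bmi_category(bmi)]
  }

  ## ---- coalesce adjacent identical segments ----
  lbl <- setdiff(names(seg), c("s", "e", "age"))
  setorder(seg, entry, s)
  seg[, run := rleidv(.SD), .SDcols = lbl]
  out <- seg[, c(.(s = s[1L], e = e[.N], age = age[1L]),
                 lapply(.SD, `[`, 1L)),
             by = run, .SDcols = lbl]
  out[, run := NULL]
  out[, `:=`(start = as.Date(s, origin = "1970-01-01"),
             end = as.Date(e, origin = "1970-01-01"),
             days = as.integer(e - s))]
  out[, py := days / DAYS_PER_YEAR]
  out[, c("s", "e") := NULL]
  setcolorder(out, c("patient_id", "cohort", "entry", "start", "end",
                     "days", "py"))
  setattr(out, "class", c("person_time", class(out)))
  out[]
}

## BMI categories used in adjustment sets; cut points documented, not
## asserted by any acceptance check.
bmi_category <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  fifelse(is.na(v), "missing",
          fifelse(v < 25, "<25", fifelse(v < 30, "25-30", "30+")))
}

#' Attribute outcome events to person-time segments
#'
#' Counts each patient's first event of an outcome in the unique segment
#' whose interval contains its date.  With `incident_only`, patients with
#' a record of that outcome before their index date contribute no
#' person-time to this outcome's analysis (never applied to death).  With
#' `censor_at_event` (the default incident-rate convention), follow-up
#' ends the day after the attributed event: the containing segment is
#' truncated and later segments dropped -- for death this is exactly the
#' truncation at the death date.  Events outside follow-up are ignored
#' with a warning.
#'
#' @param segments A `person_time` table from [split_person_time()].
#' @param events Event table with `patient_id` and `date` (and optionally
#'   an `outcome` column, filtered by `outcome`); for death analyses pass
#'   the patients' death dates.
#' @param outcome Optional outcome label used to filter `events` and to
#'   decide whether the `incident_only` exclusion applies.
#' @param incident_only Exclude patients with a pre-index event of this
#'   outcome.
#' @param censor_at_event End follow-up at the first attributed event.
#' @return The segment table with an `events` column (0/1 per segment) and
#'   adjusted `end`/`days`/`py`.
#' @export
attribute_events <- function(segments, events, outcome = NULL,
                             incident_only = TRUE,
                             censor_at_event = TRUE) {
  seg <- as.data.table(copy(segments))
  ev <- as.data.table(events)
  if (!is.null(outcome) && "outcome" %in% names(ev)) {
    o <- outcome
    ev <- ev[ev$outcome == o]
  }
  ev <- ev[!is.na(date), .(patient_id, date)]
  seg[, events := 0L]
  if (!nrow(ev)) return(finish_person_time(seg))

  bounds <- seg[, .(index = min(start), fup_end = max(end)),
                by = .(entry, patient_id)]
  ev <- bounds[ev, on = "patient_id", allow.cartesian = TRUE, nomatch = 0L]

  is_death <- identical(outcome, "death")
  if (incident_only && !is_death) {
    pre <- unique(ev[date < index, .(entry)])
    if (nrow(pre)) {
      seg <- seg[!pre, on = "entry"]
      ev <- ev[!pre, on = "entry"]
    }
    if (!nrow(seg)) return(finish_person_time(seg))
  }
  inside <- ev[date >= index & date < fup_end]
  ## pre-index events consumed by the incident-only exclusion are not
  ## "outside follow-up"; anything else unattributable is
  dropped <- nrow(ev[date >= fup_end]) +
    if (incident_only && !is_death) 0L else nrow(ev[date < index])
  if (dropped > 0L)
    warning(sprintf("%d event(s) outside follow-up ignored", dropped),
            call. = FALSE)
  if (!nrow(inside)) return(finish_person_time(seg))
  first_ev <- inside[, .(edate = min(date)), by = entry]

  seg <- first_ev[seg, on = "entry"]
  hit <- !is.na(seg$edate) & seg$start <= seg$edate & seg$end > seg$edate
  seg[hit, `:=`(events = 1L, end = edate + 1L)]
  if (censor_at_event) {
    seg <- seg[is.na(edate) | start <= edate]
  }
  seg[, edate := NULL]
  finish_person_time(seg)
}

finish_person_time <- function(seg) {
  seg[, days := as.integer(end - start)]
  seg[, py := days / DAYS_PER_YEAR]
  if (!inherits(seg, "person_time"))
    setattr(seg, "class", c("person_time", class(seg)))
  seg[]
}
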