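## Kaplan-Meier life tables over current use, cumulative incidence at
## fixed horizons with Greenwood/log(-log) confidence intervals, and
## excess-risk differences.  The product-limit estimate and Greenwood
## variance are computed by survival::survfit (ties: events before
## censorings at equal times); this module owns the horizon lookup, the
## interval transform and the reporting scale.

#' Kaplan-Meier life table
#'
#' @param time Time to event or censoring (> 0), e.g. days from start of
#'   current use.
#' @param event 1 = event, 0 = censored.
#' @return A `life_table`: data.table with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `greenwood_var`, `cuminc` (percent), and the
#'   underlying `survfit` object as attribute `fit`.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop_config("no spells")
  if (any(time <= 0)) stop_config("times must be positive")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  ## survfit std.err is se(log S); Greenwood var(S) = S^2 * se(log S)^2
  lt <- data.table(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, n_censor = fit$n.censor,
                   surv = fit$surv,
                   greenwood_var = (fit$surv * fit$std.err)^2)
  lt[, cuminc := 100 * (1 - surv)]
  setattr(lt, "fit", fit)
  setattr(lt, "n", length(time))
  setattr(lt, "class", c("life_table", class(lt)))
  lt[]
}

## step-function lookup: last row with time <= h (S = 1 before the first
## event/censoring time)
lt_at <- function(lt, h) {
  i <- findInterval(h, lt$time)
  if (i == 0L) list(surv = 1, var = 0)
  else list(surv = lt$surv[i], var = lt$greenwood_var[i])
}

#' Cumulative incidence at fixed horizons
#'
#' Returns `100 * (1 - S(h))` with a 95% confidence interval from the
#' Greenwood variance on the log(-log) survival scale.  A horizon beyond
#' the last observed time carries the last estimate forward with a
#' warning.
#'
#' @param lt A [kaplan_meier()] life table.
#' @param horizons Horizons in the time unit of the table; defaults to 1
#'   and 3 years in days.
#' @return data.table with `horizon`, `cuminc`, `lower`, `upper`
#'   (percent).
#' @export
cumulative_incidence_at <- function(lt, horizons = c(365, 1095)) {
  stopifnot(inherits(lt, "life_table"))
  if (!nrow(lt)) stop_config("empty life table")
  over <- horizons > max(lt$time)
  if (any(over))
    warning("horizon beyond last observed time; carrying last estimate",
            call. = FALSE)
  rows <- lapply(horizons, function(h) {
    a <- lt_at(lt, h)
    s <- a$surv; v <- a$var
    if (s <= 0 || s >= 1 || v <= 0) {
      lo <- hi <- 100 * (1 - s)
      if (s > 0 && s < 1) { lo <- NA_real_; hi <- NA_real_ }
    } else {
      ## var(log(-log S)) by the delta method
      se_ll <- sqrt(v) / abs(s * log(s))
      ll <- log(-log(s))
      s_lo <- exp(-exp(ll + 1.96 * se_ll))  # lower survival
      s_hi <- exp(-exp(ll - 1.96 * se_ll))
      lo <- 100 * (1 - s_hi)
      hi <- 100 * (1 - s_lo)
    }
    data.table(horizon = h, cuminc = 100 * (1 - s), lower = lo, upper = hi)
  })
  rbindlist(rows)
}

#' Excess risk
#'
#' Difference of two cumulative incidences (percent), computed at full
#' precision; rounding is a display concern only.
#'
#' @param a,b Cumulative incidences (%) on the same horizon and stratum.
#' @return `a - b`.
#' @examples
#' excess_risk(38.90, 31.81)
#' @export
excess_risk <- function(a, b) a - b

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %d subjects, %d events\n",
              attr(x, "n"), sum(x$n_event)))
  print(as.data.table(head(x, 10L)))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Time-to-first-event spells for a composite endpoint
#'
#' Combines several per-outcome spell tables (same cohort) into
#' time-to-first of any outcome: the composite duration is the shortest
#' spell and the event indicator is 1 if that shortest spell ended in an
#' event.
#'
#' @param ... Spell tables (`patient_id`, `duration`, `event`).
#' @return Composite spell table of the patients present in all inputs.
#' @export
composite_spells <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  all_sp <- rbindlist(lapply(tabs, as.data.table))
  common <- Reduce(intersect, lapply(tabs, function(t) t$patient_id))
  all_sp <- all_sp[patient_id %in% common]
  setorder(all_sp, patient_id, duration, -event)
  all_sp[, .SD[1L], by = patient_id]
}
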