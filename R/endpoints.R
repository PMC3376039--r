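#' Adjudicate a reported clinical event
#'
#' Applies the study's event definitions and returns the decision with a
#' rule trace. Myocardial infarction requires at least two of: chest
#' symptoms, ECG changes, elevated cardiac enzymes. Angina requires ECG
#' abnormalities AND chest symptoms AND the need for catheter or surgical
#' treatment. A cerebro-vascular event requires neuropathy lasting more
#' than 24 hours AND a causative lesion on CT/MRI, and must not be a TIA
#' or asymptomatic small infarction. Death and renal death (maintenance
#' hemodialysis, peritoneal dialysis, transplantation) are always
#' accepted.
#'
#' @param report a list with `type` (one of `"death"`, `"renal_death"`,
#'   `"mi"`, `"angina"`, `"stroke"`), optionally `subtype` and `date`, and
#'   the criteria booleans for the type: MI `chest_symptoms`,
#'   `ecg_changes`, `elevated_enzymes`; angina `ecg_abnormalities`,
#'   `chest_symptoms`, `intervention_needed`; stroke `symptoms_over_24h`,
#'   `lesion_on_imaging`, `is_tia_or_asymptomatic`.
#' @return list with `accepted` (logical), `type`, and `trace` (character
#'   description of the rule applied).
#' @export
adjudicate_event <- function(report) {
  r <- as.list(report)
  type <- as.character(r$type %||% NA)
  if (!type %in% c("death", "renal_death", "mi", "angina", "stroke"))
    stop_domain("unknown event type '", type, "'")
  need <- function(fields) {
    vals <- lapply(r, identity)[fields]
    miss <- fields[vapply(vals, function(v) is.null(v) || is.na(v),
                          logical(1))]
    if (length(miss))
      stop_domain("incomplete ", type, " report; missing criteria: ",
                  paste(miss, collapse = ", "))
    vapply(r[fields], function(v) isTRUE(as.logical(v)), logical(1))
  }
  if (type %in% c("death", "renal_death"))
    return(list(accepted = TRUE, type = type,
                trace = paste0(type, ": always accepted")))
  if (type == "mi") {
    crit <- need(c("chest_symptoms", "ecg_changes", "elevated_enzymes"))
    k <- sum(crit)
    return(list(accepted = k >= 2L, type = type,
                trace = sprintf("mi: %d of 3 criteria met (need >= 2)", k)))
  }
  if (type == "angina") {
    crit <- need(c("ecg_abnormalities", "chest_symptoms",
                   "intervention_needed"))
    return(list(accepted = all(crit), type = type,
                trace = sprintf("angina: all-of-3 rule, %d of 3 met",
                                sum(crit))))
  }
  # stroke
  crit <- need(c("symptoms_over_24h", "lesion_on_imaging",
                 "is_tia_or_asymptomatic"))
  ok <- crit[["symptoms_over_24h"]] && crit[["lesion_on_imaging"]] &&
    !crit[["is_tia_or_asymptomatic"]]
  list(accepted = ok, type = type,
       trace = paste0("stroke: >24h symptoms = ", crit[[1]],
                      ", lesion = ", crit[[2]],
                      ", TIA/asymptomatic = ", crit[[3]]))
}

#' Composite renal endpoint for one patient
#'
#' The primary endpoint is the first occurrence of: death, renal death
#' (maintenance dialysis or transplantation), an adjudicated
#' cerebro-cardiovascular event, or a 50% reduction in eGFR from the
#' enrollment baseline. The event time is measured in years from the
#' biopsy date. A single sub-50% eGFR measurement triggers the endpoint
#' (set `confirm_egfr = TRUE` to require the next visit to confirm).
#' Patients without an accepted event are censored at their last visit.
#'
#' @param baseline list/one-row data frame with `biopsy_date`, `age`,
#'   `sex`, `serum_creatinine` (baseline eGFR is computed from these).
#' @param visits data frame of follow-up visits with `visit_date` and
#'   `serum_creatinine`; rows need not be sorted. Ages at follow-up are
#'   advanced from the baseline age by the elapsed time.
#' @param events optional data frame of reported events, one per row, with
#'   columns `type`, `date` and the criteria columns used by
#'   [adjudicate_event()]; missing criteria columns default to `NA`.
#' @param confirm_egfr require a second consecutive sub-50% eGFR visit.
#' @return list with `event_occurred`, `event_type`, `time_years`,
#'   `censor_reason` (NA for events), `baseline_egfr` and the per-visit
#'   eGFR series.
#' @export
composite_endpoint <- function(baseline, visits, events = NULL,
                               confirm_egfr = FALSE) {
  b <- as.list(baseline)
  base_date <- as.Date(b$biopsy_date)
  base_egfr <- egfr_japanese(as.numeric(b$age), as.character(b$sex),
                             as.numeric(b$serum_creatinine))
  if (is.null(visits) || nrow(visits) == 0L) {
    return(list(event_occurred = FALSE, event_type = NA_character_,
                time_years = 0, censor_reason = "no follow-up visits",
                baseline_egfr = base_egfr, egfr = numeric()))
  }
  visits <- visits[order(as.Date(visits$visit_date)), , drop = FALSE]
  vt <- years_between(base_date, visits$visit_date)
  if (any(vt < 0)) stop_domain("visit before biopsy date")
  egfr <- egfr_japanese(as.numeric(b$age) + vt, as.character(b$sex),
                        as.numeric(visits$serum_creatinine))

  candidates <- data.frame(time = numeric(), type = character())
  # 50% eGFR reduction
  low <- egfr <= 0.5 * base_egfr
  hit <- if (confirm_egfr) which(low & c(low[-1], FALSE))[1] else which(low)[1]
  if (!is.na(hit))
    candidates <- rbind(candidates,
                        data.frame(time = vt[hit],
                                   type = "egfr_50pct_reduction"))
  # adjudicated reported events
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      rep_i <- as.list(events[i, , drop = FALSE])
      adj <- adjudicate_event(rep_i)
      if (adj$accepted)
        candidates <- rbind(candidates,
                            data.frame(time = years_between(base_date,
                                                            rep_i$date),
                                       type = adj$type))
    }
  }
  if (nrow(candidates)) {
    first <- candidates[which.min(candidates$time), ]
    return(list(event_occurred = TRUE, event_type = first$type,
                time_years = first$time, censor_reason = NA_character_,
                baseline_egfr = base_egfr, egfr = egfr))
  }
  status <- as.character(visits$status %||% "followed")
  reason <- if (any(status == "lost")) "lost to follow-up" else "end of study"
  list(event_occurred = FALSE, event_type = NA_character_,
       time_years = max(vt), censor_reason = reason,
       baseline_egfr = base_egfr, egfr = egfr)
}

#' Annual eGFR decline rate
#'
#' Ordinary least-squares slope of eGFR on years since biopsy, using all
#' available values (baseline included by passing time 0).
#'
#' @param years numeric vector of times since biopsy, years.
#' @param egfr eGFR values at those times.
#' @return slope in mL/min/1.73 m^2 per year (negative = decline).
#' @examples
#' egfr_slope(c(0, 1, 2), c(60, 55, 50))  # -5
#' @export
egfr_slope <- function(years, egfr) {
  ok <- is.finite(years) & is.finite(egfr)
  years <- years[ok]; egfr <- egfr[ok]
  if (length(years) < 2L || length(unique(years)) < 2L)
    stop_domain("need at least 2 eGFR values at distinct times")
  unname(stats::coef(stats::lm.fit(cbind(1, years), egfr))[2])
}

#' Analysis-ready time-to-event table from registry tables
#'
#' Applies [composite_endpoint()] to every patient in an enrollment table
#' and its follow-up table (schemas of [read_enrollment()] /
#' [read_followup()]) and returns the survival table any standard package
#' can consume.
#'
#' @param enrollment enrollment data frame.
#' @param followup follow-up data frame; event columns (`event_type`,
#'   `event_date`, criteria) are picked up from rows where `event_type` is
#'   non-empty.
#' @param confirm_egfr see [composite_endpoint()].
#' @return data frame: `patient_id`, `time_years`, `event` (0/1),
#'   `event_type`, `censor_reason`, `baseline_egfr`, `egfr_slope`.
#' @export
endpoints_from_tables <- function(enrollment, followup,
                                  confirm_egfr = FALSE) {
  out <- lapply(seq_len(nrow(enrollment)), function(i) {
    b <- as.list(enrollment[i, , drop = FALSE])
    fu <- followup[followup$patient_id == b$patient_id, , drop = FALSE]
    ev <- NULL
    if ("event_type" %in% names(fu)) {
      has_ev <- !is.na(fu$event_type) & nzchar(fu$event_type)
      if (any(has_ev)) {
        ev <- fu[has_ev, , drop = FALSE]
        ev$type <- ev$event_type
        ev$date <- ev$event_date
      }
    }
    res <- composite_endpoint(b, fu, events = ev,
                              confirm_egfr = confirm_egfr)
    slope <- if (nrow(fu) >= 1L) {
      yrs <- c(0, years_between(b$biopsy_date, fu$visit_date))
      eg <- c(res$baseline_egfr, res$egfr)
      if (length(unique(yrs)) >= 2L) egfr_slope(yrs, eg) else NA_real_
    } else NA_real_
    data.frame(patient_id = b$patient_id,
               time_years = res$time_years,
               event = as.integer(res$event_occurred),
               event_type = res$event_type %||% NA_character_,
               censor_reason = res$censor_reason,
               baseline_egfr = res$baseline_egfr,
               egfr_slope = slope,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
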