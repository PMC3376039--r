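test_that("event adjudication follows the study definitions", {
  # MI: two of three suffice
  expect_true(adjudicate_event(list(type = "mi", chest_symptoms = TRUE,
                                    ecg_changes = FALSE,
                                    elevated_enzymes = TRUE))$accepted)
  expect_false(adjudicate_event(list(type = "mi", chest_symptoms = FALSE,
                                     ecg_changes = TRUE,
                                     elevated_enzymes = FALSE))$accepted)
  # angina: all three required
  expect_true(adjudicate_event(list(type = "angina",
                                    ecg_abnormalities = TRUE,
                                    chest_symptoms = TRUE,
                                    intervention_needed = TRUE))$accepted)
  expect_false(adjudicate_event(list(type = "angina",
                                     ecg_abnormalities = TRUE,
                                     chest_symptoms = TRUE,
                                     intervention_needed = FALSE))$accepted)
  # stroke: >24 h symptoms AND lesion AND not TIA/asymptomatic
  expect_false(adjudicate_event(list(type = "stroke",
                                     symptoms_over_24h = FALSE,
                                     lesion_on_imaging = TRUE,
                                     is_tia_or_asymptomatic = FALSE))$accepted)
  expect_false(adjudicate_event(list(type = "stroke",
                                     symptoms_over_24h = TRUE,
                                     lesion_on_imaging = TRUE,
                                     is_tia_or_asymptomatic = TRUE))$accepted)
  expect_true(adjudicate_event(list(type = "stroke",
                                    symptoms_over_24h = TRUE,
                                    lesion_on_imaging = TRUE,
                                    is_tia_or_asymptomatic = FALSE))$accepted)
  # death and renal death need no criteria
  expect_true(adjudicate_event(list(type = "death"))$accepted)
  expect_true(adjudicate_event(list(type = "renal_death",
                                    subtype = "hemodialysis"))$accepted)
  expect_error(adjudicate_event(list(type = "mi", chest_symptoms = TRUE)),
               class = "nephest_domain_error")
  expect_error(adjudicate_event(list(type = "syncope")),
               class = "nephest_domain_error")
})

# a baseline whose eGFR is exactly egfr0 at the biopsy date
make_baseline <- function(egfr0 = 60, age = 50, sex = "male") {
  cre <- (194 * age^(-0.287) * ifelse(sex == "female", 0.739, 1) /
            egfr0)^(1 / 1.094)
  list(patient_id = "X", biopsy_date = as.Date("2011-01-01"), age = age,
       sex = sex, serum_creatinine = cre)
}

# visits with prescribed observed eGFR values at year offsets
make_visits <- function(base, egfr_at, years) {
  dates <- as.Date(base$biopsy_date) + round(years * 365.25)
  t <- as.numeric(dates - as.Date(base$biopsy_date)) / 365.25
  cre <- (194 * (base$age + t)^(-0.287) *
            ifelse(base$sex == "female", 0.739, 1) / egfr_at)^(1 / 1.094)
  data.frame(visit_date = dates, serum_creatinine = cre)
}

test_that("a 50% eGFR reduction triggers the composite", {
  b <- make_baseline(60)
  v <- make_visits(b, c(55, 29), c(1, 2))
  res <- composite_endpoint(b, v)
  expect_true(res$event_occurred)
  expect_identical(res$event_type, "egfr_50pct_reduction")
  expect_equal(res$time_years, 2, tolerance = 2e-3)
  expect_equal(res$baseline_egfr, 60)
  # exactly half counts (<=)
  v2 <- make_visits(b, c(55, 30), c(1, 2))
  expect_true(composite_endpoint(b, v2)$event_occurred)
  # 31 does not
  v3 <- make_visits(b, c(55, 31), c(1, 2))
  expect_false(composite_endpoint(b, v3)$event_occurred)
})

test_that("the first accepted event wins", {
  b <- make_baseline(60)
  v <- make_visits(b, c(55, 29), c(1, 2))
  ev <- data.frame(type = "mi", date = as.Date("2012-01-01"),
                   chest_symptoms = TRUE, ecg_changes = TRUE,
                   elevated_enzymes = FALSE)
  res <- composite_endpoint(b, v, events = ev)
  expect_identical(res$event_type, "mi")
  expect_equal(res$time_years, 1, tolerance = 2e-3)
  # a rejected event does not count
  ev2 <- transform(ev, ecg_changes = FALSE)
  expect_identical(composite_endpoint(b, v, events = ev2)$event_type,
                   "egfr_50pct_reduction")
})

test_that("censoring uses the last visit and records the reason", {
  b <- make_baseline(60)
  v <- make_visits(b, c(58, 55, 52), c(1, 2, 3))
  res <- composite_endpoint(b, v)
  expect_false(res$event_occurred)
  expect_equal(res$time_years, 3, tolerance = 2e-3)
  expect_identical(res$censor_reason, "end of study")
  v$status <- c("followed", "followed", "lost")
  expect_identical(composite_endpoint(b, v)$censor_reason,
                   "lost to follow-up")
  none <- composite_endpoint(b, v[0, ])
  expect_false(none$event_occurred)
  expect_identical(none$time_years, 0)
})

test_that("the composite equals the brute-force minimum over components", {
  set.seed(21)
  for (i in 1:20) {
    b <- make_baseline(runif(1, 30, 90))
    b_egfr <- egfr_japanese(b$age, b$sex, b$serum_creatinine)
    yrs <- sort(runif(3, 0.5, 4.5))
    egfrs <- runif(3, 0.3, 1.1) * b_egfr
    v <- make_visits(b, egfrs, yrs)
    ev <- if (runif(1) < 0.5)
      data.frame(type = "death", date = b$biopsy_date +
                   round(runif(1, 100, 1500))) else NULL
    res <- composite_endpoint(b, v, events = ev)
    # brute force: scan every candidate time
    vt <- as.numeric(v$visit_date - b$biopsy_date) / 365.25
    eg <- egfr_japanese(b$age + vt, b$sex, v$serum_creatinine)
    cand <- vt[eg <= 0.5 * b_egfr]
    if (!is.null(ev))
      cand <- c(cand, as.numeric(ev$date - b$biopsy_date) / 365.25)
    if (length(cand)) {
      expect_true(res$event_occurred)
      expect_equal(res$time_years, min(cand))
    } else {
      expect_false(res$event_occurred)
      expect_equal(res$time_years, max(vt))
    }
  }
})

test_that("eGFR slope is the OLS slope per year", {
  expect_equal(egfr_slope(c(0, 1, 2), c(60, 55, 50)), -5)
  expect_equal(egfr_slope(c(0, 1, 2), c(48, 48, 48)), 0)
  expect_equal(egfr_slope(c(0, 1.5), c(60, 54)), -4)
  expect_error(egfr_slope(1, 60), class = "nephest_domain_error")
  expect_error(egfr_slope(c(1, 1), c(60, 58)), class = "nephest_domain_error")
})
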