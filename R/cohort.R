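#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical structure assumed by the study design:
#' birth weights from a two-component Gaussian mixture whose mixing weight
#' is solved so that the realised low-birth-weight (< 2500 g) prevalence
#' equals `lbw_fraction`; nephron numbers linear in birth weight with
#' Gaussian noise; exponential event times with group-specific rates;
#' uniform entry over the accrual interval with administrative censoring
#' at the study end; and linear eGFR trajectories whose slope steepens as
#' the nephron number falls, observed at annual visits with measurement
#' noise. Set the noise standard deviations to 0 for an exactly
#' recoverable (noiseless) cohort.
#'
#' @param n_patients cohort size (default 600, the recruitment target).
#' @param lbw_fraction target LBW prevalence (default 0.095).
#' @param bw_normal_mean,bw_normal_sd normal-component birth weight, g.
#' @param bw_low_mean,bw_low_sd low-component birth weight, g.
#' @param nephron_intercept,nephron_slope_per_g linear nephron-birth
#'   weight link (glomeruli; default 130000 + 250/g, putting a 3200-g
#'   newborn near 930,000 glomeruli).
#' @param nephron_sd Gaussian noise on the nephron number.
#' @param event_rate_normal,event_rate_lbw group event rates (defaults
#'   0.1 / 0.2).
#' @param rate_interpretation `"annual_hazard"` (default) or
#'   `"cumulative_probability"`; see [design_spec()].
#' @param accrual_years,followup_years study structure (defaults 2 and 3).
#' @param egfr_baseline_mean,egfr_baseline_sd baseline eGFR distribution
#'   (mL/min/1.73 m^2), truncated below at 10.
#' @param egfr_slope_mean mean annual eGFR slope at the reference nephron
#'   number of 900,000 (default -2).
#' @param egfr_slope_per_100k slope change per 100,000 nephrons above the
#'   reference (default +0.25; fewer nephrons, steeper decline).
#' @param egfr_noise_sd measurement noise on each eGFR value (default 2;
#'   set 0 for the noiseless cohort).
#' @param dropout_fraction fraction lost to follow-up at a uniform random
#'   time (default 0).
#' @param seed generator seed (default 1).
#' @return object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_patients = 600, lbw_fraction = 0.095,
                              bw_normal_mean = 3200, bw_normal_sd = 350,
                              bw_low_mean = 2100, bw_low_sd = 250,
                              nephron_intercept = 130000,
                              nephron_slope_per_g = 250,
                              nephron_sd = 180000,
                              event_rate_normal = 0.1,
                              event_rate_lbw = 0.2,
                              rate_interpretation = c(
                                "annual_hazard", "cumulative_probability"),
                              accrual_years = 2, followup_years = 3,
                              egfr_baseline_mean = 60,
                              egfr_baseline_sd = 20,
                              egfr_slope_mean = -2,
                              egfr_slope_per_100k = 0.25,
                              egfr_noise_sd = 2,
                              dropout_fraction = 0, seed = 1L) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(lbw_fraction, "lbw_fraction", 0, 1, TRUE, TRUE)
  for (nm in c("bw_normal_sd", "bw_low_sd"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(egfr_noise_sd, "egfr_noise_sd", lower = 0)
  check_number(dropout_fraction, "dropout_fraction", 0, 1,
               strict_upper = TRUE)
  # mixing weight solving the realised P(bw < 2500) = lbw_fraction
  p_low <- stats::pnorm(2500, bw_low_mean, bw_low_sd)
  p_norm <- stats::pnorm(2500, bw_normal_mean, bw_normal_sd)
  w <- (lbw_fraction - p_norm) / (p_low - p_norm)
  if (!is.finite(w) || w <= 0 || w >= 1)
    stop_domain("birth-weight components cannot realise lbw_fraction ",
                lbw_fraction)
  structure(
    list(n_patients = as.integer(n_patients), lbw_fraction = lbw_fraction,
         bw_normal_mean = bw_normal_mean, bw_normal_sd = bw_normal_sd,
         bw_low_mean = bw_low_mean, bw_low_sd = bw_low_sd,
         mixture_weight_low = w,
         nephron_intercept = nephron_intercept,
         nephron_slope_per_g = nephron_slope_per_g,
         nephron_sd = nephron_sd,
         event_rate_normal = event_rate_normal,
         event_rate_lbw = event_rate_lbw,
         rate_interpretation = match.arg(rate_interpretation),
         accrual_years = accrual_years, followup_years = followup_years,
         egfr_baseline_mean = egfr_baseline_mean,
         egfr_baseline_sd = egfr_baseline_sd,
         egfr_slope_mean = egfr_slope_mean,
         egfr_slope_per_100k = egfr_slope_per_100k,
         egfr_noise_sd = egfr_noise_sd,
         dropout_fraction = dropout_fraction,
         seed = as.integer(seed)),
    class = "sim_cohort_config")
}

# invert the Japanese eGFR equation to a serum creatinine
creatinine_from_egfr <- function(egfr, age, sex) {
  (194 * age^(-0.287) * ifelse(sex == "female", 0.739, 1) / egfr)^(1 / 1.094)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emits an enrollment table and a follow-up table in the registry
#' schemas ([read_enrollment()] / [read_followup()]) plus a truth table
#' for recovery tests. Hard events (death, renal death, adjudicable
#' cerebro-cardiovascular events) occur at the exponential event time;
#' eGFR-halving events occur at the first annual visit whose measured
#' eGFR is at or below half the baseline; the composite truth is the
#' earlier of the two, with ties resolved in favour of the eGFR
#' component, mirroring the endpoint constructor. The generating
#' configuration is attached to each table as attribute `sim_config`.
#'
#' @param config a [sim_cohort_config()].
#' @return list with `enrollment`, `followup`, `truth` data frames and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_cohort_config"))
    stop_domain("config must be a sim_cohort_config")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_patients
  R <- config$accrual_years
  Tt <- R + config$followup_years

  low_comp <- stats::runif(n) < config$mixture_weight_low
  bw <- ifelse(low_comp,
               stats::rnorm(n, config$bw_low_mean, config$bw_low_sd),
               stats::rnorm(n, config$bw_normal_mean, config$bw_normal_sd))
  bw <- pmax(round(bw), 500)  # registries record whole grams
  lbw <- classify_lbw(bw)
  nephron <- pmax(config$nephron_intercept +
                    config$nephron_slope_per_g * bw +
                    stats::rnorm(n, 0, config$nephron_sd), 5e4)

  spec <- design_spec(event_rate_normal = config$event_rate_normal,
                      event_rate_lbw = config$event_rate_lbw,
                      rate_interpretation = config$rate_interpretation,
                      accrual_years = R,
                      followup_years = config$followup_years)
  lam <- design_hazards(spec)
  hazard <- ifelse(lbw == "low", lam[["lbw"]], lam[["normal"]])

  age <- round(stats::runif(n, 20, 75))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  e0 <- pmax(stats::rnorm(n, config$egfr_baseline_mean,
                          config$egfr_baseline_sd), 10)
  slope <- config$egfr_slope_mean +
    config$egfr_slope_per_100k * (nephron - 9e5) / 1e5
  entry <- stats::runif(n, 0, R)
  censor_years <- Tt - entry
  drop <- rep(FALSE, n)
  if (config$dropout_fraction > 0) {
    drop <- stats::runif(n) < config$dropout_fraction
    censor_years[drop] <- stats::runif(sum(drop), 0, censor_years[drop])
  }
  hard_time <- stats::rexp(n, hazard)
  hard_type <- sample(c("death", "renal_death", "mi", "angina", "stroke"),
                      n, replace = TRUE,
                      prob = c(0.2, 0.4, 0.15, 0.1, 0.15))
  hard_obs <- ifelse(hard_time <= censor_years, hard_time, NA)

  study_start <- as.Date("2011-01-01")
  biopsy_date <- study_start + round(entry * 365.25)
  pid <- sprintf("P%05d", seq_len(n))

  enrollment <- data.frame(
    patient_id = pid, biopsy_date = biopsy_date, age = age, sex = sex,
    serum_creatinine = creatinine_from_egfr(e0, age, sex),
    birth_weight_g = round(bw),
    body_weight_kg = round(stats::rnorm(n, 60, 10), 1),
    us_major_axis_cm = round(stats::rnorm(n, 10.5, 0.8), 1),
    us_minor_axis_cm = round(stats::rnorm(n, 4.5, 0.5), 1),
    us_transverse_axis_cm = round(stats::rnorm(n, 5.0, 0.5), 1),
    biopsied_side = sample(c("left", "right"), n, replace = TRUE),
    diagnosis = sample(c("IgA nephropathy", "diabetic nephropathy",
                         "nephrosclerosis", "minimal change disease",
                         "other"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  # the baseline eGFR exactly as the clinical module will recompute it
  e0_obs <- egfr_japanese(age, sex, enrollment$serum_creatinine)

  crit_cols <- c("chest_symptoms", "ecg_changes", "elevated_enzymes",
                 "ecg_abnormalities", "intervention_needed",
                 "symptoms_over_24h", "lesion_on_imaging",
                 "is_tia_or_asymptomatic")
  noise <- config$egfr_noise_sd

  # ---- annual visit rows (vectorised over all patient-years) ----
  end_time <- pmin(censor_years, ifelse(is.na(hard_obs), Inf, hard_obs))
  n_vis <- pmax(floor(end_time), 0)
  vid <- rep.int(seq_len(n), n_vis)
  k <- sequence(n_vis)
  vdate <- biopsy_date[vid] + round(k * 365.25)
  t_k <- years_between(biopsy_date[vid], vdate)
  e_k <- pmax(e0[vid] + slope[vid] * t_k +
                stats::rnorm(length(t_k), 0, noise), 1)
  cre_k <- creatinine_from_egfr(e_k, age[vid] + t_k, sex[vid])
  e_seen <- egfr_japanese(age[vid] + t_k, sex[vid], cre_k)
  halved <- e_seen <= 0.5 * e0_obs[vid]
  first_half_t <- rep(NA_real_, n)
  hh <- which(halved)
  if (length(hh)) {
    firsts <- hh[!duplicated(vid[hh])]
    first_half_t[vid[firsts]] <- t_k[firsts]
  }
  keep <- is.na(first_half_t[vid]) | t_k <= first_half_t[vid]
  annual <- data.frame(
    patient_id = pid[vid[keep]], visit_date = vdate[keep],
    serum_creatinine = cre_k[keep],
    status = "followed", event_type = "", event_date = as.Date(NA),
    stringsAsFactors = FALSE)

  # ---- hard-event rows for patients without an earlier eGFR halving ----
  eidx <- which(!is.na(hard_obs) & is.na(first_half_t))
  if (length(eidx)) {
    edate <- biopsy_date[eidx] + round(hard_obs[eidx] * 365.25)
    t_e <- years_between(biopsy_date[eidx], edate)
    e_e <- pmax(e0[eidx] + slope[eidx] * t_e +
                  stats::rnorm(length(eidx), 0, noise), 1)
    cre_e <- creatinine_from_egfr(e_e, age[eidx] + t_e, sex[eidx])
    erows <- data.frame(
      patient_id = pid[eidx], visit_date = edate,
      serum_creatinine = cre_e,
      status = "followed", event_type = hard_type[eidx],
      event_date = edate, stringsAsFactors = FALSE)
    # the event-day eGFR may itself cross the halving threshold, in which
    # case the composite ties in favour of the eGFR component
    e_seen_e <- egfr_japanese(age[eidx] + t_e, sex[eidx], cre_e)
    tie <- e_seen_e <= 0.5 * e0_obs[eidx]
    first_half_t[eidx[tie]] <- t_e[tie]
  } else {
    erows <- NULL
    t_e <- numeric()
  }

  # ---- one early final visit for patients with no other record ----
  fidx <- which(n_vis == 0 & is.na(hard_obs))
  if (length(fidx)) {
    fdate <- biopsy_date[fidx] + round(pmin(censor_years[fidx], 1) *
                                         365.25 / 2)
    t_f <- years_between(biopsy_date[fidx], fdate)
    e_f <- pmax(e0[fidx] + slope[fidx] * t_f +
                  stats::rnorm(length(fidx), 0, noise), 1)
    frows <- data.frame(
      patient_id = pid[fidx], visit_date = fdate,
      serum_creatinine = creatinine_from_egfr(e_f, age[fidx] + t_f,
                                              sex[fidx]),
      status = "followed", event_type = "", event_date = as.Date(NA),
      stringsAsFactors = FALSE)
    # a very low early measurement can already halve the baseline
    e_seen_f <- egfr_japanese(age[fidx] + t_f, sex[fidx],
                              frows$serum_creatinine)
    half_f <- e_seen_f <= 0.5 * e0_obs[fidx]
    first_half_t[fidx[half_f]] <- t_f[half_f]
  } else frows <- NULL

  followup <- rbind(annual, erows, frows)
  followup <- followup[order(followup$patient_id, followup$visit_date), ,
                       drop = FALSE]
  rownames(followup) <- NULL
  # ancillary clinical fields and empty adjudication criteria
  m <- nrow(followup)
  followup$body_weight_kg <-
    enrollment$body_weight_kg[match(followup$patient_id, pid)]
  followup$urinary_protein_gday <- round(stats::rlnorm(m, -0.7, 0.9), 2)
  followup$raas_blocker <- sample(c("yes", "no"), m, replace = TRUE)
  for (cc in crit_cols) followup[[cc]] <- NA
  is_ev <- nzchar(followup$event_type)
  mi_r <- is_ev & followup$event_type == "mi"
  followup$chest_symptoms[mi_r] <- TRUE
  followup$ecg_changes[mi_r] <- FALSE
  followup$elevated_enzymes[mi_r] <- TRUE
  an_r <- is_ev & followup$event_type == "angina"
  followup$ecg_abnormalities[an_r] <- TRUE
  followup$chest_symptoms[an_r] <- TRUE
  followup$intervention_needed[an_r] <- TRUE
  st_r <- is_ev & followup$event_type == "stroke"
  followup$symptoms_over_24h[st_r] <- TRUE
  followup$lesion_on_imaging[st_r] <- TRUE
  followup$is_tia_or_asymptomatic[st_r] <- FALSE
  # dropouts: the last record is the one where follow-up stopped
  if (any(drop)) {
    last_row <- tapply(seq_len(m), followup$patient_id, max)
    lost <- last_row[pid[drop]]
    followup$status[lost] <- "lost"
  }

  # ---- truth table ----
  last_t <- rep(0, n)
  tt <- years_between(biopsy_date[match(followup$patient_id, pid)],
                      followup$visit_date)
  mx <- tapply(tt, match(followup$patient_id, pid), max)
  last_t[as.integer(names(mx))] <- mx
  hard_t_years <- rep(NA_real_, n)
  if (length(eidx)) hard_t_years[eidx] <- t_e
  event <- ifelse(!is.na(first_half_t), 1L,
                  ifelse(!is.na(hard_obs), 1L, 0L))
  event_type <- ifelse(!is.na(first_half_t), "egfr_50pct_reduction",
                       ifelse(!is.na(hard_obs), hard_type, NA))
  time_years <- ifelse(!is.na(first_half_t), first_half_t,
                       ifelse(!is.na(hard_t_years), hard_t_years, last_t))
  # patients whose hard event came before any halving row but who kept
  # visits (possible only via the tie path) are already covered above
  truth <- data.frame(
    patient_id = pid, birth_weight_g = round(bw), lbw = lbw,
    nephron_number = round(nephron), hazard = hazard,
    entry_years = entry, censor_years = censor_years,
    event = event, event_type = event_type, time_years = time_years,
    baseline_egfr = e0_obs, egfr_slope_true = slope,
    stringsAsFactors = FALSE)

  meta <- unclass(config)
  attr(enrollment, "sim_config") <- meta
  attr(followup, "sim_config") <- meta
  attr(truth, "sim_config") <- meta
  list(enrollment = enrollment, followup = followup, truth = truth,
       config = config)
}
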