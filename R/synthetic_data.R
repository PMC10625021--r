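#' Configuration for the synthetic claims-data generator
#'
#' Builds the parameter set describing a four-archetype cohort of patients
#' initiating home non-invasive ventilation (NIV).  Each patient carries a
#' calendar of claims-style events in the 365 days before the index NIV
#' delivery (day 0): hospitalisation episodes for COPD exacerbation, stays
#' with a cardiology/respiratory diagnosis, ICU stays nested inside
#' episodes, and point events (consultations, pulmonary function tests,
#' sleep studies, oxygen-therapy start).  Post-index survival is
#' exponential with an archetype-specific hazard so that one-year mortality
#' is ordered archetype 1 < 2 < 3 < 4.
#'
#' Archetypes mirror the qualitative trajectory types of the source cohort:
#' \describe{
#'   \item{1}{NIV started in ambulatory settings (a configurable fraction
#'     with no hospitalisation at all) or after at most one hospitalisation.}
#'   \item{2}{At least two severe exacerbation stays in the final 6 months.}
#'   \item{3}{Frequent exacerbation stays spread over the whole year.}
#'   \item{4}{Several long-lasting stays (median episode length above one
#'     week, the conventional threshold for a long-lasting exacerbation).}
#' }
#'
#' @param n_patients number of patients to simulate.
#' @param cluster_weights archetype mixture proportions (length 4, sums
#'   to 1).  Default 0.66/0.12/0.21/0.01.
#' @param window_days length of the pre-index observation window in days.
#' @param ambulatory_prob per-archetype probability that NIV starts with no
#'   prior hospitalisation (nonzero only for archetype 1 by default; the
#'   default 0.317 makes the ambulatory subgroup about 21\% of the cohort).
#' @param slot_centers list of per-archetype episode-slot centres (negative
#'   days before the index).  Each archetype's trajectory shape is a set of
#'   typical hospitalisation positions -- archetype 2's mass sits in the
#'   final six months, archetype 3's is spread across the year -- realised
#'   with Gaussian jitter, which is what makes archetypes identifiable as
#'   temporal signatures rather than by raw event mass alone.
#' @param slot_probs list of per-archetype occurrence probabilities, one
#'   per slot (slots with probability 1 always occur).
#' @param slot_sd per-archetype jitter SD (days) around the slot centres.
#' @param a1_exac_prob probability that archetype 1's single stay is a COPD
#'   exacerbation rather than a cardiology/respiratory stay.
#' @param cr_rate Poisson rate of additional cardiology/respiratory stays
#'   over the window, per archetype.
#' @param dur_meanlog,dur_sdlog log-normal parameters of episode duration in
#'   days (rounded, floored at 1), per archetype.
#' @param icu_prob probability that an episode contains an ICU stay, per
#'   archetype.
#' @param mortality_rate_py exponential post-index death hazard per year,
#'   per archetype.
#' @param oxygen_prob,oxygen_lead_meanlog probability of an oxygen-therapy
#'   start before NIV and log-normal location of its lead time in days,
#'   per archetype.
#' @param consult_rates named yearly Poisson rates of point events.
#' @param age_mean,age_sd,male_prob covariate distributions per archetype
#'   (age truncated to [40, 100]).
#' @param comorbidity_prev matrix (archetype x flag) of comorbidity
#'   prevalences.
#' @param censor_days administrative end of follow-up after the index.
#' @param rng_seed root seed; per-patient substreams are derived from it so
#'   generation is order-independent.
#' @return an object of class \code{generator_config} (a validated list).
#' @seealso [generate_cohort()], [generate_patient()]
#' @export
generator_config <- function(
    n_patients = 5000L,
    cluster_weights = c(0.66, 0.12, 0.21, 0.01),
    window_days = 365L,
    ambulatory_prob = c(0.317, 0, 0, 0),
    slot_centers = list(c(-25),
                        c(-20, -75, -140),
                        c(-40, -130, -220, -310),
                        c(-30, -120, -210, -300)),
    slot_probs = list(c(1),
                      c(1, 1, 0.3),
                      c(1, 1, 0.8, 0.6),
                      c(1, 1, 1, 1)),
    slot_sd = c(5, 3, 3, 3),
    a1_exac_prob = 0.7,
    cr_rate = c(0.1, 0.1, 0.15, 0.15),
    dur_meanlog = log(c(12, 12, 10, 22)),
    dur_sdlog = c(0.2, 0.2, 0.2, 0.25),
    icu_prob = c(0.05, 0.15, 0.20, 0.30),
    mortality_rate_py = c(0.08, 0.20, 0.35, 1.20),
    oxygen_prob = c(0.42, 0.59, 0.67, 0.78),
    oxygen_lead_meanlog = log(c(51, 147, 276, 180)),
    consult_rates = c(gp_consult = 9, pulmonologist_consult = 0.3,
                      hospital_consult = 2, pft = 1.5, sleep_study = 0.3),
    age_mean = c(69, 72, 71, 71),
    age_sd = 11,
    male_prob = c(0.50, 0.53, 0.54, 0.56),
    comorbidity_prev = default_comorbidity_prev(),
    censor_days = 730L,
    rng_seed = 20150101L) {
  cfg <- list(
    n_patients = as.integer(n_patients), cluster_weights = cluster_weights,
    window_days = as.integer(window_days), ambulatory_prob = ambulatory_prob,
    slot_centers = slot_centers, slot_probs = slot_probs,
    slot_sd = slot_sd, a1_exac_prob = a1_exac_prob, cr_rate = cr_rate,
    dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog, icu_prob = icu_prob,
    mortality_rate_py = mortality_rate_py, oxygen_prob = oxygen_prob,
    oxygen_lead_meanlog = oxygen_lead_meanlog, consult_rates = consult_rates,
    age_mean = age_mean, age_sd = age_sd, male_prob = male_prob,
    comorbidity_prev = comorbidity_prev, censor_days = as.integer(censor_days),
    rng_seed = as.integer(rng_seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

default_comorbidity_prev <- function() {
  # Rows: archetype 1..4.  Prevalences follow the stratified comorbidity
  # pattern of the emulated cohort (most comorbidities rise with severity;
  # obesity and sleep apnoea do not).
  m <- rbind(
    c(undernutrition = 0.22, morbid_obesity = 0.46, sleep_apnoea = 0.33,
      hypertension_cvd = 0.72, diabetes = 0.29, psychiatric = 0.33),
    c(0.39, 0.46, 0.34, 0.83, 0.29, 0.43),
    c(0.38, 0.47, 0.36, 0.83, 0.38, 0.46),
    c(0.66, 0.38, 0.28, 0.83, 0.66, 0.62))
  rownames(m) <- paste0("archetype", 1:4)
  m
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("config error: n_patients must be positive")
  w <- cfg$cluster_weights
  if (length(w) != 4L || any(w < 0))
    stop("config error: cluster_weights must be 4 non-negative proportions")
  if (abs(sum(w) - 1) > 1e-12)
    stop("config error: cluster_weights must sum to 1")
  for (fld in c("cr_rate", "icu_prob", "mortality_rate_py",
                "oxygen_prob", "consult_rates")) {
    if (any(cfg[[fld]] < 0))
      stop(sprintf("config error: %s must be non-negative", fld))
  }
  for (a in 1:4) {
    if (length(cfg$slot_centers[[a]]) != length(cfg$slot_probs[[a]]))
      stop("config error: slot_centers and slot_probs lengths differ")
    if (any(cfg$slot_probs[[a]] < 0 | cfg$slot_probs[[a]] > 1))
      stop("config error: slot_probs must be probabilities")
    if (any(cfg$slot_centers[[a]] >= 0))
      stop("config error: slot_centers must be negative (pre-index) days")
  }
  if (cfg$window_days < 1L) stop("config error: window_days must be >= 1")
  invisible(cfg)
}

# Episode durations in whole days, >= 1 (log-normal, right-skewed like
# observed lengths of stay).
draw_duration <- function(n, archetype, cfg) {
  pmax(1L, as.integer(round(stats::rlnorm(n, cfg$dur_meanlog[archetype],
                                          cfg$dur_sdlog[archetype]))))
}

#' Generate one patient's pre-index event calendar
#'
#' Draws the event records for a single patient of the given archetype,
#' using the current RNG state (callers wanting reproducible per-patient
#' streams should seed before calling; [generate_cohort()] does this).
#' Events are integer day offsets relative to the index NIV delivery at
#' day 0; hospitalisation intervals are half-open \code{[start, end)} and
#' clipped to the observation window.
#'
#' @param archetype integer 1-4.
#' @param config a [generator_config()].
#' @param patient_id identifier placed in the returned rows.
#' @param ambulatory logical; force the no-hospitalisation variant
#'   (archetype 1 only).  \code{NULL} draws it from
#'   \code{config$ambulatory_prob}.
#' @return data.frame with columns patient_id, event_type, start_day,
#'   end_day.  Point events have \code{end_day == start_day}.  Always
#'   contains one \code{niv} row at day 0 and one \code{copd_drug}
#'   qualifying marker.
#' @export
generate_patient <- function(archetype, config = generator_config(),
                             patient_id = "p1", ambulatory = NULL) {
  if (!archetype %in% 1:4) stop("unknown archetype: ", archetype)
  cfg <- config
  Tw <- cfg$window_days
  if (is.null(ambulatory))
    ambulatory <- stats::runif(1) < cfg$ambulatory_prob[archetype]

  starts <- integer(0); durs <- integer(0); types <- character(0)
  if (!(archetype == 1L && ambulatory)) {
    if (archetype == 1L) {
      # at most one hospitalisation, close to the index
      is_exac <- stats::runif(1) < cfg$a1_exac_prob
      starts <- as.integer(round(stats::rnorm(1, cfg$slot_centers[[1L]][1L],
                                              cfg$slot_sd[1L])))
      starts <- pmin(pmax(starts, -Tw), -1L)
      durs <- draw_duration(1L, 1L, cfg)
      types <- if (is_exac) "copd_exacerbation_stay" else "cardio_resp_stay"
    } else {
      # exacerbation episodes realised from the archetype's temporal slots
      probs <- cfg$slot_probs[[archetype]]
      occ <- stats::runif(length(probs)) < probs
      occ[probs >= 1] <- TRUE
      ex_starts <- as.integer(round(stats::rnorm(
        sum(occ), cfg$slot_centers[[archetype]][occ],
        cfg$slot_sd[archetype])))
      ex_starts <- pmin(pmax(ex_starts, -Tw), -1L)
      if (archetype == 2L) {
        # archetype 2 invariant: >= 2 exacerbation stays start in the
        # final 6 months
        ex_starts[1:2] <- pmin(pmax(ex_starts[1:2], -179L), -1L)
      }
      n_ex <- length(ex_starts)
      n_cr <- stats::rpois(1L, cfg$cr_rate[archetype])
      cr_starts <- if (n_cr > 0L)
        -as.integer(sample.int(Tw, n_cr, replace = TRUE)) else integer(0)
      starts <- c(ex_starts, cr_starts)
      durs <- draw_duration(length(starts), archetype, cfg)
      types <- c(rep("copd_exacerbation_stay", n_ex),
                 rep("cardio_resp_stay", n_cr))
    }
    # clip to [-Tw, 0): stays truncate at the index day
    ends <- pmin(starts + durs, 0L)
    starts <- pmax(starts, -Tw)

    # ICU stays nested at the start of an episode
    icu <- stats::runif(length(starts)) < cfg$icu_prob[archetype]
    icu_start <- starts[icu]
    icu_end <- pmin(icu_start + 1L + stats::rpois(sum(icu), 2L), ends[icu])
    types <- c(types, rep("icu_stay", sum(icu)))
    starts <- c(starts, icu_start)
    ends2 <- c(ends, icu_end)
  } else {
    ends2 <- integer(0)
  }

  # point events: homogeneous Poisson over the window
  pt_types <- character(0); pt_days <- integer(0)
  for (ev in names(cfg$consult_rates)) {
    k <- stats::rpois(1L, cfg$consult_rates[[ev]] * Tw / 365)
    if (k > 0L) {
      pt_types <- c(pt_types, rep(ev, k))
      pt_days <- c(pt_days, -as.integer(sample.int(Tw, k, replace = TRUE)))
    }
  }
  if (stats::runif(1) < cfg$oxygen_prob[archetype]) {
    lead <- as.integer(round(stats::rlnorm(
      1, cfg$oxygen_lead_meanlog[archetype], 0.6)))
    pt_types <- c(pt_types, "oxygen_start")
    pt_days <- c(pt_days, -min(max(lead, 1L), Tw))
  }
  # COPD qualifying marker (stands in for the diagnosis/drug algorithm)
  pt_types <- c(pt_types, "copd_drug")
  pt_days <- c(pt_days, -as.integer(sample.int(Tw, 1L)))

  data.frame(
    patient_id = patient_id,
    event_type = c(types, pt_types, "niv"),
    start_day = c(starts, pt_days, 0L),
    end_day = c(ends2, pt_days, 0L),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of pre-NIV health trajectories
#'
#' Draws \code{config$n_patients} patients from the archetype mixture and
#' returns their event calendars, covariates and ground-truth archetype
#' labels.  Deterministic given \code{config$rng_seed}: every patient has
#' its own RNG substream derived from the root seed, so the output does not
#' depend on generation order.
#'
#' @param config a [generator_config()].
#' @return list with components \code{events} (long event table:
#'   patient_id, event_type, start_day, end_day), \code{covariates}
#'   (patient_id, archetype-independent id columns, age, sex, comorbidity
#'   flags, prescriber, setting, time_days, death) and \code{truth}
#'   (patient_id, archetype).  \code{time_days} is follow-up from index to
#'   death or administrative censoring; \code{death} is the event
#'   indicator.
#' @export
generate_cohort <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  n <- cfg$n_patients
  set.seed(cfg$rng_seed)
  arch <- sample.int(4L, n, replace = TRUE, prob = cfg$cluster_weights)
  ids <- sprintf("p%06d", seq_len(n))

  flags <- colnames(cfg$comorbidity_prev)
  ev_list <- vector("list", n)
  cov_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(cfg$rng_seed, i))
    a <- arch[i]
    ev_list[[i]] <- generate_patient(a, cfg, patient_id = ids[i])
    age <- min(max(round(stats::rnorm(1, cfg$age_mean[a], cfg$age_sd)), 40), 100)
    sex <- if (stats::runif(1) < cfg$male_prob[a]) "male" else "female"
    com <- as.integer(stats::runif(length(flags)) < cfg$comorbidity_prev[a, ])
    names(com) <- flags
    ttd <- stats::rexp(1, cfg$mortality_rate_py[a] / 365)
    death <- as.integer(ttd <= cfg$censor_days)
    time_days <- max(1, min(ttd, cfg$censor_days))
    prescriber <- sample(c("hospital_physician", "private_pulmonologist",
                           "other"), 1L, prob = c(0.65, 0.26, 0.09))
    amb <- !any(ev_list[[i]]$event_type %in%
                  c("copd_exacerbation_stay", "cardio_resp_stay", "icu_stay"))
    setting <- if (amb) sample(c("home", "private_practice"), 1L)
               else sample(c("hospital", "home", "private_practice"), 1L,
                           prob = c(0.74, 0.13, 0.13))
    cov_rows[[i]] <- data.frame(
      patient_id = ids[i], age = age, sex = sex,
      as.list(com), prescriber = prescriber, setting = setting,
      time_days = round(time_days, 1), death = death,
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  truth <- data.frame(patient_id = ids, archetype = arch,
                      stringsAsFactors = FALSE)
  list(events = events, covariates = covariates, truth = truth)
}
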