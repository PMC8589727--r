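#' Configuration for the synthetic EHR generator
#'
#' The generator emulates the data structure the analysis assumes: prevalent
#' liver disease preceding an incident cardiovascular indication, drug-naive
#' first prescriptions, refill streams following four adherence archetypes,
#' AR(1) INR trajectories for warfarin users, laboratory panels sufficient
#' for the clinical scores, censoring events, and stroke/bleeding outcomes
#' with configurable hazard multipliers.
#'
#' Default rates are set to the marginal conditions of the study population
#' the pipeline targets: roughly one in five liver patients (one in three
#' non-liver) prescribed after an indication, a primary non-adherence share
#' near 8%, and archetype weights that populate all four cells of the joint
#' adherence-by-persistence classification.
#'
#' @param n_patients Number of synthetic persons.
#' @param liver_prevalence Fraction with prevalent liver disease.
#' @param liver_subtype_weights Named non-negative weights over the six
#'   liver conditions.
#' @param indication_rate Per-year hazard of the incident cardiovascular
#'   indication after cohort entry (after the first liver diagnosis for
#'   liver patients).
#' @param p_prescribed_liver,p_prescribed_nonliver Probability of receiving
#'   a prescription of the indicated class after the indication.
#' @param archetype_weights Named non-negative weights over
#'   `primary_nonadherent`, `steady_refiller`, `irregular_refiller`,
#'   `early_discontinuer`.
#' @param refill_mean_days,refill_sd_days Refill-interval mean/sd for
#'   steady refillers (also the short component of irregular refillers and
#'   the interval of early discontinuers).
#' @param irregular_long_mean_days,irregular_long_sd_days,irregular_p_long
#'   Long-interval component of irregular refillers and its mixing weight.
#' @param early_stop_p Success probability of the geometric refill count of
#'   early discontinuers.
#' @param switch_probability Probability that a refilling patient switches
#'   to another drug of the same class mid-stream.
#' @param p_pre_indication_rx Probability that a prescribed patient also
#'   carries a planted same-class prescription before the indication
#'   (violating drug-naivety; used to exercise the new-user filter,
#'   default 0).
#' @param inr_mean,inr_sd,inr_ar1 Stationary mean, stationary sd and lag-1
#'   autocorrelation of the INR trajectory of warfarin users; measurements
#'   are spaced uniformly 14-42 days apart.
#' @param stroke_base_hazard Per-year stroke hazard in the reference
#'   uncovered-time category.
#' @param stroke_hr_by_uncovered_category Five multipliers, one per
#'   uncovered-time category (`<1 week` first, the reference).
#' @param bleed_base_hazard Per-year non-fatal bleeding hazard at PDC 0.
#' @param bleed_hr_per_10pct_pdc Bleeding hazard ratio per 10-percentage-
#'   point PDC increment.
#' @param censor_rate Per-year hazard of death/deregistration after the
#'   indication.
#' @param class_balance Probability that a patient's indication is for
#'   anticoagulants (vs antiplatelets).
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   tables byte for byte.
#' @return A list with class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 2000L,
                             liver_prevalence = 0.30,
                             liver_subtype_weights = c(
                               ALD = 0.28, autoimmune_liver_disease = 0.06,
                               cirrhosis = 0.31, HBV = 0.03, HCV = 0.06,
                               NAFLD = 0.26
                             ),
                             indication_rate = 0.10,
                             p_prescribed_liver = 0.21,
                             p_prescribed_nonliver = 0.335,
                             archetype_weights = c(
                               primary_nonadherent = 0.08,
                               steady_refiller = 0.30,
                               irregular_refiller = 0.42,
                               early_discontinuer = 0.20
                             ),
                             refill_mean_days = 30,
                             refill_sd_days = 5,
                             irregular_long_mean_days = 80,
                             irregular_long_sd_days = 25,
                             irregular_p_long = 0.35,
                             early_stop_p = 0.4,
                             switch_probability = 0.08,
                             p_pre_indication_rx = 0,
                             inr_mean = 2.5,
                             inr_sd = 0.5,
                             inr_ar1 = 0.6,
                             stroke_base_hazard = 0.02,
                             stroke_hr_by_uncovered_category = c(1, 1, 1, 1.22, 1.20),
                             bleed_base_hazard = 0.015,
                             bleed_hr_per_10pct_pdc = 1.18,
                             censor_rate = 0.05,
                             class_balance = 0.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

archetype_levels <- c(
  "primary_nonadherent", "steady_refiller", "irregular_refiller",
  "early_discontinuer"
)

english_regions <- c(
  "north_east", "north_west", "yorkshire_and_humber", "east_midlands",
  "west_midlands", "east_of_england", "london", "south_east", "south_west"
)

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_patients > 0,
    cfg$liver_prevalence >= 0, cfg$liver_prevalence <= 1,
    length(cfg$liver_subtype_weights) == 6,
    all(cfg$liver_subtype_weights >= 0), sum(cfg$liver_subtype_weights) > 0,
    all(names(cfg$archetype_weights) == archetype_levels) ||
      setequal(names(cfg$archetype_weights), archetype_levels),
    length(cfg$archetype_weights) == 4,
    all(cfg$archetype_weights >= 0),
    cfg$indication_rate > 0, cfg$censor_rate > 0,
    cfg$stroke_base_hazard > 0, cfg$bleed_base_hazard > 0,
    length(cfg$stroke_hr_by_uncovered_category) == 5,
    all(cfg$stroke_hr_by_uncovered_category > 0),
    cfg$bleed_hr_per_10pct_pdc > 0,
    cfg$p_prescribed_liver >= 0, cfg$p_prescribed_liver <= 1,
    cfg$p_prescribed_nonliver >= 0, cfg$p_prescribed_nonliver <= 1,
    cfg$switch_probability >= 0, cfg$switch_probability <= 1,
    cfg$p_pre_indication_rx >= 0, cfg$p_pre_indication_rx <= 1,
    abs(cfg$inr_ar1) < 1, cfg$inr_sd > 0
  )
  if (sum(cfg$archetype_weights) <= 0) {
    abort("generator_config: archetype_weights must have positive sum")
  }
  invisible(cfg)
}

rnorm_trunc1 <- function(n, mean, sd) {
  pmax(1, round(rnorm(n, mean, sd)))
}

# Index-drug sampling weights within each class; warfarin and aspirin
# dominate first prescriptions in the population this emulates.
index_drug_weights <- list(
  anticoagulant = c(
    apixaban = 0.15, dabigatran = 0.05, edoxaban = 0.03,
    rivaroxaban = 0.17, warfarin = 0.60
  ),
  antiplatelet = c(
    aspirin = 0.60, clopidogrel = 0.28, dipyridamole = 0.07,
    prasugrel = 0.02, ticagrelor = 0.03
  )
)

#' Generate a linked synthetic EHR cohort
#'
#' Produces the four analysis tables plus a `truth` table recording every
#' latent draw (liver status, archetype, index drug, planted pre-indication
#' prescriptions, ...), so downstream modules can be checked against the
#' generator's own bookkeeping.
#'
#' Structural guarantees: each liver patient's earliest liver diagnosis
#' strictly precedes any indication event; no same-class prescription
#' precedes the indication unless explicitly planted via
#' `p_pre_indication_rx`; refill streams follow the drawn archetype;
#' warfarin users carry an INR series; every patient has the laboratory
#' panel needed by the Child-Pugh and FIB-4 scores within 90 days of the
#' indication; identical seeds give identical tables.
#'
#' @param config A [generator_config()].
#' @param study A [study_config()] providing the calendar anchors.
#' @return A list of class `"thromb_sim"` with elements `patients`,
#'   `prescriptions`, `diagnoses`, `labs` (validated tibbles) and `truth`.
#' @examples
#' sim <- simulate_ehr(generator_config(n_patients = 50, seed = 42))
#' nrow(sim$patients)
#' @export
simulate_ehr <- function(config = generator_config(), study = study_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, simulate_ehr_impl(config, study))
}

simulate_ehr_impl <- function(cfg, study) {
  n <- cfg$n_patients
  admin_end <- study$admin_censor_date
  start0 <- study$study_start

  ids <- sprintf("p%06d", seq_len(n))
  sex <- sample(sex_levels, n, replace = TRUE)
  region <- sample(english_regions, n, replace = TRUE)
  reg_start <- start0 + round(runif(n, 0, 8 * 365.25))
  age_at_reg <- runif(n, 35, 85)
  birth_year <- as.integer(format(reg_start, "%Y")) - floor(age_at_reg)

  liver <- runif(n) < cfg$liver_prevalence
  sub_w <- cfg$liver_subtype_weights[liver_conditions]
  liver_first <- rep(as.Date(NA), n)
  subtype_rows <- vector("list", n)
  for (i in which(liver)) {
    k <- 1L + (runif(1) < 0.15)
    subs <- sample(liver_conditions, k, prob = sub_w)
    d1 <- reg_start[i] + round(runif(1, 180, 4 * 365))
    dates <- c(d1, if (k > 1) d1 + round(runif(1, 30, 730)))
    liver_first[i] <- d1
    subtype_rows[[i]] <- tibble(
      patient_id = ids[i], event_date = dates, condition = subs,
      source = "primary_care"
    )
  }

  ind_class <- if_else(runif(n) < cfg$class_balance, "anticoagulant", "antiplatelet")
  entry <- as.Date(ifelse(liver, liver_first, reg_start), origin = "1970-01-01")
  ind_delay <- 1 + round(rexp(n, cfg$indication_rate / 365.25))
  ind_date <- entry + ind_delay
  # keep indications observable: redraw any that overshoot the admin censor
  over <- which(ind_date > admin_end - 90)
  ind_date[over] <- entry[over] +
    pmax(1, round(runif(length(over), 1, pmax(2, as.numeric(admin_end - 90 - entry[over])))))
  ind_cond <- ifelse(
    ind_class == "anticoagulant", "atrial_fibrillation",
    sample(indication_conditions$antiplatelet, n, replace = TRUE)
  )

  cens_days <- round(rexp(n, cfg$censor_rate / 365.25))
  cens_date <- ind_date + cens_days
  death_date <- rep(as.Date(NA), n)
  dereg_date <- rep(as.Date(NA), n)
  cens_hits <- which(cens_date < admin_end)
  is_death <- runif(n) < 0.5
  death_date[cens_hits[is_death[cens_hits]]] <- cens_date[cens_hits[is_death[cens_hits]]]
  dereg_date[cens_hits[!is_death[cens_hits]]] <- cens_date[cens_hits[!is_death[cens_hits]]]
  followup_end <- pmin(cens_date, admin_end)

  p_rx <- if_else(liver, cfg$p_prescribed_liver, cfg$p_prescribed_nonliver)
  prescribed <- runif(n) < p_rx
  arche_w <- cfg$archetype_weights[archetype_levels]
  archetype <- rep(NA_character_, n)
  archetype[prescribed] <- sample(
    archetype_levels, sum(prescribed),
    replace = TRUE, prob = arche_w
  )

  rx_rows <- vector("list", n)
  inr_rows <- vector("list", n)
  index_drug <- rep(NA_character_, n)
  switched <- rep(FALSE, n)
  pre_rx <- rep(FALSE, n)

  for (i in which(prescribed)) {
    cls <- ind_class[i]
    pool <- drugs_in_class(cls)
    w <- index_drug_weights[[cls]][pool]
    drug0 <- sample(pool, 1, prob = w)
    index_drug[i] <- drug0
    first_issue <- ind_date[i] + round(runif(1, 0, 30))
    stream_end <- followup_end[i]

    issue_dates <- first_issue
    if (archetype[i] != "primary_nonadherent") {
      n_refills <- switch(archetype[i],
        early_discontinuer = 1L + rgeom(1, cfg$early_stop_p),
        200L
      )
      gaps <- switch(archetype[i],
        steady_refiller = rnorm_trunc1(n_refills, cfg$refill_mean_days, cfg$refill_sd_days),
        early_discontinuer = rnorm_trunc1(n_refills, cfg$refill_mean_days, cfg$refill_sd_days),
        irregular_refiller = {
          long <- runif(n_refills) < cfg$irregular_p_long
          ifelse(long,
            rnorm_trunc1(n_refills, cfg$irregular_long_mean_days, cfg$irregular_long_sd_days),
            rnorm_trunc1(n_refills, cfg$refill_mean_days, cfg$refill_sd_days)
          )
        }
      )
      issue_dates <- first_issue + cumsum(c(0, gaps))
      issue_dates <- issue_dates[issue_dates <= stream_end]
      if (length(issue_dates) == 0) issue_dates <- first_issue
    }

    drugs <- rep(drug0, length(issue_dates))
    if (length(issue_dates) >= 3 && runif(1) < cfg$switch_probability) {
      pos <- sample(2:length(issue_dates), 1)
      alt <- sample(setdiff(pool, drug0), 1)
      drugs[pos:length(drugs)] <- alt
      switched[i] <- TRUE
    }

    if (cfg$p_pre_indication_rx > 0 && runif(1) < cfg$p_pre_indication_rx) {
      pre_date <- ind_date[i] - round(runif(1, 90, 720))
      issue_dates <- c(pre_date, issue_dates)
      drugs <- c(sample(pool, 1, prob = w), drugs)
      pre_rx[i] <- TRUE
    }

    rx_rows[[i]] <- tibble(
      patient_id = ids[i], issue_date = issue_dates, drug = drugs
    )

    if (drug0 == "warfarin") {
      inr_end <- min(stream_end, first_issue + 365)
      t <- first_issue
      vals <- numeric(0)
      dates <- as.Date(character(0))
      x <- rnorm(1, cfg$inr_mean, cfg$inr_sd)
      innov_sd <- cfg$inr_sd * sqrt(1 - cfg$inr_ar1^2)
      while (t <= inr_end) {
        dates <- c(dates, t)
        vals <- c(vals, min(19, max(0.6, x)))
        x <- cfg$inr_mean + cfg$inr_ar1 * (x - cfg$inr_mean) + rnorm(1, 0, innov_sd)
        t <- t + round(runif(1, 14, 42))
      }
      if (length(vals) > 0) {
        inr_rows[[i]] <- tibble(
          patient_id = ids[i], date = as.Date(dates, origin = "1970-01-01"),
          analyte = "INR", value = round(vals, 2)
        )
      }
    }
  }

  # comorbidities before the indication (covariates for the risk scores)
  como <- tibble(
    patient_id = rep(ids, 9),
    condition = rep(c(
      "hypertension", "diabetes", "heart_failure", "vascular_disease",
      "chronic_kidney_disease", "proton_pump_inhibitor_use",
      "ascites", "varices", "hepatic_encephalopathy"
    ), each = n),
    p = rep(c(0.45, 0.20, 0.12, 0.15, 0.12, 0.25, 0.12, 0.08, 0.06), each = n),
    liver = rep(liver, 9),
    ind = rep(ind_date, 9),
    reg = rep(reg_start, 9)
  ) |>
    filter(
      runif(dplyr::n()) < .data$p,
      # liver complications only arise in liver patients
      !(.data$condition %in% c("ascites", "varices", "hepatic_encephalopathy") & !.data$liver)
    ) |>
    mutate(
      event_date = .data$ind - round(runif(dplyr::n(), 30, 1500)),
      event_date = pmax(.data$event_date, .data$reg + 1),
      source = "primary_care"
    ) |>
    select("patient_id", "event_date", "condition", "source")

  indications <- tibble(
    patient_id = ids, event_date = ind_date, condition = ind_cond,
    source = "secondary_care"
  )

  diagnoses <- bind_rows(
    bind_rows(subtype_rows), indications, como
  ) |>
    arrange(.data$patient_id, .data$event_date, .data$condition)

  # laboratory panel near the indication: enough for Child-Pugh and FIB-4
  lab_date <- ind_date + round(runif(n, -90, 90))
  lab_date <- pmax(lab_date, reg_start + 1)
  bili_meanlog <- if_else(liver, log(1.6), log(0.8))
  labs_panel <- tibble(
    patient_id = rep(ids, 5),
    date = rep(lab_date, 5),
    analyte = rep(c("bilirubin_total", "albumin", "AST", "ALT", "platelets"), each = n),
    value = c(
      round(exp(rnorm(n, bili_meanlog, 0.55)), 2),
      round(pmax(1.5, rnorm(n, if_else(liver, 3.4, 4.1), 0.5)), 2),
      round(exp(rnorm(n, if_else(liver, log(55), log(28)), 0.45)), 1),
      round(exp(rnorm(n, if_else(liver, log(45), log(30)), 0.45)), 1),
      round(pmax(20, rnorm(n, if_else(liver, 160, 250), 60)), 0)
    )
  )
  labs <- bind_rows(labs_panel, bind_rows(inr_rows)) |>
    arrange(.data$patient_id, .data$date, .data$analyte)

  patients <- tibble(
    patient_id = ids, sex = sex, birth_year = birth_year, region = region,
    registration_start = reg_start, registration_end = dereg_date,
    death_date = death_date, practice_last_collection = as.Date(NA)
  )

  prescriptions <- bind_rows(rx_rows) |>
    arrange(.data$patient_id, .data$issue_date, .data$drug)

  truth <- tibble(
    patient_id = ids, liver = liver, liver_first_date = liver_first,
    indication_class = ind_class, indication_condition = ind_cond,
    indication_date = ind_date, followup_end = followup_end,
    prescribed = prescribed, archetype = archetype,
    index_drug = index_drug, switched = switched,
    pre_indication_rx = pre_rx
  )

  out <- list(
    patients = validate_ehr_table(patients, "patients"),
    prescriptions = validate_ehr_table(prescriptions, "prescriptions"),
    diagnoses = validate_ehr_table(diagnoses, "diagnoses"),
    labs = validate_ehr_table(labs, "labs"),
    truth = truth,
    config = cfg
  )
  class(out) <- "thromb_sim"
  out
}

#' @export
print.thromb_sim <- function(x, ...) {
  cat(sprintf(
    "<thromb_sim> %d patients, %d prescriptions, %d diagnoses, %d labs (seed %d)\n",
    nrow(x$patients), nrow(x$prescriptions), nrow(x$diagnoses), nrow(x$labs),
    x$config$seed
  ))
  invisible(x)
}

#' Write the simulated tables to a directory
#'
#' Writes `patients.csv`, `prescriptions.csv`, `diagnoses.csv`, `labs.csv`
#' plus `provenance.json` echoing the generator configuration.
#'
#' @param sim A `thromb_sim` from [simulate_ehr()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "thromb_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in ehr_table_kinds) {
    write_ehr_table(sim[[kind]], file.path(dir, paste0(kind, ".csv")), kind)
  }
  cfg <- sim$config
  jsonlite::write_json(
    cfg[setdiff(names(cfg), "")],
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read four simulated (or real-format) tables from a directory
#'
#' @param dir Directory holding `patients.csv`, `prescriptions.csv`,
#'   `diagnoses.csv`, `labs.csv`.
#' @return Named list of validated tibbles.
#' @export
read_ehr_tables <- function(dir) {
  setNames(
    lapply(ehr_table_kinds, function(kind) {
      read_ehr_table(file.path(dir, paste0(kind, ".csv")), kind)
    }),
    ehr_table_kinds
  )
}

#' Simulate stroke and bleeding outcome events from derived summaries
#'
#' Event times are exponential. The stroke hazard is the per-year base
#' hazard times the multiplier of the patient's uncovered-time category;
#' the bleeding hazard is the base hazard times
#' `bleed_hr_per_10pct_pdc^(10 * pdc)`. Events beyond the patient's
#' follow-up are censored.
#'
#' @param summaries Tibble with columns `patient_id`, `followup_days`,
#'   `uncovered_category` (integer 1-5 or factor with the five category
#'   labels) and `pdc`; an optional `index_date` column dates the events.
#' @param config A [generator_config()] carrying the hazards.
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with `patient_id`, `outcome` (`stroke_ischaemic`,
#'   `bleeding_nonfatal`), `time_days`, `event`, and `event_date` when an
#'   index date was supplied.
#' @export
simulate_outcomes <- function(summaries, config = generator_config(), seed = NULL) {
  stopifnot(all(c("patient_id", "followup_days", "uncovered_category", "pdc")
  %in% names(summaries)))
  seed <- seed %||% config$seed
  withr::with_seed(seed, {
    cat_idx <- summaries$uncovered_category
    if (is.factor(cat_idx) || is.character(cat_idx)) {
      cat_idx <- match(as.character(cat_idx), uncovered_category_labels)
    }
    stopifnot(all(cat_idx %in% 1:5))
    n <- nrow(summaries)
    h_stroke <- config$stroke_base_hazard / 365.25 *
      config$stroke_hr_by_uncovered_category[cat_idx]
    h_bleed <- config$bleed_base_hazard / 365.25 *
      config$bleed_hr_per_10pct_pdc^(10 * summaries$pdc)
    t_stroke <- rexp(n, h_stroke)
    t_bleed <- rexp(n, h_bleed)
    out <- bind_rows(
      tibble(
        patient_id = summaries$patient_id, outcome = "stroke_ischaemic",
        time_days = pmin(t_stroke, summaries$followup_days),
        event = t_stroke <= summaries$followup_days
      ),
      tibble(
        patient_id = summaries$patient_id, outcome = "bleeding_nonfatal",
        time_days = pmin(t_bleed, summaries$followup_days),
        event = t_bleed <= summaries$followup_days
      )
    )
    if ("index_date" %in% names(summaries)) {
      idx <- summaries[, c("patient_id", "index_date")]
      out <- left_join(out, idx, by = "patient_id") |>
        mutate(event_date = .data$index_date + round(.data$time_days)) |>
        select(-"index_date")
      out$event_date[!out$event] <- NA
    }
    out
  })
}
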