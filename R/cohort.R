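#' Classify prevalent liver disease per patient
#'
#' A patient carries liver disease if they have at least one diagnosis
#' among the six chronic liver conditions (ALD, autoimmune liver disease,
#' cirrhosis, HBV, HCV, NAFLD); the first liver date is the earliest such
#' event and a patient may carry several subtypes.
#'
#' @param diagnoses A validated diagnoses tibble.
#' @return Tibble with one row per patient appearing in `diagnoses`:
#'   `patient_id`, `liver_status` (`with_liver_disease` /
#'   `without_liver_disease`), `liver_subtypes` (list column),
#'   `liver_first_date` (`NA` when without).
#' @export
classify_liver_status <- function(diagnoses) {
  liver_events <- diagnoses |>
    filter(.data$condition %in% liver_conditions) |>
    group_by(.data$patient_id) |>
    summarise(
      liver_subtypes = list(sort(unique(.data$condition))),
      liver_first_date = min(.data$event_date),
      .groups = "drop"
    )
  diagnoses |>
    distinct(.data$patient_id) |>
    left_join(liver_events, by = "patient_id") |>
    mutate(
      liver_status = if_else(is.na(.data$liver_first_date),
        "without_liver_disease", "with_liver_disease"
      ),
      liver_subtypes = purrr::map(.data$liver_subtypes, ~ .x %||% character(0))
    ) |>
    select("patient_id", "liver_status", "liver_subtypes", "liver_first_date")
}

#' Find each patient's incident indication for one drug class
#'
#' The indication for anticoagulants is the earliest atrial fibrillation
#' event; for antiplatelets, the earliest event among myocardial
#' infarction, peripheral arterial disease, unstable angina and transient
#' ischaemic attack. For patients with liver disease the cohort is
#' restricted to indications incident to the liver disease: the earliest
#' qualifying event must fall strictly after the first liver diagnosis,
#' otherwise the patient has no qualifying indication in the liver-incident
#' cohort. Patients without liver disease use their earliest event.
#'
#' @param diagnoses A validated diagnoses tibble.
#' @param liver_info Output of [classify_liver_status()].
#' @param class `"anticoagulant"` or `"antiplatelet"`.
#' @return Tibble `patient_id`, `indication_condition`, `indication_date`
#'   (patients with no qualifying indication are absent).
#' @export
find_incident_indication <- function(diagnoses, liver_info, class) {
  class <- match.arg(class, drug_classes)
  conds <- indication_conditions[[class]]
  earliest <- diagnoses |>
    filter(.data$condition %in% conds) |>
    group_by(.data$patient_id) |>
    slice_min(.data$event_date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id",
      indication_condition = "condition",
      indication_date = "event_date"
    )
  earliest |>
    left_join(
      liver_info |> select("patient_id", "liver_status", "liver_first_date"),
      by = "patient_id"
    ) |>
    filter(
      .data$liver_status != "with_liver_disease" |
        .data$indication_date > .data$liver_first_date
    ) |>
    select("patient_id", "indication_condition", "indication_date")
}

#' Remove patients with same-class prescriptions before the indication
#'
#' Implements the new-user (drug-naive) restriction: any member with a
#' prescription of any drug in the indication class strictly before the
#' indication date is dropped. Prescriptions of the other class do not
#' disqualify.
#'
#' @param members Tibble with `patient_id`, `indication_class`,
#'   `indication_date`.
#' @param prescriptions A validated prescriptions tibble.
#' @return `members` restricted to drug-naive patients.
#' @export
apply_drug_naive_filter <- function(members, prescriptions) {
  prior <- members |>
    inner_join(prescriptions, by = "patient_id", relationship = "one-to-many") |>
    filter(
      .data$drug_class == .data$indication_class,
      .data$issue_date < .data$indication_date
    ) |>
    distinct(.data$patient_id)
  anti_join(members, prior, by = "patient_id")
}

followup_reason_priority <- c(
  "endpoint", "death", "last_collection", "deregistration", "admin_censor"
)

#' Resolve the end of follow-up
#'
#' Follow-up ends at the earliest of: primary endpoint, death, last data
#' collection of the practice, deregistration, or administrative
#' censoring. Ties on the same day are labelled by the priority
#' endpoint > death > last_collection > deregistration > admin_censor.
#'
#' @param endpoint_date,death_date,last_collection_date,deregistration_date
#'   Date vectors (may be `NA`).
#' @param admin_censor_date Scalar administrative censoring date (always
#'   present).
#' @return Tibble `followup_end`, `followup_end_reason`.
#' @export
resolve_followup_end <- function(endpoint_date = as.Date(NA),
                                 death_date = as.Date(NA),
                                 last_collection_date = as.Date(NA),
                                 deregistration_date = as.Date(NA),
                                 admin_censor_date) {
  if (anyNA(admin_censor_date)) {
    abort("admin_censor_date must always be present")
  }
  n <- max(
    length(endpoint_date), length(death_date), length(last_collection_date),
    length(deregistration_date), length(admin_censor_date)
  )
  cand <- cbind(
    rep(as.numeric(as.Date(endpoint_date)), length.out = n),
    rep(as.numeric(as.Date(death_date)), length.out = n),
    rep(as.numeric(as.Date(last_collection_date)), length.out = n),
    rep(as.numeric(as.Date(deregistration_date)), length.out = n),
    rep(as.numeric(as.Date(admin_censor_date)), length.out = n)
  )
  min_val <- apply(cand, 1, min, na.rm = TRUE)
  # which.min over columns in priority order breaks same-day ties correctly
  reason_idx <- vapply(
    seq_len(n),
    function(i) which(cand[i, ] == min_val[i])[1],
    integer(1)
  )
  tibble(
    followup_end = as.Date(min_val, origin = "1970-01-01"),
    followup_end_reason = followup_reason_priority[reason_idx]
  )
}

#' Build the analysis cohort for one drug class
#'
#' Chains liver classification, incident-indication discovery, the age
#' restriction (30 or older at indication), the drug-naive filter, and
#' follow-up resolution into one member table — the denominator for the
#' prescribing-prevalence analysis and the entry point for adherence and
#' persistence.
#'
#' @param tables Named list with `patients`, `prescriptions`, `diagnoses`
#'   (validated tibbles, as returned by [simulate_ehr()] or
#'   [read_ehr_tables()]).
#' @param class `"anticoagulant"` or `"antiplatelet"`.
#' @param config A [study_config()].
#' @param endpoint_dates Optional tibble `patient_id`, `endpoint_date`
#'   giving the first primary-endpoint event after the indication.
#' @param drug_naive Apply the new-user filter (default `TRUE`).
#' @return Cohort member tibble: `patient_id`, `liver_status`,
#'   `liver_subtypes`, `liver_first_date`, `indication_class`,
#'   `indication_condition`, `indication_date`, `followup_end`,
#'   `followup_end_reason`, `age_at_indication`, `sex`, `region`.
#' @export
build_cohort <- function(tables, class, config = study_config(),
                         endpoint_dates = NULL, drug_naive = TRUE) {
  class <- match.arg(class, drug_classes)
  liver_info <- classify_liver_status(tables$diagnoses)
  members <- find_incident_indication(tables$diagnoses, liver_info, class) |>
    mutate(indication_class = class) |>
    left_join(liver_info, by = "patient_id") |>
    inner_join(
      tables$patients |>
        select(
          "patient_id", "sex", "birth_year", "region", "registration_start",
          "registration_end", "death_date", "practice_last_collection"
        ),
      by = "patient_id"
    ) |>
    mutate(
      age_at_indication =
        as.integer(format(.data$indication_date, "%Y")) - .data$birth_year
    ) |>
    filter(
      .data$age_at_indication >= 30,
      .data$indication_date >= .data$registration_start,
      .data$indication_date <= config$admin_censor_date
    )

  if (drug_naive) {
    members <- apply_drug_naive_filter(members, tables$prescriptions)
  }

  if (!is.null(endpoint_dates)) {
    members <- left_join(members, endpoint_dates, by = "patient_id")
  } else {
    members$endpoint_date <- as.Date(NA)
  }

  fe <- resolve_followup_end(
    endpoint_date = members$endpoint_date,
    death_date = members$death_date,
    last_collection_date = members$practice_last_collection,
    deregistration_date = members$registration_end,
    admin_censor_date = config$admin_censor_date
  )
  members |>
    bind_cols(fe) |>
    filter(.data$followup_end >= .data$indication_date) |>
    select(
      "patient_id", "liver_status", "liver_subtypes", "liver_first_date",
      "indication_class", "indication_condition", "indication_date",
      "followup_end", "followup_end_reason", "age_at_indication",
      "sex", "region"
    )
}
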