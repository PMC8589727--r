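#' Build supply episodes from prescription issues
#'
#' Each issue opens a covered interval of `supply_days` days unless the
#' next issue of the same stream arrives earlier, in which case the episode
#' is truncated at the next issue (no stockpiling): for consecutive issues
#' `d[i], d[i+1]` the episode is `[d[i], d[i] + min(supply_days,
#' d[i+1] - d[i]))`; the last issue always contributes `supply_days`.
#' Same-day duplicate issues collapse to one. Intervals are half-open, so
#' episodes of one stream never overlap.
#'
#' @param prescriptions Validated prescriptions tibble (any number of
#'   patients and drugs).
#' @param supply_days Assumed supply per issue (default 30).
#' @param level `"drug"` builds one episode stream per patient-drug;
#'   `"class"` pools all issues of one drug class per patient (the union
#'   stream used for class-level adherence summaries).
#' @return Tibble `patient_id`, `drug` (`"any"` at class level), `start`,
#'   `end`, ordered by start within stream.
#' @examples
#' rx <- tibble::tibble(
#'   patient_id = "p1",
#'   issue_date = as.Date("2015-01-01") + c(0, 25, 60),
#'   drug = "warfarin"
#' )
#' build_supply_episodes(rx)
#' @export
build_supply_episodes <- function(prescriptions, supply_days = 30, level = c("drug", "class")) {
  level <- match.arg(level)
  if (nrow(prescriptions) == 0) {
    return(tibble(
      patient_id = character(0), drug = character(0),
      start = as.Date(character(0)), end = as.Date(character(0))
    ))
  }
  df <- as_tibble(prescriptions)
  if (level == "class") df$drug <- "any"
  df |>
    distinct(.data$patient_id, .data$drug, .data$issue_date) |>
    arrange(.data$patient_id, .data$drug, .data$issue_date) |>
    group_by(.data$patient_id, .data$drug) |>
    mutate(
      gap_to_next = as.numeric(lead(.data$issue_date) - .data$issue_date),
      duration = pmin(supply_days, .data$gap_to_next, na.rm = TRUE),
      duration = if_else(is.na(.data$gap_to_next), as.numeric(supply_days), .data$duration)
    ) |>
    ungroup() |>
    mutate(start = .data$issue_date, end = .data$issue_date + .data$duration) |>
    select("patient_id", "drug", "start", "end")
}

#' Classify primary non-adherence within a drug class
#'
#' A patient is primary non-adherent when they received exactly one
#' prescription event of the class (one distinct issue-date/drug pair)
#' during follow-up and never refilled. Patients with zero prescriptions
#' are outside the classification and are absent from the result.
#'
#' @param prescriptions Prescriptions of one drug class (already clipped
#'   to follow-up by the caller).
#' @return Tibble `patient_id`, `n_issues`, `primary_nonadherent`.
#' @export
classify_primary_nonadherence <- function(prescriptions) {
  prescriptions |>
    distinct(.data$patient_id, .data$issue_date, .data$drug) |>
    count(.data$patient_id, name = "n_issues") |>
    mutate(primary_nonadherent = .data$n_issues == 1L)
}

# total episode-day overlap with [win_start, win_end), one stream
overlap_days <- function(start, end, win_start, win_end) {
  sum(pmax(0, as.numeric(pmin(end, win_end) - pmax(start, win_start))))
}

#' Proportion of days covered over a fixed window
#'
#' PDC is the total length of the supply episodes intersected with the
#' window `[index, index + window_days)` divided by `window_days`.
#' Adherence is strict: PDC must exceed the threshold. Patients whose
#' follow-up from index is shorter than the window are ineligible and get
#' `NA` PDC; primary non-adherent patients are ineligible by definition.
#'
#' @param episodes Episode tibble from [build_supply_episodes()].
#' @param index_tbl Tibble `patient_id`, optional `drug`, `index_date`
#'   (first prescription date) and `followup_days` (days from index to end
#'   of follow-up); an optional `primary_nonadherent` column marks
#'   ineligible patients.
#' @param window_days Window length (183 for 6 months, 365 for 12).
#' @param pdc_threshold Adherence threshold (default 0.80, strict `>`).
#' @return Tibble `patient_id`, `drug`, `window_days`, `eligible`,
#'   `covered_days`, `pdc`, `adherent`.
#' @export
compute_pdc <- function(episodes, index_tbl, window_days,
                        pdc_threshold = 0.80) {
  by <- intersect(c("patient_id", "drug"), names(index_tbl))
  if (!"primary_nonadherent" %in% names(index_tbl)) {
    index_tbl$primary_nonadherent <- FALSE
  }
  joined <- index_tbl |>
    left_join(episodes, by = by, relationship = "one-to-many")
  out <- joined |>
    group_by(across(dplyr::all_of(c(by, "index_date", "followup_days", "primary_nonadherent")))) |>
    summarise(
      covered_days = overlap_days(
        .data$start, .data$end,
        .data$index_date[1], .data$index_date[1] + window_days
      ),
      .groups = "drop"
    ) |>
    mutate(
      window_days = window_days,
      eligible = .data$followup_days >= window_days & !.data$primary_nonadherent
    ) |>
    (\(d) {
      if (any(d$eligible & is.na(d$covered_days))) {
        abort("compute_pdc: eligible patient with no supply episodes (first prescription implies at least one)")
      }
      d
    })() |>
    mutate(
      covered_days = if_else(.data$eligible, .data$covered_days, NA_real_),
      pdc = .data$covered_days / window_days,
      adherent = .data$eligible & !is.na(.data$pdc) & .data$pdc > pdc_threshold
    )
  if (!"drug" %in% names(out)) out$drug <- "any"
  out |>
    select(dplyr::all_of(c(
      "patient_id", "drug", "index_date", "followup_days", "window_days",
      "eligible", "covered_days", "pdc", "adherent"
    )))
}

#' Per-patient adherence summary for a cohort
#'
#' Restricts prescriptions to the member's indication class within
#' follow-up, finds the index prescription, classifies primary
#' non-adherence at class level, builds episodes at the requested level and
#' computes PDC over the 6- or 12-month window.
#'
#' @param members Cohort tibble from [build_cohort()].
#' @param prescriptions Validated prescriptions tibble.
#' @param config A [study_config()].
#' @param window `"6m"` or `"12m"`.
#' @param level `"drug"` (PDC of the index drug) or `"class"` (union of
#'   all class episodes).
#' @return One row per prescribed member: `patient_id`, `index_drug`,
#'   `index_date`, `followup_days`, `n_issues`, `primary_nonadherent`,
#'   plus the [compute_pdc()] columns.
#' @export
adherence_summary <- function(members, prescriptions, config = study_config(),
                              window = c("12m", "6m"), level = c("drug", "class")) {
  window <- match.arg(window)
  level <- match.arg(level)
  window_days <- if (window == "6m") config$window_6m_days else config$window_12m_days
  class <- members$indication_class[1]

  rx <- class_stream(members, prescriptions)
  if (nrow(rx) == 0) {
    return(tibble())
  }

  index <- rx |>
    group_by(.data$patient_id) |>
    arrange(.data$issue_date, .data$drug, .by_group = TRUE) |>
    summarise(
      index_drug = first(.data$drug), index_date = first(.data$issue_date),
      .groups = "drop"
    )
  pna <- classify_primary_nonadherence(rx)

  index_tbl <- index |>
    left_join(pna, by = "patient_id") |>
    left_join(members |> select("patient_id", "followup_end"), by = "patient_id") |>
    mutate(followup_days = as.numeric(.data$followup_end - .data$index_date))

  episodes <- if (level == "drug") {
    rx_idx <- rx |>
      inner_join(index, by = "patient_id") |>
      filter(.data$drug == .data$index_drug)
    build_supply_episodes(rx_idx, config$supply_days, level = "drug")
  } else {
    build_supply_episodes(rx, config$supply_days, level = "class")
  }

  idx_for_pdc <- index_tbl |>
    select("patient_id", "index_date", "followup_days", "primary_nonadherent")
  if (level == "drug") {
    idx_for_pdc <- bind_cols(
      idx_for_pdc,
      index_tbl |> select(drug = "index_drug")
    )
  }

  compute_pdc(episodes, idx_for_pdc, window_days, config$pdc_threshold) |>
    rename(index_drug = "drug") |>
    left_join(
      index_tbl |> select("patient_id", "n_issues", "primary_nonadherent"),
      by = "patient_id"
    ) |>
    relocate(
      "patient_id", "index_drug", "index_date", "followup_days",
      "n_issues", "primary_nonadherent"
    )
}

# prescriptions of the members' indication class, clipped to follow-up
class_stream <- function(members, prescriptions) {
  class <- members$indication_class[1]
  prescriptions |>
    filter(.data$drug_class == class) |>
    inner_join(
      members |> select("patient_id", "indication_date", "followup_end"),
      by = "patient_id"
    ) |>
    filter(
      .data$issue_date >= .data$indication_date,
      .data$issue_date <= .data$followup_end
    ) |>
    select("patient_id", "issue_date", "drug", "drug_class", "followup_end")
}
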