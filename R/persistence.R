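#' Detect treatment discontinuation via the supply-gap rule
#'
#' Scanning the supply episodes of one stream in order, discontinuation
#' occurs at the end of the first episode from which the interval to the
#' next issue (or to the end of follow-up when there is no next issue) is
#' at least `gap_threshold_days`. With `gap_from = "issue"` the gap is
#' measured from the issue date instead of the end of assumed supply.
#'
#' @param episodes Episode tibble for any number of streams
#'   ([build_supply_episodes()] output; `start` is the issue date).
#' @param followup_tbl Tibble `patient_id` (and `drug` if the episodes are
#'   drug-level) with `followup_end`.
#' @param gap_threshold_days Gap threshold (default 90, compared `>=`).
#' @param gap_from `"supply_end"` (default) or `"issue"`.
#' @return Tibble `patient_id`, `drug`, `discontinuation_date` (`NA` when
#'   the stream never discontinues within follow-up).
#' @export
detect_discontinuation <- function(episodes, followup_tbl,
                                   gap_threshold_days = 90,
                                   gap_from = c("supply_end", "issue")) {
  gap_from <- match.arg(gap_from)
  by <- intersect(c("patient_id", "drug"), names(followup_tbl))
  joined <- followup_tbl |>
    left_join(episodes, by = by, relationship = "one-to-many") |>
    group_by(across(dplyr::all_of(by))) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      next_issue = lead(.data$start),
      gap_anchor = if (gap_from == "supply_end") .data$end else .data$start,
      gap = as.numeric(
        if_else(is.na(.data$next_issue), .data$followup_end, .data$next_issue) -
          .data$gap_anchor
      )
    ) |>
    summarise(
      discontinuation_date = {
        hit <- which(.data$gap >= gap_threshold_days)
        if (length(hit) == 0) as.Date(NA) else .data$end[hit[1]]
      },
      .groups = "drop"
    )
  if (!"drug" %in% names(joined)) joined$drug <- "any"
  joined[, c(by, setdiff(c("drug", "discontinuation_date"), by))]
}

#' Detect an in-class switch away from the index drug
#'
#' The switch date is the first issue, within follow-up, of a drug of the
#' same class different from the index (first-prescribed) drug.
#'
#' @param prescriptions Class-level prescription stream with
#'   `patient_id`, `issue_date`, `drug`.
#' @param index_tbl Tibble `patient_id`, `index_drug`, `followup_end`.
#' @return Tibble `patient_id`, `switch_date` (`NA` when no switch).
#' @export
detect_switch <- function(prescriptions, index_tbl) {
  index_tbl |>
    left_join(
      prescriptions |> select("patient_id", "issue_date", "drug"),
      by = "patient_id", relationship = "one-to-many"
    ) |>
    group_by(.data$patient_id) |>
    summarise(
      switch_date = {
        alt <- .data$issue_date[!is.na(.data$drug) &
          .data$drug != .data$index_drug[1] &
          .data$issue_date <= .data$followup_end[1]]
        if (length(alt) == 0) as.Date(NA) else min(alt)
      },
      .groups = "drop"
    )
}

persistence_status_levels <- c(
  "persistent", "non_persistent", "censored_switch", "censored_followup"
)

#' Landmark persistence status
#'
#' The earliest of discontinuation, switch and end of follow-up decides
#' the status at the landmark: a discontinuation first makes the patient
#' non-persistent; a switch first censors them (`censored_switch`, not
#' counted as non-persistent); follow-up ending first censors them
#' (`censored_followup`); if nothing happens before the landmark the
#' patient is persistent. A same-day discontinuation/switch tie resolves
#' to the switch.
#'
#' @param disc_days,switch_days,followup_days Days from index to each
#'   event (`NA` when absent), vectorised.
#' @param landmark_days Landmark (183 or 365).
#' @return Character vector of statuses.
#' @export
landmark_status <- function(disc_days, switch_days, followup_days, landmark_days) {
  d <- if_else(is.na(disc_days), Inf, as.numeric(disc_days))
  s <- if_else(is.na(switch_days), Inf, as.numeric(switch_days))
  f <- as.numeric(followup_days)
  first_event <- pmin(d, s, f)
  case_when(
    first_event >= landmark_days ~ "persistent",
    s <= d & s <= f ~ "censored_switch", # same-day tie: switch dominates
    d < s & d <= f ~ "non_persistent",
    .default = "censored_followup"
  )
}

#' Per-patient persistence summary for a cohort
#'
#' Builds index-drug supply episodes, applies the gap rule and switch
#' censoring, and reports the landmark status at 6 and 12 months together
#' with the time-to-event columns a Cox model consumes (`event_time_days`
#' from index to discontinuation or censoring, `event_flag` for an
#' observed discontinuation).
#'
#' @inheritParams adherence_summary
#' @return One row per prescribed member: `patient_id`, `index_drug`,
#'   `index_date`, `followup_days`, `primary_nonadherent`,
#'   `discontinuation_date`, `switch_date`, `disc_days`, `switch_days`,
#'   `status_6m`, `status_12m`, `event_time_days`, `event_flag`.
#' @export
persistence_summary <- function(members, prescriptions, config = study_config()) {
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
    ) |>
    left_join(members |> select("patient_id", "followup_end"), by = "patient_id")
  pna <- classify_primary_nonadherence(rx)

  rx_idx <- rx |>
    inner_join(index |> select("patient_id", "index_drug"), by = "patient_id") |>
    filter(.data$drug == .data$index_drug)
  episodes <- build_supply_episodes(rx_idx, config$supply_days, level = "drug") |>
    rename(index_drug = "drug")

  sw <- detect_switch(rx, index |> select("patient_id", "index_drug", "followup_end"))

  # a switch interrupts any pending gap: the gap scan stops at the switch,
  # so only gaps that reach the threshold before the switch discontinue
  fu_for_gap <- index |>
    left_join(sw, by = "patient_id") |>
    mutate(followup_end = pmin(.data$followup_end, .data$switch_date, na.rm = TRUE)) |>
    select("patient_id", drug = "index_drug", "followup_end")
  disc <- detect_discontinuation(
    episodes |> rename(drug = "index_drug"),
    fu_for_gap,
    config$gap_threshold_days, config$gap_from
  ) |>
    select("patient_id", "discontinuation_date")

  index |>
    left_join(pna, by = "patient_id") |>
    left_join(disc, by = "patient_id") |>
    left_join(sw, by = "patient_id") |>
    mutate(
      followup_days = as.numeric(.data$followup_end - .data$index_date),
      disc_days = as.numeric(.data$discontinuation_date - .data$index_date),
      switch_days = as.numeric(.data$switch_date - .data$index_date),
      status_6m = landmark_status(
        .data$disc_days, .data$switch_days, .data$followup_days,
        config$window_6m_days
      ),
      status_12m = landmark_status(
        .data$disc_days, .data$switch_days, .data$followup_days,
        config$window_12m_days
      ),
      event_time_days = pmin(
        if_else(is.na(.data$disc_days), Inf, .data$disc_days),
        if_else(is.na(.data$switch_days), Inf, .data$switch_days),
        .data$followup_days
      ),
      event_flag = !is.na(.data$disc_days) &
        .data$disc_days <= .data$event_time_days &
        (is.na(.data$switch_days) | .data$disc_days < .data$switch_days)
    ) |>
    select(
      "patient_id", "index_drug", "index_date", "followup_days",
      "n_issues", "primary_nonadherent", "discontinuation_date",
      "switch_date", "disc_days", "switch_days", "status_6m", "status_12m",
      "event_time_days", "event_flag"
    )
}

#' Joint adherence-by-persistence classification
#'
#' Cross-classifies landmark-eligible patients (follow-up at least the
#' landmark, not primary non-adherent) into adherent/non-adherent times
#' persistent/non-persistent, with switch- and follow-up-censored patients
#' carried as their own rows. Percentages use the full landmark-eligible
#' population as denominator, censored patients included.
#'
#' @param adherence Output of [adherence_summary()] for the landmark
#'   window.
#' @param persistence Output of [persistence_summary()].
#' @param landmark `"6m"` or `"12m"`.
#' @param by Optional grouping columns present in either input (for
#'   example `index_drug`).
#' @return Tibble with `cell`, `k`, `n`, `percent` per group.
#' @export
joint_classification <- function(adherence, persistence,
                                 landmark = c("12m", "6m"), by = "index_drug") {
  landmark <- match.arg(landmark)
  status_col <- if (landmark == "6m") "status_6m" else "status_12m"
  df <- adherence |>
    select("patient_id", "index_drug", "eligible", "adherent") |>
    inner_join(
      persistence |>
        select("patient_id", status = dplyr::all_of(status_col)),
      by = "patient_id"
    ) |>
    filter(.data$eligible) |>
    mutate(
      cell = case_when(
        .data$status == "censored_switch" ~ "censored_switch",
        .data$status == "censored_followup" ~ "censored_followup",
        .data$adherent & .data$status == "persistent" ~ "adherent_persistent",
        .data$adherent & .data$status == "non_persistent" ~ "adherent_non_persistent",
        !.data$adherent & .data$status == "persistent" ~ "non_adherent_persistent",
        .default = "non_adherent_non_persistent"
      )
    )
  by <- intersect(by, names(df))
  df |>
    group_by(across(dplyr::all_of(by))) |>
    mutate(n = dplyr::n()) |>
    group_by(across(dplyr::all_of(c(by, "n", "cell")))) |>
    summarise(k = dplyr::n(), .groups = "drop") |>
    mutate(percent = 100 * .data$k / .data$n) |>
    relocate(dplyr::all_of(by), "cell", "k", "n", "percent")
}
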