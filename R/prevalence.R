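#' Wald confidence interval for a prescribing proportion
#'
#' Normal-approximation (central-limit-theorem) interval for a dichotomous
#' outcome, reported per 100 persons: with `p = k/n`, the half-width is
#' `z * sqrt(p * (1 - p) / n)` and the bounds `100 * (p -/+ half-width)`,
#' clipped to `[0, 100]`. Degenerate cells (`k` equal to 0 or `n`) yield a
#' zero-width interval and are flagged.
#'
#' @param k Numerators (counts, vectorised).
#' @param n Denominators (counts, positive).
#' @param z Normal quantile (default 1.96 for 95% coverage).
#' @return Tibble `k`, `n`, `percent`, `ci_low`, `ci_high`, `degenerate`.
#'   Values are unrounded; use [format_percent()] for presentation.
#' @examples
#' wald_ci(806, 3921)
#' @export
wald_ci <- function(k, n, z = 1.96) {
  if (any(n <= 0)) abort("wald_ci: denominator must be positive")
  if (any(k < 0 | k > n)) abort("wald_ci: need 0 <= k <= n")
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  tibble(
    k = k, n = n,
    percent = 100 * p,
    ci_low = pmax(0, 100 * (p - half)),
    ci_high = pmin(100, 100 * (p + half)),
    degenerate = k == 0 | k == n
  )
}

#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding for percentages (base `round()` rounds half to
#' even, which never reproduces printed rates such as 20.65 -> 20.7).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5 + 1e-9 * sign(x)) / 10^digits
}

#' @rdname round_half_up
#' @export
format_percent <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}

#' Prescribing prevalence per 100 persons, overall and stratified
#'
#' The denominator is the drug-naive cohort; the numerator counts members
#' with at least one prescription of any drug in the indication class on or
#' after the indication date (optionally restricted to follow-up). Strata:
#' overall, liver status, each liver subtype (a patient with several
#' subtypes counts in each), region, or any member column.
#'
#' @param members Cohort tibble from [build_cohort()].
#' @param prescriptions Validated prescriptions tibble.
#' @param by Character vector of strata: any of `"liver_status"`,
#'   `"liver_subtype"`, `"region"`, or another column of `members`;
#'   `NULL` gives the overall estimate.
#' @param config A [study_config()].
#' @param within_followup Count only prescriptions on or before
#'   `followup_end` (default `FALSE`: any prescription on/after the
#'   indication counts).
#' @return Tibble with one row per stratum level: the stratum columns plus
#'   the [wald_ci()] columns.
#' @export
prevalence_table <- function(members, prescriptions, by = NULL,
                             config = study_config(),
                             within_followup = FALSE) {
  stopifnot(length(unique(members$indication_class)) <= 1)
  rx <- prescriptions |>
    inner_join(
      members |>
        select("patient_id", "indication_class", "indication_date", "followup_end"),
      by = "patient_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$drug_class == .data$indication_class,
      .data$issue_date >= .data$indication_date
    )
  if (within_followup) {
    rx <- filter(rx, .data$issue_date <= .data$followup_end)
  }
  prescribed_ids <- unique(rx$patient_id)
  members <- mutate(members, prescribed = .data$patient_id %in% prescribed_ids)

  if (is.null(by)) {
    return(wald_ci(sum(members$prescribed), nrow(members), config$ci_z))
  }

  purrr::map_dfr(by, function(stratum) {
    if (stratum == "liver_subtype") {
      expanded <- members |>
        filter(.data$liver_status == "with_liver_disease") |>
        tidyr::unnest_longer("liver_subtypes", values_to = "level")
      grouped <- expanded |> group_by(.data$level)
    } else {
      if (!stratum %in% names(members)) {
        abort(sprintf("prevalence_table: unknown stratum '%s'", stratum))
      }
      grouped <- members |>
        mutate(level = as.character(.data[[stratum]])) |>
        group_by(.data$level)
    }
    grouped |>
      summarise(k = sum(.data$prescribed), n = dplyr::n(), .groups = "drop") |>
      mutate(stratum = stratum) |>
      bind_cols() |>
      (\(d) bind_cols(
        d[, c("stratum", "level")],
        wald_ci(d$k, d$n, config$ci_z)
      ))()
  })
}
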