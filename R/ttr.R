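#' Fraction of an inter-measurement interval spent in therapeutic range
#'
#' Between two consecutive INR measurements the INR is assumed to move
#' linearly, so the fraction of time in range equals the fraction of the
#' INR shift that lies inside the range: the length of the intersection of
#' the value interval `[min(a, b), max(a, b)]` with `[lower, upper]`
#' divided by `|b - a|`. When the two values are equal the fraction is 1
#' if the common value is in range, else 0. Boundaries are inclusive.
#'
#' @param inr_a,inr_b Consecutive INR values (vectorised).
#' @param lower,upper Therapeutic range (default 2 and 3).
#' @return Fractions in `[0, 1]`.
#' @examples
#' interval_in_range_fraction(1.8, 2.3) # 0.3 of a 0.5 shift -> 0.6
#' @export
interval_in_range_fraction <- function(inr_a, inr_b, lower = 2, upper = 3) {
  lo <- pmin(inr_a, inr_b)
  hi <- pmax(inr_a, inr_b)
  flat <- hi == lo
  inter <- pmax(0, pmin(hi, upper) - pmax(lo, lower))
  out <- if_else(flat,
    as.numeric(lo >= lower & lo <= upper),
    inter / (hi - lo)
  )
  out
}

#' Rosendaal time in therapeutic range for one INR series
#'
#' Linear interpolation assigns an INR value to each day between
#' consecutive measurements; TTR is the percentage of interpolated time
#' with INR in `[lower, upper]`. Time before the first and after the last
#' measurement is not interpolated and is excluded from the denominator.
#' At least two measurements inside the period are required; otherwise the
#' TTR is undefined (`NA`).
#'
#' @param dates Measurement dates (Date or numeric days), one patient.
#' @param values INR values, same length.
#' @param period_start,period_end Optional period bounds; measurements
#'   outside are dropped.
#' @param lower,upper Therapeutic range (default 2-3, inclusive).
#' @param ttr_cut Percent cut for the `above_cut` flag (default 60).
#' @param max_gap_days Optional maximum inter-measurement gap; longer
#'   gaps are excluded from the interpolation (default unlimited).
#' @return One-row tibble `n_measurements`, `days_in_range`,
#'   `total_interpolated_days`, `ttr_percent`, `above_cut`.
#' @examples
#' rosendaal_ttr(c(0, 10, 20, 30), c(1.5, 2.5, 3.5, 2.5))
#' @export
rosendaal_ttr <- function(dates, values, period_start = NULL,
                          period_end = NULL, lower = 2, upper = 3,
                          ttr_cut = 60, max_gap_days = Inf) {
  ord <- order(dates)
  dates <- as.numeric(dates)[ord]
  values <- values[ord]
  keep <- rep(TRUE, length(dates))
  if (!is.null(period_start)) keep <- keep & dates >= as.numeric(period_start)
  if (!is.null(period_end)) keep <- keep & dates <= as.numeric(period_end)
  dates <- dates[keep]
  values <- values[keep]
  if (length(dates) < 2) {
    return(tibble(
      n_measurements = length(dates), days_in_range = NA_real_,
      total_interpolated_days = NA_real_, ttr_percent = NA_real_,
      above_cut = NA
    ))
  }
  gaps <- diff(dates)
  fracs <- interval_in_range_fraction(
    values[-length(values)], values[-1],
    lower, upper
  )
  use <- gaps > 0 & gaps <= max_gap_days
  days_in <- sum(fracs[use] * gaps[use])
  total <- sum(gaps[use])
  ttr <- if (total > 0) 100 * days_in / total else NA_real_
  tibble(
    n_measurements = length(dates), days_in_range = days_in,
    total_interpolated_days = total, ttr_percent = ttr,
    above_cut = if (is.na(ttr)) NA else ttr > ttr_cut
  )
}

#' TTR for every warfarin user in a cohort
#'
#' Computes [rosendaal_ttr()] per patient from the INR rows of the labs
#' table, over the period from the index date to `index + period_days`
#' (default the 12-month adherence window).
#'
#' @param index_tbl Tibble `patient_id`, `index_date` (warfarin users).
#' @param labs Validated labs tibble.
#' @param period_days Assessment period length from index (default 365).
#' @param config A [study_config()] (`ttr_cut`).
#' @param ... Passed to [rosendaal_ttr()].
#' @return One row per patient of `index_tbl` with the TTR columns;
#'   patients with fewer than two in-period INR measurements get `NA` TTR.
#' @export
ttr_summary <- function(index_tbl, labs, period_days = 365,
                        config = study_config(), ...) {
  inr <- labs |>
    filter(.data$analyte == "INR") |>
    inner_join(index_tbl |> select("patient_id", "index_date"),
      by = "patient_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$date >= .data$index_date,
      .data$date <= .data$index_date + period_days
    )
  res <- inr |>
    group_by(.data$patient_id) |>
    summarise(
      rosendaal_ttr(.data$date, .data$value, ttr_cut = config$ttr_cut, ...),
      .groups = "drop"
    )
  index_tbl |>
    left_join(res, by = "patient_id") |>
    mutate(n_measurements = if_else(is.na(.data$n_measurements), 0L, .data$n_measurements))
}
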