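# Shared fixtures and independent oracles, all built in code.

origin_date <- as.Date("2015-01-01")

# prescription stream at integer day offsets from a fixed origin
mk_rx <- function(days, drug = "warfarin", id = "p1", origin = origin_date) {
  validate_ehr_table(
    tibble::tibble(patient_id = id, issue_date = origin + days, drug = drug),
    "prescriptions"
  )
}

# minimal cohort-member rows for adherence/persistence drivers
mk_members <- function(ids, class = "anticoagulant",
                       indication_day = 0, followup_day = 400,
                       origin = origin_date) {
  tibble::tibble(
    patient_id = ids,
    indication_class = class,
    indication_date = origin + indication_day,
    followup_end = origin + followup_day
  )
}

# brute-force day-grid PDC oracle: mark each covered day in a boolean array
oracle_pdc_daygrid <- function(issue_days, supply, window) {
  issue_days <- sort(unique(issue_days))
  index <- issue_days[1]
  covered <- rep(FALSE, window)
  n <- length(issue_days)
  for (i in seq_len(n)) {
    dur <- if (i < n) min(supply, issue_days[i + 1] - issue_days[i]) else supply
    days <- seq(issue_days[i], length.out = dur) - index # 0-based day offsets
    days <- days[days >= 0 & days < window]
    covered[days + 1] <- TRUE
  }
  mean(covered)
}

# 1e-3-day midpoint quadrature of the piecewise-linear INR path's [2,3]
# indicator. In-range midpoints are counted analytically per pair (the
# count has a closed form for a linear segment), so arbitrarily long
# series cost O(pairs), not O(days/step).
oracle_ttr_quadrature <- function(days, values, h = 1e-3,
                                  lower = 2, upper = 3) {
  ord <- order(days)
  days <- as.numeric(days)[ord]
  values <- values[ord]
  in_days <- 0
  total <- 0
  for (i in seq_len(length(days) - 1)) {
    g <- days[i + 1] - days[i]
    if (g <= 0) next
    n_steps <- round(g / h)
    y0 <- values[i]
    y1 <- values[i + 1]
    if (y0 == y1) {
      count <- if (y0 >= lower && y0 <= upper) n_steps else 0
    } else {
      s <- (y1 - y0) / g
      t_at <- function(y) (y - y0) / s
      t_lo <- max(0, min(t_at(lower), t_at(upper)))
      t_hi <- min(g, max(t_at(lower), t_at(upper)))
      if (t_hi <= 0 || t_lo >= g || t_hi < t_lo) {
        count <- 0
      } else {
        # midpoints are (k + 0.5) * h, k = 0 .. n_steps - 1
        k_lo <- max(0, ceiling(t_lo / h - 0.5))
        k_hi <- min(n_steps - 1, floor(t_hi / h - 0.5))
        count <- max(0, k_hi - k_lo + 1)
      }
    }
    in_days <- in_days + count * h
    total <- total + n_steps * h
  }
  if (total == 0) {
    return(NA_real_)
  }
  in_days / total
}

# direct (materialised) midpoint quadrature, for cross-checking the
# analytic counting on small cases
oracle_ttr_quadrature_direct <- function(days, values, h = 1e-3,
                                         lower = 2, upper = 3) {
  ord <- order(days)
  days <- as.numeric(days)[ord]
  values <- values[ord]
  in_steps <- 0
  total_steps <- 0
  for (i in seq_len(length(days) - 1)) {
    g <- days[i + 1] - days[i]
    if (g <= 0) next
    n_steps <- round(g / h)
    mid <- (seq_len(n_steps) - 0.5) * h
    y <- values[i] + (values[i + 1] - values[i]) * mid / g
    in_steps <- in_steps + sum(y >= lower & y <= upper)
    total_steps <- total_steps + n_steps
  }
  if (total_steps == 0) {
    return(NA_real_)
  }
  in_steps / total_steps
}

# exact TTR by solving range-boundary crossing times on each linear
# segment and summing sub-interval lengths (time-domain derivation,
# independent of the value-shift ratio used by the implementation)
oracle_ttr_exact <- function(days, values, lower = 2, upper = 3) {
  ord <- order(days)
  days <- as.numeric(days)[ord]
  values <- values[ord]
  in_days <- 0
  total <- 0
  for (i in seq_len(length(days) - 1)) {
    g <- days[i + 1] - days[i]
    if (g <= 0) next
    y0 <- values[i]
    y1 <- values[i + 1]
    if (y0 == y1) {
      t_in <- if (y0 >= lower && y0 <= upper) g else 0
    } else {
      s <- (y1 - y0) / g
      ts <- sort(c((lower - y0) / s, (upper - y0) / s))
      t_in <- max(0, min(g, ts[2]) - max(0, ts[1]))
    }
    in_days <- in_days + t_in
    total <- total + g
  }
  if (total == 0) {
    return(NA_real_)
  }
  in_days / total
}

# random prescription stream for property tests
random_stream <- function(n_issues, max_gap = 90) {
  cumsum(c(0, sample.int(max_gap, n_issues - 1, replace = TRUE)))
}
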