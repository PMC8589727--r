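#' @rdname derive_uncovered_exposure
#' @export
uncovered_category_labels <- c(
  "<1 week", "1 week to 1 month", "1 to 3 months", "3 to 6 months",
  ">6 months"
)

#' Uncovered-time exposure over follow-up
#'
#' Uncovered days are the follow-up days from index not covered by supply
#' episodes; the category boundaries are `<7`, `[7, 30)`, `[30, 91)`,
#' `[91, 183)` and `>=183` days (calendar readings of 1 week, 1 month,
#' 3 months, 6 months).
#'
#' @param episodes Episode tibble ([build_supply_episodes()]).
#' @param index_tbl Tibble `patient_id` (plus `drug` if drug-level),
#'   `index_date`, `followup_days`.
#' @return `index_tbl` plus `covered_days`, `uncovered_days`,
#'   `uncovered_category` (factor with the five labels).
#' @export
derive_uncovered_exposure <- function(episodes, index_tbl) {
  by <- intersect(c("patient_id", "drug"), names(index_tbl))
  index_tbl |>
    left_join(episodes, by = by, relationship = "one-to-many") |>
    group_by(across(dplyr::all_of(c(by, "index_date", "followup_days")))) |>
    summarise(
      covered_days = overlap_days(
        .data$start, .data$end,
        .data$index_date[1], .data$index_date[1] + .data$followup_days[1]
      ),
      .groups = "drop"
    ) |>
    mutate(
      covered_days = if_else(is.na(.data$covered_days), 0, .data$covered_days),
      uncovered_days = pmax(0, .data$followup_days - .data$covered_days),
      uncovered_category = cut(.data$uncovered_days,
        breaks = c(-Inf, 7, 30, 91, 183, Inf), right = FALSE,
        labels = uncovered_category_labels
      )
    )
}

new_thromb_fit <- function(fit, family, effect_label, data_n, events = NA_integer_,
                           ph = NULL) {
  structure(
    list(
      fit = fit, family = family, effect_label = effect_label,
      n = data_n, events = events, ph = ph
    ),
    class = "thromb_fit"
  )
}

#' @export
print.thromb_fit <- function(x, ...) {
  cat(sprintf(
    "<thromb_fit: %s> n = %d%s\n", x$family, x$n,
    if (!is.na(x$events)) sprintf(", events = %d", x$events) else ""
  ))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a fitted adherence/persistence/outcome model
#'
#' Returns one row per model term with the exponentiated estimate (odds
#' ratio for logistic fits, hazard ratio for Cox fits), Wald confidence
#' limits computed on the log scale, and the Wald p-value.
#'
#' @param x A `thromb_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `ci_low`, `ci_high`, `p_value`.
#' @method tidy thromb_fit
#' @export
tidy.thromb_fit <- function(x, conf_level = 0.95, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  keep <- !is.na(est) & names(est) != "(Intercept)"
  est <- est[keep]
  se <- se[names(est)]
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(est),
    estimate = unname(exp(est)),
    ci_low = unname(exp(est - z * se)),
    ci_high = unname(exp(est + z * se)),
    p_value = unname(2 * pnorm(-abs(est / se)))
  )
}

#' @rdname tidy.thromb_fit
#' @method glance thromb_fit
#' @export
glance.thromb_fit <- function(x, ...) {
  tibble(
    family = x$family, n = x$n, events = x$events,
    n_terms = sum(!is.na(coef(x$fit))),
    ph_global_p = if (!is.null(x$ph)) x$ph$table["GLOBAL", "p"] else NA_real_
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

relevel_covariates <- function(df, covariates) {
  # reference levels: warfarin / aspirin for drug, first band elsewhere
  refs <- list(
    index_drug = c("warfarin", "aspirin"),
    age_band = "30-49",
    chadsvasc_stratum = "0-1",
    child_pugh_class = "A",
    fib4_stratum = "<1.45",
    uncovered_category = uncovered_category_labels[1]
  )
  for (cov in covariates) {
    v <- df[[cov]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      ref <- intersect(refs[[cov]] %||% character(0), levels(v))
      if (length(ref) > 0) v <- stats::relevel(v, ref = ref[1])
      df[[cov]] <- v
    }
  }
  df
}

drop_empty_terms <- function(df, covariates) {
  keep <- vapply(covariates, function(cov) {
    v <- df[[cov]]
    if (is.null(v)) {
      warn(sprintf("covariate '%s' absent; dropped", cov))
      return(FALSE)
    }
    if (is.character(v) || is.factor(v)) {
      nlev <- length(unique(v[!is.na(v)]))
      if (nlev < 2) {
        warn(sprintf("covariate '%s' has a single level; dropped", cov))
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  covariates[keep]
}

#' Age bands used as model covariates
#'
#' @param age_years Numeric ages.
#' @return Factor with levels 30-49, 50-59, 60-69, 70-79, 80+.
#' @export
age_band <- function(age_years) {
  cut(age_years,
    breaks = c(30, 50, 60, 70, 80, Inf), right = FALSE,
    labels = c("30-49", "50-59", "60-69", "70-79", "80+")
  )
}

#' Multivariable logistic model of non-adherence
#'
#' Fits non-adherence at the 6- or 12-month horizon among eligible,
#' non-primary-non-adherent patients by maximum-likelihood logistic
#' regression, fully adjusted for the supplied covariates. Reference
#' levels follow the study convention (warfarin or aspirin for drug, age
#' 30-49, CHA2DS2-VASc 0-1, Child-Pugh A, FIB-4 <1.45).
#'
#' @param rows Covariate tibble with a logical `non_adherent` outcome.
#' @param covariates Character vector of covariate column names.
#' @return A `thromb_fit` (see [tidy.thromb_fit()]).
#' @export
fit_nonadherence_model <- function(rows, covariates) {
  stopifnot("non_adherent" %in% names(rows))
  rows <- relevel_covariates(rows, covariates)
  covariates <- drop_empty_terms(rows, covariates)
  f <- as.formula(paste(
    "non_adherent ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- glm(f, data = rows, family = binomial())
  new_thromb_fit(fit, "logistic_nonadherence", "odds ratio",
    data_n = nrow(rows),
    events = sum(rows$non_adherent)
  )
}

#' Cox model of non-persistence
#'
#' Partial-likelihood Cox fit of time to discontinuation, with switch and
#' end of follow-up as censoring. The proportional-hazards assumption is
#' checked with the scaled-Schoenfeld-residual correlation test
#' ([survival::cox.zph()]) and attached to the fit.
#'
#' @param rows Tibble with `event_time_days` (> 0), logical/integer
#'   `event_flag`, and covariates.
#' @inheritParams fit_nonadherence_model
#' @return A `thromb_fit` with a `ph` element.
#' @export
fit_nonpersistence_model <- function(rows, covariates) {
  stopifnot(all(c("event_time_days", "event_flag") %in% names(rows)))
  if (sum(rows$event_flag) == 0) abort("fit_nonpersistence_model: no events")
  rows <- filter(rows, .data$event_time_days > 0)
  rows <- relevel_covariates(rows, covariates)
  covariates <- drop_empty_terms(rows, covariates)
  f <- as.formula(paste(
    "survival::Surv(event_time_days, event_flag) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(f, data = rows)
  ph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  new_thromb_fit(fit, "cox_nonpersistence", "hazard ratio",
    data_n = nrow(rows), events = sum(rows$event_flag), ph = ph
  )
}

#' Cox model of stroke risk by uncovered-time category
#'
#' Hazard of ischaemic stroke by the time spent not taking medication,
#' with `<1 week` as the reference category; optionally stratified by
#' CHA2DS2-VASc stratum (separate baseline hazards) or contrasting liver
#' status within categories.
#'
#' @param rows Tibble with `time_days`, `event`, `uncovered_category` and
#'   optional adjustment covariates.
#' @param covariates Additional adjustment terms (default none).
#' @param strata_col Optional column name for stratified baselines (for
#'   example `"chadsvasc_stratum"`).
#' @param liver_contrast If `TRUE`, fits `liver_status` within
#'   uncovered-category strata (the liver-versus-non-liver contrast), with
#'   `uncovered_category` as strata instead of a covariate.
#' @return A `thromb_fit`.
#' @export
fit_stroke_model <- function(rows, covariates = character(0),
                             strata_col = NULL, liver_contrast = FALSE) {
  stopifnot(all(c("time_days", "event", "uncovered_category") %in% names(rows)))
  rows <- filter(rows, .data$time_days > 0)
  rows$uncovered_category <- factor(rows$uncovered_category,
    levels = uncovered_category_labels
  )
  rows$uncovered_category <- droplevels(rows$uncovered_category)
  if (liver_contrast) {
    terms <- c("liver_status", covariates, "survival::strata(uncovered_category)")
  } else {
    terms <- c("uncovered_category", covariates)
    if (!is.null(strata_col)) {
      terms <- c(terms, sprintf("survival::strata(%s)", strata_col))
    }
  }
  rows <- relevel_covariates(rows, intersect(terms, names(rows)))
  f <- as.formula(paste(
    "survival::Surv(time_days, event) ~", paste(terms, collapse = " + ")
  ))
  fit <- survival::coxph(f, data = rows)
  new_thromb_fit(fit, "cox_stroke", "hazard ratio",
    data_n = nrow(rows), events = sum(rows$event)
  )
}

#' Cox model of bleeding risk per 10-percentage-point PDC
#'
#' Hazard of non-fatal bleeding with adherence entered as PDC scaled in
#' 10-percentage-point increments, so the reported hazard ratio is per
#' 10% PDC increase.
#'
#' @param rows Tibble with `time_days`, `event`, `pdc` in `[0, 1]` and
#'   optional covariates.
#' @param covariates Additional adjustment terms (default none).
#' @param scale_divisor PDC increment as a fraction (default 0.10).
#' @return A `thromb_fit`; the `pdc_per_10pct` term is the per-increment
#'   hazard ratio.
#' @export
fit_bleeding_model <- function(rows, covariates = character(0),
                               scale_divisor = 0.10) {
  stopifnot(all(c("time_days", "event", "pdc") %in% names(rows)))
  rows <- filter(rows, .data$time_days > 0)
  rows$pdc_per_10pct <- rows$pdc / scale_divisor
  terms <- c("pdc_per_10pct", covariates)
  rows <- relevel_covariates(rows, intersect(covariates, names(rows)))
  f <- as.formula(paste(
    "survival::Surv(time_days, event) ~", paste(terms, collapse = " + ")
  ))
  fit <- survival::coxph(f, data = rows)
  new_thromb_fit(fit, "cox_bleeding", "hazard ratio",
    data_n = nrow(rows), events = sum(rows$event)
  )
}
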