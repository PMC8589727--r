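test_that("the single-covariate logistic fit equals the 2x2 cross-ratio", {
  rows <- tibble::tibble(
    exposed = rep(c(TRUE, FALSE), each = 100),
    non_adherent = c(
      rep(c(TRUE, FALSE), c(40, 60)),
      rep(c(TRUE, FALSE), c(20, 80))
    )
  )
  fit <- fit_nonadherence_model(rows, "exposed")
  td <- tidy(fit)
  expect_equal(td$estimate, (40 * 80) / (60 * 20), tolerance = 1e-6)
  expect_true(td$ci_low < td$estimate & td$estimate < td$ci_high)
  expect_lt(td$p_value, 0.05)
})

test_that("reference levels follow the study convention", {
  withr::with_seed(40, {
    rows <- tibble::tibble(
      index_drug = sample(c("warfarin", "apixaban", "rivaroxaban"), 600, replace = TRUE),
      age_band = age_band(runif(600, 30, 95)),
      non_adherent = runif(600) < 0.4
    )
    fit <- fit_nonadherence_model(rows, c("index_drug", "age_band"))
    terms <- tidy(fit)$term
    expect_false(any(grepl("warfarin", terms))) # reference level absorbed
    expect_false(any(grepl("30-49", terms)))
    expect_true(any(grepl("apixaban", terms)))
  })
})

test_that("a planted drug odds ratio is recovered", {
  withr::with_seed(41, {
    n <- 5000
    drug <- sample(c("warfarin", "apixaban"), n, replace = TRUE)
    p <- ifelse(drug == "warfarin", 0.6, 0.6 * 0.5 / (1 - 0.6 + 0.6 * 0.5))
    rows <- tibble::tibble(
      index_drug = drug, non_adherent = runif(n) < p
    )
    est <- tidy(fit_nonadherence_model(rows, "index_drug"))$estimate
    expect_gt(est, 0.40)
    expect_lt(est, 0.62)
  })
})

test_that("a two-group exponential toy recovers the rate ratio as the HR", {
  withr::with_seed(43, {
    n <- 2000
    grp <- rep(c(0, 1), each = n / 2)
    rate <- ifelse(grp == 1, 0.002, 0.001)
    rows <- tibble::tibble(
      event_time_days = rexp(n, rate),
      event_flag = TRUE,
      exposed = grp == 1
    )
    fit <- fit_nonpersistence_model(rows, "exposed")
    est <- tidy(fit)$estimate
    expect_gt(est, 1.8)
    expect_lt(est, 2.2)
    expect_false(is.null(fit$ph)) # PH diagnostic attached
    expect_gt(glance(fit)$ph_global_p, 0) # well-defined p-value
  })
})

test_that("a planted non-persistence HR is recovered with censoring", {
  withr::with_seed(44, {
    n <- 5000
    x <- runif(n) < 0.5
    t_event <- rexp(n, 0.002 * ifelse(x, 1.5, 1))
    t_cens <- runif(n, 100, 700) # ~40-60% events
    rows <- tibble::tibble(
      event_time_days = pmin(t_event, t_cens),
      event_flag = t_event <= t_cens,
      exposed = x
    )
    est <- tidy(fit_nonpersistence_model(rows, "exposed"))$estimate
    expect_gt(est, 1.35)
    expect_lt(est, 1.65)
  })
})

test_that("uncovered time is categorised by the calendar boundaries", {
  ep <- tibble::tibble(
    patient_id = "p1", drug = "any",
    start = origin_date, end = origin_date + 365
  )
  idx <- function(fu) {
    tibble::tibble(
      patient_id = "p1", index_date = origin_date, followup_days = fu
    )
  }
  fully <- derive_uncovered_exposure(ep, idx(365))
  expect_equal(fully$uncovered_days, 0)
  expect_equal(as.character(fully$uncovered_category), "<1 week")

  for (case in list(
    list(u = 6, lab = "<1 week"), list(u = 7, lab = "1 week to 1 month"),
    list(u = 29, lab = "1 week to 1 month"), list(u = 30, lab = "1 to 3 months"),
    list(u = 90, lab = "1 to 3 months"), list(u = 91, lab = "3 to 6 months"),
    list(u = 100, lab = "3 to 6 months"), list(u = 183, lab = ">6 months"),
    list(u = 200, lab = ">6 months")
  )) {
    got <- derive_uncovered_exposure(ep, idx(365 + case$u))
    expect_equal(got$uncovered_days, case$u)
    expect_equal(as.character(got$uncovered_category), case$lab)
  }
})

test_that("the stroke model uses the reference category and recovers effects", {
  cfg <- generator_config(
    stroke_hr_by_uncovered_category = c(1, 1, 1, 1, 1.5),
    stroke_base_hazard = 0.05, seed = 52
  )
  summaries <- withr::with_seed(520, tibble::tibble(
    patient_id = sprintf("s%05d", 1:8000),
    followup_days = 2 * 365,
    uncovered_category = sample(c(1L, 5L), 8000, replace = TRUE),
    pdc = runif(8000)
  ))
  ev <- simulate_outcomes(summaries, cfg)
  stroke <- ev[ev$outcome == "stroke_ischaemic", ]
  rows <- dplyr::inner_join(summaries, stroke[, c("patient_id", "time_days", "event")],
    by = "patient_id"
  )
  rows$uncovered_category <- uncovered_category_labels[rows$uncovered_category]
  td <- tidy(fit_stroke_model(rows))
  expect_equal(nrow(td), 1) # reference "<1 week" absorbed
  expect_true(grepl(">6 months", td$term))
  expect_gt(td$estimate, 1.2)
  expect_lt(td$estimate, 1.9)
})

test_that("the bleeding model reports the per-10%-PDC hazard ratio", {
  cfg <- generator_config(
    bleed_hr_per_10pct_pdc = 1.18, bleed_base_hazard = 0.05, seed = 53
  )
  summaries <- withr::with_seed(530, tibble::tibble(
    patient_id = sprintf("s%05d", 1:8000),
    followup_days = 2 * 365,
    uncovered_category = 1L,
    pdc = runif(8000)
  ))
  ev <- simulate_outcomes(summaries, cfg)
  bleed <- ev[ev$outcome == "bleeding_nonfatal", ]
  rows <- dplyr::inner_join(summaries, bleed[, c("patient_id", "time_days", "event")],
    by = "patient_id"
  )
  fit1 <- fit_bleeding_model(rows, scale_divisor = 0.10)
  est1 <- tidy(fit1)$estimate
  expect_gt(est1, 1.10)
  expect_lt(est1, 1.26)

  # reparameterisation identity: doubling the increment doubles the
  # log-estimate exactly (per-20% effect = squared per-10% effect)
  fit2 <- fit_bleeding_model(rows, scale_divisor = 0.20)
  expect_equal(log(tidy(fit2)$estimate), 2 * log(est1), tolerance = 1e-8)
})

test_that("changing the reference level rescales estimates by exact ratios", {
  withr::with_seed(45, {
    n <- 1500
    drug <- sample(c("warfarin", "apixaban", "rivaroxaban"), n, replace = TRUE)
    rows <- tibble::tibble(
      index_drug = drug,
      non_adherent = runif(n) < ifelse(drug == "warfarin", 0.5, 0.35)
    )
    td_w <- tidy(fit_nonadherence_model(rows, "index_drug"))
    rows2 <- dplyr::mutate(rows, index_drug = factor(index_drug,
      levels = c("apixaban", "warfarin", "rivaroxaban")
    ))
    fit2 <- stats::glm(non_adherent ~ index_drug, data = rows2, family = binomial())
    or_w_vs_a <- exp(coef(fit2)[["index_drugwarfarin"]])
    or_a_vs_w <- td_w$estimate[grepl("apixaban", td_w$term)]
    expect_equal(or_w_vs_a, 1 / or_a_vs_w, tolerance = 1e-9)
  })
})

test_that("single-level covariates are dropped with a warning, not an error", {
  rows <- tibble::tibble(
    index_drug = "warfarin",
    sex = sample(c("male", "female"), 200, replace = TRUE),
    non_adherent = runif(200) < 0.4
  )
  expect_warning(
    fit <- fit_nonadherence_model(rows, c("index_drug", "sex")),
    "single level"
  )
  expect_true(all(grepl("sex", tidy(fit)$term)))
})

test_that("null logistic simulations cover the true odds ratio", {
  covered <- withr::with_seed(46, purrr::map_lgl(1:100, function(i) {
    n <- 1000
    rows <- tibble::tibble(
      exposed = runif(n) < 0.5,
      non_adherent = runif(n) < 0.4 # no effect
    )
    td <- tidy(fit_nonadherence_model(rows, "exposed"))
    td$ci_low <= 1 && 1 <= td$ci_high
  }))
  expect_gte(mean(covered), 0.90)
})

test_that("PH diagnostic p-values look uniform under the null", {
  pvals <- withr::with_seed(47, purrr::map_dbl(1:60, function(i) {
    n <- 400
    rows <- tibble::tibble(
      event_time_days = rexp(n, 0.002),
      event_flag = TRUE,
      exposed = runif(n) < 0.5
    )
    fit <- fit_nonpersistence_model(rows, "exposed")
    fit$ph$table["exposed", "p"]
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
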